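#' Minimum-area enclosing rectangle of a 2D point set
#'
#' Computes the convex hull, then enumerates hull edges (rotating calipers):
#' the minimum-area enclosing rectangle has one side collinear with a hull
#' edge, so the optimum is the smallest rotated bounding box over hull-edge
#' directions. The reported angle is reduced to \[0, pi/2) (a rectangle is
#' invariant under quarter-turns), swapping width and height as needed.
#'
#' Degenerate inputs: a single point gives a 0 x 0 rectangle at angle 0;
#' collinear points give a 0-height rectangle along the segment.
#'
#' @param coords a `gene_coordinates` data.frame, or any data.frame/matrix
#'   with `x` and `y` columns.
#' @return A list of class `enclosing_rectangle` with `center` (length-2),
#'   `angle` (radians in \[0, pi/2)), `width`, `height`, `area`.
#' @export
minimum_enclosing_rectangle <- function(coords) {
  P <- as_xy(coords)
  n <- nrow(P)
  if (n == 0L) stop("need at least one point", call. = FALSE)
  if (n == 1L)
    return(new_rect(center = P[1L, ], angle = 0, width = 0, height = 0))

  hull <- P[unique(grDevices::chull(P[, 1L], P[, 2L])), , drop = FALSE]
  if (nrow(hull) <= 2L) {
    # collinear: chull may return just the extremes; find the longest span
    d2 <- as.matrix(stats::dist(P))
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
    a <- P[ij[1L], ]; b <- P[ij[2L], ]
    theta <- atan2(b[2L] - a[2L], b[1L] - a[1L])
    return(reduce_rect(P, theta))
  }

  edges <- diff(rbind(hull, hull[1L, , drop = FALSE]))
  thetas <- atan2(edges[, 2L], edges[, 1L])
  best <- NULL
  for (th in thetas) {
    r <- rot_extent(hull, th)
    if (is.null(best) || r$area < best$area - 1e-15) {
      best <- r; best$theta <- th
    }
  }
  reduce_rect(P, best$theta)
}

# width/height/area of the bounding box of P rotated by -theta
rot_extent <- function(P, theta) {
  Q <- P %*% rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  w <- max(Q[, 1L]) - min(Q[, 1L])
  h <- max(Q[, 2L]) - min(Q[, 2L])
  list(width = w, height = h, area = w * h)
}

# build the rectangle at angle theta reduced into [0, pi/2)
reduce_rect <- function(P, theta) {
  a <- theta %% (pi / 2)
  if (a > pi / 2 - 1e-12) a <- 0           # guard against wrap-around noise
  cth <- cos(a); sth <- sin(a)
  Rm <- rbind(c(cth, sth), c(-sth, cth))   # rotation by -a
  Q <- P %*% t(Rm)
  xr <- range(Q[, 1L]); yr <- range(Q[, 2L])
  ctr_rot <- c(mean(xr), mean(yr))
  center <- c(cth * ctr_rot[1L] - sth * ctr_rot[2L],
              sth * ctr_rot[1L] + cth * ctr_rot[2L])
  new_rect(center = center, angle = a,
           width = diff(xr), height = diff(yr))
}

new_rect <- function(center, angle, width, height) {
  structure(list(center = as.numeric(center), angle = angle,
                 width = width, height = height, area = width * height),
            class = "enclosing_rectangle")
}

#' Rotate points so their enclosing rectangle is axis-aligned at the origin
#'
#' Applies the rigid motion that rotates by `-rect$angle` about the
#' rectangle center and translates the rectangle's lower-left corner to the
#' origin: the points then lie in \[0, width\] x \[0, height\].
#'
#' @param coords the points the rectangle was fitted on.
#' @param rect an `enclosing_rectangle` from
#'   [minimum_enclosing_rectangle()].
#' @return A `gene_coordinates` data.frame of transformed points.
#' @export
rotate_to_axes <- function(coords, rect) {
  stopifnot(inherits(rect, "enclosing_rectangle"))
  P <- as_xy(coords)
  a <- rect$angle
  Rm <- rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))  # rotation by -a
  ctr <- matrix(rect$center, nrow(P), 2L, byrow = TRUE)
  Q <- (P - ctr) %*% t(Rm)
  Q[, 1L] <- Q[, 1L] + rect$width / 2
  Q[, 2L] <- Q[, 2L] + rect$height / 2
  out <- data.frame(gene_id = gene_ids_of(coords, nrow(P)),
                    x = Q[, 1L], y = Q[, 2L], stringsAsFactors = FALSE)
  class(out) <- c("gene_coordinates", "data.frame")
  out
}

as_xy <- function(coords) {
  if (is.matrix(coords)) return(unname(coords[, 1:2, drop = FALSE]))
  cbind(coords$x, coords$y)
}

gene_ids_of <- function(coords, n) {
  if (!is.null(coords$gene_id)) coords$gene_id else sprintf("p%d", seq_len(n))
}
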