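#' Rasterize axis-aligned gene coordinates onto a pixel grid
#'
#' Each point is scaled from its axis-aligned span to
#' \[0, width-1\] x \[0, height-1\] and snapped to the nearest pixel
#' (round half up). Row 0 is the top of the image, so larger y maps to
#' smaller row index. Genes sharing a pixel form a collision group; their
#' expression values are averaged at render time. A point cloud with zero
#' width (or height) collapses onto a single column (or row).
#'
#' @param coords axis-aligned `gene_coordinates` (from [rotate_to_axes()]).
#' @param resolution integer `c(width, height)` in pixels, each >= 2.
#' @return A list of class `pixel_layout`: `image_width`, `image_height`,
#'   `gene_ids`, `pixel` (genes x 2 integer matrix of 0-based (row, col)),
#'   and `collision_groups` (named list: "row,col" -> gene ids).
#' @export
rasterize <- function(coords, resolution = c(64L, 64L)) {
  P <- as_xy(coords)
  wpx <- as.integer(resolution[1L]); hpx <- as.integer(resolution[2L])
  if (wpx < 2L || hpx < 2L) stop("resolution must be at least 2 x 2", call. = FALSE)
  scale01 <- function(v) {
    r <- range(v)
    if (diff(r) <= 0) rep(0, length(v)) else (v - r[1L]) / diff(r)
  }
  col <- round_half_up(scale01(P[, 1L]) * (wpx - 1L))
  row <- (hpx - 1L) - round_half_up(scale01(P[, 2L]) * (hpx - 1L))
  pixel <- cbind(row = as.integer(row), col = as.integer(col))
  ids <- gene_ids_of(coords, nrow(P))
  key <- paste(pixel[, 1L], pixel[, 2L], sep = ",")
  groups <- split(ids, key)
  structure(list(image_width = wpx, image_height = hpx,
                 gene_ids = ids, pixel = pixel,
                 collision_groups = groups),
            class = "pixel_layout")
}

#' @export
print.pixel_layout <- function(x, ...) {
  cat(sprintf("pixel_layout: %d x %d px, %d genes on %d occupied pixels\n",
              x$image_width, x$image_height, length(x$gene_ids),
              length(x$collision_groups)))
  invisible(x)
}

#' Render one sample's expression vector through a pixel layout
#'
#' Every occupied pixel takes the mean expression of its collision group;
#' all gene-free pixels are exactly 0.
#'
#' @param expression numeric vector with one value per layout gene, in the
#'   layout's gene order (names, if present, must match).
#' @param layout a `pixel_layout`.
#' @param sample_id,label optional metadata attached to the image.
#' @return A list of class `sample_image`: `pixels`
#'   (image_height x image_width matrix in \[0,1\]), `sample_id`, `label`.
#' @export
render_sample <- function(expression, layout, sample_id = NA_character_,
                          label = NA_character_) {
  stopifnot(inherits(layout, "pixel_layout"))
  if (length(expression) != length(layout$gene_ids))
    stop("alignment error: ", length(expression), " values for ",
         length(layout$gene_ids), " layout genes", call. = FALSE)
  if (!is.null(names(expression)) &&
      !identical(names(expression), layout$gene_ids))
    stop("alignment error: expression names do not match layout gene order",
         call. = FALSE)
  img <- matrix(0, layout$image_height, layout$image_width)
  key <- layout$pixel[, 1L] * layout$image_width + layout$pixel[, 2L]
  means <- rowsum(expression, key) / rowsum(rep(1, length(key)), key)
  at <- as.integer(rownames(means))
  # key = row * width + col; matrix is filled by (row, col) 0-based
  img[cbind(at %/% layout$image_width + 1L,
            at %% layout$image_width + 1L)] <- means[, 1L]
  structure(list(pixels = img, sample_id = sample_id, label = label),
            class = "sample_image")
}

#' Render every sample of an expression set through a fitted layout
#'
#' The layout is reused unchanged, so held-out samples are imaged through
#' the training-fitted transform.
#'
#' @param em an `expression_set` restricted to exactly the layout's genes
#'   (same order).
#' @param layout a `pixel_layout`.
#' @return A list of `sample_image` objects, one per sample.
#' @export
render_dataset <- function(em, layout) {
  stopifnot(inherits(em, "expression_set"), inherits(layout, "pixel_layout"))
  if (!identical(rownames(em$values), layout$gene_ids))
    stop("alignment error: expression gene set/order differs from layout",
         call. = FALSE)
  lapply(colnames(em$values), function(s)
    render_sample(unname(em$values[, s]), layout,
                  sample_id = s, label = as.character(em$labels[[s]])))
}

#' Stack rendered images into an array for the CNN
#'
#' @param images list of `sample_image` objects of equal shape.
#' @return A list with `x` (height x width x n array), `labels` (factor),
#'   `sample_ids`.
#' @export
image_stack <- function(images) {
  stopifnot(length(images) > 0L)
  h <- nrow(images[[1L]]$pixels); w <- ncol(images[[1L]]$pixels)
  x <- array(0, dim = c(h, w, length(images)))
  for (i in seq_along(images)) x[, , i] <- images[[i]]$pixels
  list(x = x,
       labels = factor(vapply(images, function(im) im$label, "")),
       sample_ids = vapply(images, function(im) im$sample_id, ""))
}

#' Serialize a pixel layout to JSON
#'
#' The JSON carries the resolution, per-gene pixel assignment and collision
#' groups, so a fitted transform can be stored and re-applied to new
#' samples. Serialization is canonical: rerunning an identical fit yields a
#' byte-identical file.
#'
#' @param layout a `pixel_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "pixel_layout"))
  obj <- list(image_width = layout$image_width,
              image_height = layout$image_height,
              gene_ids = layout$gene_ids,
              pixel_row = unname(layout$pixel[, 1L]),
              pixel_col = unname(layout$pixel[, 2L]),
              collision_groups = layout$collision_groups[
                order(names(layout$collision_groups))])
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a pixel layout from JSON
#'
#' @param path a file written by [write_layout_json()].
#' @return A `pixel_layout`.
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(image_width = as.integer(obj$image_width),
                 image_height = as.integer(obj$image_height),
                 gene_ids = obj$gene_ids,
                 pixel = cbind(row = as.integer(obj$pixel_row),
                               col = as.integer(obj$pixel_col)),
                 collision_groups = lapply(obj$collision_groups, as.character)),
            class = "pixel_layout")
}

#' Write a sample image as 8-bit grayscale PNG
#'
#' Pixel values in \[0,1\] are scaled to 0..255 and rounded.
#'
#' @param image a `sample_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "sample_image"))
  png::writePNG(round(image$pixels * 255) / 255, path)
  invisible(path)
}
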