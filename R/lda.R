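#' Embed genes in 2D by category-supervised linear discriminant analysis
#'
#' Treats each gene as an observation whose feature vector is its expression
#' across the training samples, and the Fisher-distance category as its
#' class label. Fits discriminant axes maximizing between-category scatter
#' against within-category scatter and returns each gene's projection onto
#' the top two axes (eigenvalue order), so genes in the same category land
#' in each other's immediate vicinity on the image plane.
#'
#' The within-class scatter is shrunk towards a trace-scaled identity,
#' Sw + gamma * (tr(Sw)/p) * I, which keeps the solve well-posed when the
#' feature dimension (number of training samples) rivals the number of
#' genes per category.
#'
#' @param em an `expression_set` restricted to the selected genes (training
#'   samples only).
#' @param categories a `category_assignment` for exactly those genes, with
#'   t >= 3 so that at least two discriminant axes exist.
#' @param gamma shrinkage weight for the within-class scatter (default 1e-3).
#' @return A data.frame of class `gene_coordinates` with columns `gene_id`,
#'   `x`, `y`.
#' @export
lda_project_genes <- function(em, categories, gamma = 1e-3) {
  stopifnot(inherits(em, "expression_set"),
            inherits(categories, "category_assignment"))
  t_cat <- attr(categories, "t")
  if (t_cat < 3L)
    stop("dimensionality error: need t >= 3 categories for a 2D embedding",
         call. = FALSE)
  if (!identical(rownames(em$values), categories$gene_id))
    stop("gene order mismatch between expression and categories", call. = FALSE)
  sz <- table(factor(categories$category, levels = seq_len(t_cat)))
  if (any(sz < 2L))
    stop("scatter-estimation error: categories with < 2 genes: ",
         paste(names(sz)[sz < 2L], collapse = ", "), call. = FALSE)

  Z <- em$values                      # genes (obs) x samples (features)
  p <- ncol(Z)
  grand <- colMeans(Z)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  for (cl in seq_len(t_cat)) {
    Zc <- Z[categories$category == cl, , drop = FALSE]
    mc <- colMeans(Zc)
    Zc_c <- sweep(Zc, 2L, mc)
    Sw <- Sw + crossprod(Zc_c)
    d <- mc - grand
    Sb <- Sb + nrow(Zc) * tcrossprod(d)
  }
  Sw_reg <- Sw + gamma * (sum(diag(Sw)) / p) * diag(p)

  # generalized eigenproblem Sb a = lambda Sw a via Cholesky whitening:
  # Sw = L L', solve symmetric L^-1 Sb L^-T, map back a = L^-T v
  R <- chol(Sw_reg)                   # upper: Sw = R'R, L = t(R)
  B <- forwardsolve(t(R), Sb)
  B <- t(forwardsolve(t(R), t(B)))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  axes <- backsolve(R, eig$vectors[, 1:2, drop = FALSE])

  coords <- sweep(Z, 2L, grand) %*% axes
  # sign convention: centroid of the top category sits in the first quadrant
  top <- colMeans(coords[categories$category == t_cat, , drop = FALSE])
  flip <- ifelse(top < 0, -1, 1)
  coords <- sweep(coords, 2L, flip, `*`)

  out <- data.frame(gene_id = categories$gene_id,
                    x = coords[, 1L], y = coords[, 2L],
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_coordinates", "data.frame")
  out
}
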