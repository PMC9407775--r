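#' Fisher distance between two classes of a single gene
#'
#' d = |mu1 - mu2| / (sigma1^2 + sigma2^2), with population (biased)
#' variances. When both variances vanish the denominator is floored at
#' 1e-12, so constant genes with differing class means get a huge but
#' finite score. Symmetric in its arguments.
#'
#' @param values_a,values_b numeric vectors of the gene's expression in the
#'   two classes, each of length >= 2.
#' @return Non-negative scalar distance.
#' @export
fisher_distance <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("insufficient-data error: each class needs >= 2 values",
         call. = FALSE)
  pop_var <- function(x) mean((x - mean(x))^2)
  denom <- pop_var(values_a) + pop_var(values_b)
  abs(mean(values_a) - mean(values_b)) / max(denom, 1e-12)
}

#' Multi-class Fisher distance: mean over unordered class pairs
#'
#' @param values_by_class named list of numeric vectors, one per class
#'   (>= 2 classes, each with >= 2 values).
#' @return The arithmetic mean of [fisher_distance()] over all class pairs.
#' @export
multiclass_fisher_distance <- function(values_by_class) {
  k <- length(values_by_class)
  if (k < 2L) stop("need at least 2 classes", call. = FALSE)
  pairs <- utils::combn(k, 2L)
  mean(apply(pairs, 2L, function(p)
    fisher_distance(values_by_class[[p[1L]]], values_by_class[[p[2L]]])))
}

#' Per-gene Fisher distances for an expression set
#'
#' With two classes this is the plain two-class distance; with three or more
#' it is the average of all pairwise distances (the multi-class rule), and
#' the per-pair scores are kept alongside.
#'
#' @param em an `expression_set`.
#' @return A data.frame of class `gene_scores` with columns `gene_id` and
#'   `distance`; for >= 3 classes, a `pairwise` attribute holds the per-pair
#'   distance matrix (genes x pairs).
#' @export
fisher_scores <- function(em) {
  stopifnot(inherits(em, "expression_set"))
  cls <- levels(em$labels)
  if (length(cls) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(table(em$labels) < 2L))
    stop("insufficient-data error: each class needs >= 2 samples",
         call. = FALSE)
  # vectorized per-class row means and population variances
  stats_for <- function(cl) {
    v <- em$values[, em$labels == cl, drop = FALSE]
    mu <- rowMeans(v)
    list(mu = mu, var = rowMeans(v * v) - mu * mu)
  }
  st <- lapply(stats::setNames(cls, cls), stats_for)
  pairs <- utils::combn(cls, 2L, simplify = FALSE)
  pw <- vapply(pairs, function(p) {
    denom <- pmax(st[[p[1L]]]$var + st[[p[2L]]]$var, 1e-12)
    abs(st[[p[1L]]]$mu - st[[p[2L]]]$mu) / denom
  }, numeric(nrow(em$values)))
  pw <- matrix(pw, nrow = nrow(em$values),
               dimnames = list(rownames(em$values),
                               vapply(pairs, paste, "", collapse = "|")))
  out <- data.frame(gene_id = rownames(em$values),
                    distance = rowMeans(pw),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gene_scores", "data.frame")
  if (length(cls) > 2L) attr(out, "pairwise") <- pw
  out
}

#' Bin genes into t equal-count categories by Fisher distance
#'
#' Genes are sorted by (distance ascending, original index ascending) and
#' cut into t consecutive blocks. When t does not divide the gene count, the
#' remainder r goes to the r highest categories, one extra gene each.
#' Category t holds the most discriminative genes.
#'
#' @param scores a `gene_scores` data.frame from [fisher_scores()].
#' @param t number of categories, 2 <= t <= number of genes.
#' @return A data.frame of class `category_assignment` with columns
#'   `gene_id`, `distance`, `category` (integer in 1..t), in the original
#'   gene order; attribute `t`.
#' @export
categorize_genes <- function(scores, t) {
  stopifnot(inherits(scores, "gene_scores"))
  m <- nrow(scores)
  t <- as.integer(t)
  if (t < 2L) stop("category-count error: t must be >= 2", call. = FALSE)
  if (t > m)
    stop("category-count error: t (", t, ") exceeds gene count (", m, ")",
         call. = FALSE)
  ord <- order(scores$distance, seq_len(m))   # stable tie-break by index
  sizes <- rep(m %/% t, t)
  r <- m %% t
  if (r > 0L) sizes[(t - r + 1L):t] <- sizes[(t - r + 1L):t] + 1L
  cat_sorted <- rep(seq_len(t), times = sizes)
  category <- integer(m)
  category[ord] <- cat_sorted
  out <- data.frame(gene_id = scores$gene_id, distance = scores$distance,
                    category = category, stringsAsFactors = FALSE)
  class(out) <- c("category_assignment", "data.frame")
  attr(out, "t") <- t
  out
}

#' Select genes by L1-penalized least-squares regression (LASSO)
#'
#' Fits a linear LASSO of the 0/1 class indicator on all genes at a single
#' penalty `lambda` (objective 1/(2n) * RSS + lambda * sum|beta|, with
#' intercept, no standardization -- the data are already min-max scaled) and
#' returns the genes whose coefficient is non-zero at the solver's
#' convergence tolerance.
#'
#' With three or more classes the selection is one-vs-rest: a LASSO per
#' class against the rest, and the union of the per-class selections.
#'
#' @param em a normalized `expression_set`.
#' @param lambda positive penalty; the default 6e-3 is the value used for
#'   the blood-transcriptome experiments this method was developed on.
#' @return A list of class `lasso_selection`: `lambda`, `coefficients`
#'   (named per-gene vector; for multi-class, a genes x classes matrix) and
#'   `selected_gene_ids` (in original gene order).
#' @export
lasso_select <- function(em, lambda = 6e-3) {
  stopifnot(inherits(em, "expression_set"))
  if (!em$normalized) stop("expression must be min-max normalized", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  cls <- levels(em$labels)
  if (length(cls) < 2L) stop("label error: need >= 2 classes", call. = FALSE)
  x <- t(em$values)                       # samples x genes
  fit_one <- function(y) {
    fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                          lambda = lambda, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-12)
    as.numeric(fit$beta[, 1L])
  }
  if (length(cls) == 2L) {
    beta <- fit_one(as.numeric(em$labels == cls[2L]))
    names(beta) <- rownames(em$values)
    sel <- rownames(em$values)[beta != 0]
  } else {
    beta <- vapply(cls, function(cl) fit_one(as.numeric(em$labels == cl)),
                   numeric(nrow(em$values)))
    rownames(beta) <- rownames(em$values)
    sel <- rownames(em$values)[rowSums(beta != 0) > 0]
  }
  if (!length(sel))
    stop("empty-selection error: no gene survives lambda = ", lambda,
         "; try a smaller lambda", call. = FALSE)
  structure(list(lambda = lambda, coefficients = beta,
                 selected_gene_ids = sel),
            class = "lasso_selection")
}

#' Pick the largest workable LASSO penalty for a category count
#'
#' The embedding needs at least two genes per category, so a selection must
#' contain >= 2t genes. Mirroring how the penalty is chosen in practice --
#' by the gene count it yields -- this walks a descending lambda grid and
#' returns the first (largest) value whose selection is big enough.
#'
#' @param em a normalized training `expression_set`.
#' @param t intended number of Fisher categories.
#' @param grid descending vector of candidate penalties.
#' @return The chosen lambda.
#' @export
choose_lambda <- function(em, t = 13L,
                          grid = c(6e-3, 5e-3, 4e-3, 3e-3, 2e-3, 1e-3)) {
  for (lam in sort(grid, decreasing = TRUE)) {
    n_sel <- tryCatch(length(lasso_select(em, lambda = lam)$selected_gene_ids),
                      error = function(e) 0L)
    if (n_sel >= 2L * t) return(lam)
  }
  stop("empty-selection error: no grid lambda yields ", 2L * t,
       " genes; extend the grid downwards", call. = FALSE)
}

#' Write gene scores / categories / selection as TSV
#'
#' @param x a `category_assignment` or `lasso_selection`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(x, path) {
  df <- if (inherits(x, "lasso_selection")) {
    co <- x$coefficients
    if (is.matrix(co)) co <- co[, 1L]
    data.frame(gene_id = names(co), coefficient = as.numeric(co))
  } else as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
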