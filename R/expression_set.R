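#' Labeled expression matrix
#'
#' An `expression_set` bundles a genes-by-samples numeric matrix with
#' per-sample class labels and a flag recording whether the values have been
#' min-max normalized to \[0, 1\]. Rows are genes (unique identifiers),
#' columns are samples (unique identifiers).
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   carry rownames (gene ids) and colnames (sample ids).
#' @param labels character or factor of per-sample class labels, either in
#'   column order or named by sample id.
#' @param normalized logical; `TRUE` asserts every value lies in \[0, 1\].
#' @return An object of class `expression_set` with fields `values`,
#'   `labels` (factor named by sample id) and `normalized`.
#' @export
expression_set <- function(values, labels, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("need at least 1 gene and 2 samples", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("identifier error: duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("identifier error: duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("parse error: non-finite or missing expression values", call. = FALSE)

  if (!is.null(names(labels))) {
    missing_lab <- setdiff(colnames(values), names(labels))
    if (length(missing_lab))
      stop("label-mismatch error: samples without a label: ",
           paste(missing_lab, collapse = ", "), call. = FALSE)
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values))
    stop("label-mismatch error: ", length(labels), " labels for ",
         ncol(values), " samples", call. = FALSE)
  labels <- factor(as.character(labels))
  names(labels) <- colnames(values)

  if (isTRUE(normalized) && (min(values) < 0 || max(values) > 1))
    stop("normalized = TRUE but values fall outside [0, 1]", call. = FALSE)

  structure(list(values = values, labels = labels,
                 normalized = isTRUE(normalized)),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "min-max normalized" else "raw"))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Subset an expression set by genes and/or samples
#'
#' @param em an `expression_set`.
#' @param genes gene ids or row indices to keep (default all).
#' @param samples sample ids or column indices to keep (default all).
#' @return A new `expression_set`.
#' @export
subset_expression <- function(em, genes = NULL, samples = NULL) {
  stopifnot(inherits(em, "expression_set"))
  v <- em$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_set(v, em$labels[colnames(v)], normalized = em$normalized)
}

#' Read an expression table and its label file
#'
#' Expression input is a delimited text table (TSV or CSV, sniffed from the
#' extension or the header) whose header row holds sample ids and whose first
#' column holds gene ids. The label file is a two-column table
#' (sample_id, label) with a header.
#'
#' @param path path to the expression table.
#' @param label_path path to the sample_id/label table.
#' @param transpose set `TRUE` when the table is samples-in-rows,
#'   genes-in-columns; it is transposed before validation.
#' @return An `expression_set` with `normalized = FALSE`; row and column
#'   order are preserved from the file.
#' @export
read_expression_table <- function(path, label_path, transpose = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L) stop("parse error: expected gene id column plus >= 2 samples",
                           call. = FALSE)
  gene_ids <- tab[[1L]]
  num <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error: non-numeric value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], colnames(num)[bad[2L]]), call. = FALSE)
  }
  rownames(num) <- gene_ids
  if (transpose) num <- t(num)

  lsep <-if (grepl("\\.csv$", label_path, ignore.case = TRUE)) "," else "\t"
  lab <- utils::read.table(label_path, header = TRUE, sep = lsep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(lab) < 2L) stop("parse error: label file needs (sample_id, label) columns",
                           call. = FALSE)
  if (anyDuplicated(lab[[1L]]))
    stop("identifier error: duplicate sample ids in label file", call. = FALSE)
  extra <- setdiff(lab[[1L]], colnames(num))
  if (length(extra))
    stop("label-mismatch error: labeled samples absent from table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  labels <- stats::setNames(lab[[2L]], lab[[1L]])
  expression_set(num, labels, normalized = FALSE)
}

#' Write an expression set back to the TSV dialect `read_expression_table` reads
#'
#' @param em an `expression_set`.
#' @param path output path for the expression table (TSV).
#' @param label_path optional output path for the (sample_id, label) TSV.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(em, path, label_path = NULL) {
  stopifnot(inherits(em, "expression_set"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(label_path)) {
    ldf <- data.frame(sample_id = names(em$labels),
                      label = as.character(em$labels))
    utils::write.table(ldf, label_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Min-max normalize each gene to \[0, 1\]
#'
#' Per gene g, v -> (v - min(g)) / (max(g) - min(g)). Constant genes
#' (max = min) map to all zeros: they carry no class information and zero
#' keeps them on the image background scale.
#'
#' @param em an `expression_set` with at least 2 samples.
#' @return The normalized `expression_set` (`normalized = TRUE`).
#' @export
minmax_normalize <- function(em) {
  stopifnot(inherits(em, "expression_set"))
  v <- em$values
  rmin <- apply(v, 1L, min)
  rmax <- apply(v, 1L, max)
  rng <- rmax - rmin
  out <- (v - rmin) / ifelse(rng > 0, rng, 1)
  out[rng == 0, ] <- 0
  expression_set(out, em$labels, normalized = TRUE)
}

#' Intersect gene sets and merge datasets, then re-normalize
#'
#' The merged gene set is the intersection of all inputs' gene sets, kept in
#' the gene order of the first dataset; samples are concatenated in input
#' order. After merging, each gene is min-max normalized again over the
#' combined samples, mirroring the normalize / integrate / normalize-again
#' scheme used when pooling cohorts measured on different platforms.
#'
#' @param datasets list of normalized `expression_set` objects sharing a
#'   label set.
#' @return A merged, re-normalized `expression_set`.
#' @export
intersect_and_merge <- function(datasets) {
  if (!length(datasets)) stop("need at least one dataset", call. = FALSE)
  stopifnot(all(vapply(datasets, inherits, logical(1), "expression_set")))
  if (!all(vapply(datasets, function(d) d$normalized, logical(1))))
    stop("all datasets must be min-max normalized before merging", call. = FALSE)
  genes <- rownames(datasets[[1L]]$values)
  for (d in datasets[-1L]) genes <- genes[genes %in% rownames(d$values)]
  if (!length(genes))
    stop("empty-intersection error: no genes shared by all datasets",
         call. = FALSE)
  all_samples <- unlist(lapply(datasets, function(d) colnames(d$values)))
  if (anyDuplicated(all_samples))
    stop("identifier error: duplicate sample ids across datasets: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  merged <- do.call(cbind, lapply(datasets, function(d)
    d$values[genes, , drop = FALSE]))
  labels <- unlist(lapply(datasets, function(d)
    stats::setNames(as.character(d$labels), names(d$labels))))
  minmax_normalize(expression_set(merged, labels, normalized = FALSE))
}

#' Stratified train/test split
#'
#' Per class, `round_half_up(test_fraction * class size)` samples (at least
#' one) are drawn without replacement into the test set; the split is
#' deterministic for a fixed seed and does not disturb the caller's RNG
#' state.
#'
#' @param em an `expression_set` where every class has >= 2 samples.
#' @param test_fraction fraction of each class assigned to the test set,
#'   in (0, 1).
#' @param seed integer seed controlling the draw.
#' @return A list with `expression_set` elements `train` and `test`.
#' @export
split_train_test <- function(em, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(em, "expression_set"),
            test_fraction > 0, test_fraction < 1)
  tab <- table(em$labels)
  if (any(tab < 2L))
    stop("insufficient-class error: classes with < 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  test_ids <- with_seed(seed, {
    unlist(lapply(levels(em$labels), function(cl) {
      ids <- names(em$labels)[em$labels == cl]
      k <- max(1L, round_half_up(test_fraction * length(ids)))
      sample(ids, k)
    }))
  })
  train_ids <- setdiff(names(em$labels), test_ids)
  list(train = subset_expression(em, samples = train_ids),
       test  = subset_expression(em, samples = test_ids))
}

# round-half-up, unlike base round()'s round-half-even
round_half_up <- function(x) floor(x + 0.5)

# evaluate `expr` under a fixed Mersenne-Twister seed, restoring RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}
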