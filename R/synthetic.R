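#' Specification for a synthetic labeled expression matrix
#'
#' Describes a min-max-scaled expression matrix in which a minority of
#' informative genes is mean-shifted between a disease class and a control
#' class, with an optional intermediate class sitting between them --
#' emulating the AD / MCI / CTL structure of blood transcriptome cohorts.
#'
#' Non-informative genes draw from N(0.5, noise_sd^2) identically in every
#' class. Informative genes keep that baseline in the control class, are
#' shifted by `+effect_size` in the disease class, and by
#' `+mci_mixing * effect_size` in the intermediate class when present.
#' Values are clipped to \[0, 1\].
#'
#' @param n_genes total number of genes.
#' @param n_informative number of mean-shifted genes (<= n_genes).
#' @param samples_per_class named integer vector, e.g.
#'   `c(CTL = 100, AD = 100)` or `c(CTL = 93, MCI = 63, AD = 96)`; every
#'   count must be >= 2. Recognized intermediate class name: `"MCI"`.
#' @param effect_size mean shift delta of informative genes in the disease
#'   class, in normalized expression units.
#' @param noise_sd within-class standard deviation sigma.
#' @param mci_mixing position of the intermediate class between control (0)
#'   and disease (1) means.
#' @param seed integer seed; generation is fully deterministic per seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 1000L, n_informative = 40L,
                           samples_per_class = c(CTL = 100L, AD = 100L),
                           effect_size = 0.15, noise_sd = 0.1,
                           mci_mixing = 0.7, seed = 1L) {
  if (n_informative > n_genes)
    stop("spec error: n_informative exceeds n_genes", call. = FALSE)
  if (is.null(names(samples_per_class)) || any(!nzchar(names(samples_per_class))))
    stop("spec error: samples_per_class must be named by class", call. = FALSE)
  if (any(samples_per_class < 2L))
    stop("spec error: every class needs >= 2 samples", call. = FALSE)
  if (noise_sd <= 0) stop("spec error: noise_sd must be positive", call. = FALSE)
  if (mci_mixing < 0 || mci_mixing > 1)
    stop("spec error: mci_mixing must lie in [0, 1]", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 samples_per_class = samples_per_class,
                 effect_size = effect_size, noise_sd = noise_sd,
                 mci_mixing = mci_mixing, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression matrix with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `em` (an `expression_set`, `normalized = TRUE`) and
#'   `informative` (character vector of the mean-shifted gene ids).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- names(spec$samples_per_class)
  n <- sum(spec$samples_per_class)
  m <- spec$n_genes
  # class-specific mean shift applied to informative genes only
  shift <- vapply(classes, function(cl) {
    switch(cl, AD = spec$effect_size,
           MCI = spec$mci_mixing * spec$effect_size, 0)
  }, numeric(1))

  vals <- with_seed(spec$seed, {
    base <- matrix(stats::rnorm(m * n, mean = 0.5, sd = spec$noise_sd), m, n)
    labels <- rep(classes, times = spec$samples_per_class)
    # informative genes scattered over the matrix, not stacked at the top
    inf_rows <- sort(sample.int(m, spec$n_informative))
    if (spec$n_informative > 0L)
      base[inf_rows, ] <- base[inf_rows, ] +
        matrix(shift[labels], nrow = spec$n_informative, ncol = n, byrow = TRUE)
    list(values = pmin(pmax(base, 0), 1), labels = labels, inf_rows = inf_rows)
  })

  gene_ids <- sprintf("G%05d", seq_len(m))
  sample_ids <- sprintf("S%04d", seq_len(n))
  v <- vals$values
  dimnames(v) <- list(gene_ids, sample_ids)
  em <- expression_set(v, stats::setNames(vals$labels, sample_ids),
                       normalized = TRUE)
  list(em = em, informative = gene_ids[vals$inf_rows])
}
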