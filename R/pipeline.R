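#' Pipeline configuration
#'
#' Defaults are the method's published operating point: LASSO penalty
#' 6e-3, 13 Fisher categories, 80/20 stratified split, Adam at 1e-4 with
#' batch size 32. The image resolution is freely adjustable; 64 x 64 is the
#' package default, while desk-scale runs (tests, examples) typically use
#' 16 x 16.
#'
#' Exactly one input source must be given: an in-memory `expression_set`
#' (`em`), a pair of file paths (`expression_path`, `label_path`), or a
#' [synthetic_spec()] (`synthetic`).
#'
#' @param em optional `expression_set`.
#' @param expression_path,label_path optional input table paths.
#' @param synthetic optional [synthetic_spec()].
#' @param lasso_lambda LASSO penalty (default 6e-3).
#' @param n_categories number of Fisher categories t >= 3 (default 13).
#' @param resolution integer `c(width, height)` pixels (default 64 x 64).
#' @param test_fraction held-out fraction per class, in (0, 1).
#' @param cnn a [cnn_config()].
#' @param output_dir optional directory; when set, runs write their
#'   artifacts (layout JSON, stacks, reports, manifest) there.
#' @param seed master seed for the split (and synthetic generation when no
#'   explicit spec seed is wanted).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(em = NULL, expression_path = NULL,
                            label_path = NULL, synthetic = NULL,
                            lasso_lambda = 6e-3, n_categories = 13L,
                            resolution = c(64L, 64L), test_fraction = 0.2,
                            cnn = cnn_config(), output_dir = NULL,
                            seed = 1L) {
  if (n_categories < 3L)
    stop("dimensionality error: n_categories must be >= 3 (2D embedding ",
         "needs at least two discriminant axes)", call. = FALSE)
  stopifnot(test_fraction > 0, test_fraction < 1,
            inherits(cnn, "cnn_config"))
  n_inputs <- sum(!is.null(em), !is.null(expression_path), !is.null(synthetic))
  if (n_inputs != 1L)
    stop("give exactly one of `em`, `expression_path` (+ `label_path`), ",
         "or `synthetic`", call. = FALSE)
  structure(list(em = em, expression_path = expression_path,
                 label_path = label_path, synthetic = synthetic,
                 lasso_lambda = lasso_lambda,
                 n_categories = as.integer(n_categories),
                 resolution = as.integer(resolution),
                 test_fraction = test_fraction, cnn = cnn,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_input <- function(config) {
  if (!is.null(config$em)) {
    em <- config$em
  } else if (!is.null(config$synthetic)) {
    em <- simulate_expression(config$synthetic)$em
  } else {
    em <- read_expression_table(config$expression_path, config$label_path)
  }
  if (!em$normalized) em <- minmax_normalize(em)
  em
}

#' Fit the full 1D-to-2D transform on training data
#'
#' Runs the image-formation stages in order on the training samples only:
#' LASSO gene selection at `lambda`, Fisher-distance scoring of the
#' selected genes (pairwise-averaged when more than two classes),
#' equal-count categorization into t bins, category-supervised LDA to the
#' plane, minimum-area enclosing rectangle, rotation to axis alignment, and
#' rasterization. The returned layout is then reused unchanged for any
#' sample, held-out ones included.
#'
#' @param train_em normalized training `expression_set`.
#' @param lambda LASSO penalty.
#' @param t number of Fisher categories (>= 3).
#' @param resolution integer `c(width, height)` pixels.
#' @return A list of class `fitted_transform`: `layout` (a `pixel_layout`),
#'   `selection`, `scores`, `categories`, `coordinates`, `rectangle`.
#' @export
fit_pixel_layout <- function(train_em, lambda = 6e-3, t = 13L,
                             resolution = c(64L, 64L)) {
  selection <- lasso_select(train_em, lambda = lambda)
  em_sel <- subset_expression(train_em, genes = selection$selected_gene_ids)
  scores <- fisher_scores(em_sel)
  categories <- categorize_genes(scores, t)
  coords <- lda_project_genes(em_sel, categories)
  rect <- minimum_enclosing_rectangle(coords)
  aligned <- rotate_to_axes(coords, rect)
  layout <- rasterize(aligned, resolution)
  structure(list(layout = layout, selection = selection, scores = scores,
                 categories = categories, coordinates = aligned,
                 rectangle = rect),
            class = "fitted_transform")
}

#' Transform expression data into train/test image stacks
#'
#' Splits the input (stratified, seeded), fits the image transform on the
#' training samples only, and renders both partitions through the fitted
#' layout. With `output_dir` set, writes `layout.json`, the two stacks
#' (`train_stack.rds`, `test_stack.rds`) and `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `transform_result`: `fit` (the
#'   `fitted_transform`), `train`, `test` (image stacks), `split_ids`.
#' @export
run_transform <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  em <- load_input(config)
  parts <- split_train_test(em, config$test_fraction, config$seed)
  fit <- fit_pixel_layout(parts$train, lambda = config$lasso_lambda,
                          t = config$n_categories,
                          resolution = config$resolution)
  genes <- fit$layout$gene_ids
  train_stack <- image_stack(render_dataset(
    subset_expression(parts$train, genes = genes), fit$layout))
  test_stack <- image_stack(render_dataset(
    subset_expression(parts$test, genes = genes), fit$layout))
  out <- structure(list(fit = fit, train = train_stack, test = test_stack,
                        split_ids = list(
                          train = colnames(parts$train$values),
                          test = colnames(parts$test$values))),
                   class = "transform_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_layout_json(fit$layout, file.path(config$output_dir, "layout.json"))
    saveRDS(train_stack, file.path(config$output_dir, "train_stack.rds"))
    saveRDS(test_stack, file.path(config$output_dir, "test_stack.rds"))
    write_manifest(config, out, file.path(config$output_dir, "manifest.json"))
  }
  out
}

write_manifest <- function(config, result, path) {
  cfg <- config[c("lasso_lambda", "n_categories", "resolution",
                  "test_fraction", "seed")]
  manifest <- list(
    package_version = as.character(utils::packageVersion("gene2image")),
    config = cfg,
    cnn = unclass(config$cnn),
    n_genes_selected = length(result$fit$selection$selected_gene_ids),
    train_samples = result$split_ids$train,
    test_samples = result$split_ids$test,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Transform, train the CNN, and evaluate on the held-out samples
#'
#' @param config a [pipeline_config()].
#' @param transform optional precomputed [run_transform()] result.
#' @return A list of class `classify_result`: `report` (an `eval_report`),
#'   `model`, `transform`.
#' @export
run_classify <- function(config, transform = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(transform)) transform <- run_transform(config)
  shape <- dim(transform$train$x)[1:2]
  model <- build_model(config$cnn, shape,
                       n_classes = nlevels(transform$train$labels))
  model <- train_model(model, transform$train)
  report <- evaluate_model(model, transform$test)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_eval_json(report, file.path(config$output_dir, "eval_report.json"))
    if (!is.null(report$roc_points))
      utils::write.csv(report$roc_points,
                       file.path(config$output_dir, "roc_points.csv"),
                       row.names = FALSE)
  }
  structure(list(report = report, model = model, transform = transform),
            class = "classify_result")
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(accuracy = report$accuracy, auc = report$auc,
              confusion = apply(report$confusion, 1L, as.list),
              per_class_counts = as.list(report$per_class_counts),
              roc_points = report$roc_points)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null", pretty = TRUE), path)
  invisible(path)
}

#' Repeat the pipeline over a grid of category counts
#'
#' All runs share one stratified split (and one seed), so rows differ only
#' in t. Larger t packs same-category genes more tightly in the image.
#'
#' @param config a [pipeline_config()].
#' @param t_values integer vector of category counts, each >= 3.
#' @return A data.frame with columns `t`, `accuracy`, `auc`,
#'   `n_genes_selected`; attribute `split_ids` records the shared split.
#' @export
sweep_categories <- function(config, t_values = c(7L, 9L, 11L, 13L, 15L, 17L)) {
  stopifnot(inherits(config, "pipeline_config"), all(t_values >= 3L))
  em <- load_input(config)
  parts <- split_train_test(em, config$test_fraction, config$seed)
  rows <- lapply(t_values, function(t) {
    fit <- fit_pixel_layout(parts$train, lambda = config$lasso_lambda,
                            t = as.integer(t), resolution = config$resolution)
    genes <- fit$layout$gene_ids
    tr <- image_stack(render_dataset(
      subset_expression(parts$train, genes = genes), fit$layout))
    te <- image_stack(render_dataset(
      subset_expression(parts$test, genes = genes), fit$layout))
    model <- build_model(config$cnn, dim(tr$x)[1:2],
                         n_classes = nlevels(tr$labels))
    model <- train_model(model, tr)
    rep <- evaluate_model(model, te)
    data.frame(t = as.integer(t), accuracy = rep$accuracy, auc = rep$auc,
               n_genes_selected = length(genes))
  })
  out <- do.call(rbind, rows)
  attr(out, "split_ids") <- list(train = colnames(parts$train$values),
                                 test = colnames(parts$test$values))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(config$output_dir, "sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
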