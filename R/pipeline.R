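#' Run the full feature-comparison experiment
#'
#' End-to-end benchmark: filter the input sequences, extract features with
#' each requested method (one shared measurement matrix per experiment for
#' `"cs"`), cluster the features with fuzzy c-means using as many clusters
#' as there are distinct true labels, and score each feature set with the
#' three validity indices (label-matched accuracy, partition entropy,
#' scatter-trace ratio on the true labels).
#'
#' @param records A tibble with columns `id` and `sequence`, optionally
#'   `label`.
#' @param labels True class labels: `NULL` to use `records$label`, a
#'   vector aligned with `records`, or a tibble with columns `id`, `label`
#'   joined by id.
#' @param methods Feature methods to compare, a subset of
#'   `c("cs", "aac")`.
#' @param m Compressed dimension for the `"cs"` method.
#' @param matrix_seed Seed of the Gaussian measurement matrix.
#' @param fcm_seed Seed of the fuzzy c-means initialization.
#' @param clusters Number of clusters; defaults to the number of distinct
#'   labels.
#' @param fuzzifier,tol,max_iter Fuzzy c-means settings (see [fcm()]).
#' @param scatter_on Labels used for the scatter traces, `"true"` or
#'   `"predicted"`.
#' @return A tibble of class `cs_experiment` with one row per method and
#'   columns `method`, `n`, `dim`, `accuracy`, `etp`, `tr_sw`, `tr_sb`,
#'   `ratio`. Attributes: `fits` (named list of `fcm_fit`s), `features`
#'   (named list of feature tibbles), `filter_report`, and `metadata`
#'   (seeds, PRNG, settings, package version) sufficient to reproduce the
#'   run.
#' @examples
#' models <- make_class_models(2, separation = 0.8, seed = 1,
#'                             min_len = 40, max_len = 60)
#' ds <- simulate_dataset(models, n_per_class = 10, seed = 2)
#' run_experiment(ds, m = 5)
#' @export
run_experiment <- function(records, labels = NULL, methods = c("cs", "aac"),
                           m = 5L, matrix_seed = 1L, fcm_seed = 1L,
                           clusters = NULL, fuzzifier = 2, tol = 1e-5,
                           max_iter = 300L,
                           scatter_on = c("true", "predicted")) {
  check_records(records)
  scatter_on <- match.arg(scatter_on)
  methods <- match.arg(methods, several.ok = TRUE)

  if (is.null(labels)) {
    if (!"label" %in% names(records)) {
      abort("No `labels` given and `records` has no 'label' column.",
            class = "trisense_config_error")
    }
  } else if (is.data.frame(labels)) {
    if (!all(c("id", "label") %in% names(labels))) {
      abort("`labels` data frame must have columns 'id' and 'label'.",
            class = "trisense_config_error")
    }
    records$label <- labels$label[match(records$id, labels$id)]
    if (anyNA(records$label)) {
      abort("Some record ids have no label.", class = "trisense_config_error")
    }
  } else {
    if (length(labels) != nrow(records)) {
      abort("`labels` must have one entry per record.", class = "trisense_config_error")
    }
    records$label <- labels
  }

  kept <- filter_valid(records)
  report <- filter_report(kept)
  kept <- kept[kept$length >= 3L, , drop = FALSE]
  if (nrow(kept) == 0L) {
    abort("No valid sequences left after filtering.", class = "trisense_empty_dataset")
  }
  truth <- factor(kept$label)
  C <- clusters %||% nlevels(truth)

  fits <- list()
  feats <- list()
  rows <- lapply(methods, function(meth) {
    fm <- extract_features(kept, method = meth, m = m, seed = matrix_seed)
    fit <- fcm(fm, clusters = C, fuzzifier = fuzzifier, tol = tol,
               max_iter = max_iter, seed = fcm_seed)
    fits[[meth]] <<- fit
    feats[[meth]] <<- fm
    ev <- evaluate_features(fm, fit, truth, scatter_on = scatter_on)
    dplyr::bind_cols(
      tibble(method = meth, n = nrow(fm), dim = attr(fm, "feature_dim")),
      ev
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  attr(out, "features") <- feats
  attr(out, "filter_report") <- report
  attr(out, "metadata") <- list(
    package_version = as.character(utils::packageVersion("trisense")),
    prng = "Mersenne-Twister/Inversion",
    matrix_seed = matrix_seed,
    fcm_seed = fcm_seed,
    m = m,
    clusters = C,
    fuzzifier = fuzzifier,
    tol = tol,
    max_iter = max_iter,
    scatter_on = scatter_on
  )
  class(out) <- c("cs_experiment", class(out))
  out
}

#' Fuzzy c-means fits of an experiment
#'
#' @param experiment A `cs_experiment` from [run_experiment()].
#' @return A named list of `fcm_fit` objects, one per method.
#' @export
experiment_fits <- function(experiment) {
  attr(experiment, "fits", exact = TRUE)
}

#' Run metadata of an experiment
#'
#' @param experiment A `cs_experiment` from [run_experiment()].
#' @return A list with the seeds, PRNG, clustering settings and package
#'   version that reproduce the run.
#' @export
experiment_metadata <- function(experiment) {
  attr(experiment, "metadata", exact = TRUE)
}

#' Accuracy sweep over the compressed dimension
#'
#' Re-runs the compressive pipeline at several feature dimensions on one
#' dataset, using leading-row prefixes of a single master measurement
#' matrix (see [prefix_measurement_matrix()]) so all dimensions share one
#' random draw — a paired design that isolates the effect of the dimension
#' itself.
#'
#' @param records A tibble with columns `id`, `sequence` and `label` (or
#'   pass `labels`).
#' @param dims Integer vector of compressed dimensions to test.
#' @param labels Optional labels as in [run_experiment()].
#' @param matrix_seed Seed of the master measurement matrix (drawn at
#'   `max(dims)` rows).
#' @param fcm_seed Seed of the fuzzy c-means initialization.
#' @param ... Further arguments passed to [fcm()].
#' @return A tibble with columns `m` and `accuracy`.
#' @export
dimension_sweep <- function(records, dims = c(5L, 10L, 15L, 20L, 30L, 50L),
                            labels = NULL, matrix_seed = 1L, fcm_seed = 1L,
                            ...) {
  check_records(records)
  if (!is.null(labels)) records$label <- labels
  if (!"label" %in% names(records)) {
    abort("Labels are required for the accuracy sweep.",
          class = "trisense_config_error")
  }
  kept <- filter_valid(records)
  kept <- kept[kept$length >= 3L, , drop = FALSE]
  truth <- factor(kept$label)
  master <- make_measurement_matrix(max(dims), seed = matrix_seed)
  acc <- vapply(dims, function(m) {
    phi <- prefix_measurement_matrix(master, m)
    feats <- extract_features(kept, method = "cs", phi = phi)
    fit <- fcm(feats, clusters = nlevels(truth), seed = fcm_seed, ...)
    clustering_accuracy(fit, truth)$accuracy
  }, numeric(1))
  tibble(m = as.integer(dims), accuracy = acc)
}
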