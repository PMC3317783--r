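# End-to-end orchestration: simulate (or load) -> preprocess -> discretize ->
# select -> (optionally meta-features) -> evaluate, from a single config list,
# with reproducible seeds and a manifest of what ran.

#' Build and validate a pipeline run configuration
#'
#' @param comparison character(2), the two diagnostic classes to compare
#'   (must be distinct).
#' @param scale `"log10"` or `"raw"` analysis scale.
#' @param mode `"single"`, `"metafeature_diff"` or `"metafeature_sum"`.
#' @param exclude analyte ids excluded before selection (e.g. an APOE
#'   analyte).
#' @param protocol evaluation protocol: `"cv10"`, `"split"` or `"none"`.
#' @param size_matched evaluate on size-matched groups (default TRUE).
#' @param top_m top-m restriction for meta-feature modes.
#' @param synth a [synth_config()] used to simulate the input panel, or NULL
#'   to supply `panel` directly to [run_pipeline()].
#' @param seed master seed for evaluation and matching.
#' @return a validated `run_config` list.
#' @export
run_config <- function(comparison = c("Control", "MCI_Progressor"),
                       scale = c("log10", "raw"),
                       mode = c("single", "metafeature_diff", "metafeature_sum"),
                       exclude = character(0),
                       protocol = c("cv10", "split", "none"),
                       size_matched = TRUE,
                       top_m = 100,
                       synth = synth_config(),
                       seed = 1L) {
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  protocol <- match.arg(protocol)
  if (length(comparison) != 2 || comparison[1] == comparison[2])
    stop("comparison must name two distinct classes")
  structure(list(comparison = comparison, scale = scale, mode = mode,
                 exclude = exclude, protocol = protocol,
                 size_matched = size_matched, top_m = top_m, synth = synth,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full signature-discovery pipeline
#'
#' Sequence: obtain panel (simulate from `config$synth` unless `panel` is
#' given) -> LDD floor -> detectability filter -> log transform (unless raw
#' scale) -> restrict to the comparison classes -> discretize/select
#' (single analytes or meta-features, honouring the exclusion list) ->
#' evaluate the signature under the configured protocol. Fully reproducible:
#' config and seeds determine all outputs.
#'
#' @param config a [run_config()].
#' @param panel optional pre-built raw-scale [analyte_panel()] (overrides
#'   simulation).
#' @return a `run_report`: list with `signature`, `report` (classification
#'   report or NULL), `ranking`, `removed_analytes`, `pruned_samples`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, panel = NULL) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (is.null(panel)) {
    sim <- generate_panel(config$synth)
    panel <- sim$panel
    truth <- sim$truth
  }
  missing_cls <- setdiff(config$comparison, unique(panel$sample_meta$class))
  if (length(missing_cls))
    stop("comparison class absent from panel: ", paste(missing_cls, collapse = ", "))

  panel <- apply_ldd_floor(panel)
  fd <- filter_detectability(panel)
  panel <- fd$panel
  if (config$scale == "log10") panel <- log_transform(panel)

  cls <- panel_classes(panel)
  two <- subset_panel(panel, samples = names(cls)[cls %in% config$comparison])
  labels <- panel_classes(two)

  exclude <- intersect(config$exclude, colnames(two$values))
  ranking <- NULL
  if (config$mode == "single") {
    ana <- setdiff(colnames(two$values), exclude)
    disc <- withCallingHandlers(
      entropy_filter(subset_panel(two, analytes = ana)),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!disc$empty) ranking <- rank_univariate(disc)
  } else {
    op <- if (config$mode == "metafeature_diff") "difference" else "sum"
    z <- zscore(two)
    mf <- make_metafeatures(z, op, exclude = exclude)
    top <- top_m_by_univariate(mf, labels, m = config$top_m)
    disc <- top$disc
    ranking <- top$ranking
  }

  pruned <- character(0)
  if (disc$empty) {
    signature <- NULL
  } else {
    pr <- prune_duplicate_patterns(disc)
    pruned <- pr$pruned
    signature <- solve_min_k(pr$instance)
  }

  report <- NULL
  if (!is.null(signature) && signature$status != "infeasible" &&
      config$protocol != "none") {
    feats <- signature$features
    x <- if (config$mode == "single") two$values[, feats, drop = FALSE]
         else {
           mf_top <- mf$values[, feats, drop = FALSE]
           mf_top
         }
    ids <- rownames(x)
    if (config$size_matched) {
      ids <- size_match(two, seed = config$seed)
      x <- x[ids, , drop = FALSE]
    }
    y <- factor(labels[ids], levels = config$comparison)
    if (config$protocol == "cv10") {
      report <- crossvalidate(x, y, seed = config$seed)
    } else {
      sp <- split_train_test_matched(
        subset_panel(two, samples = ids), seed = config$seed)
      report <- evaluate_train_test(x[sp$train, , drop = FALSE], y[match(sp$train, ids)],
                                    x[sp$test, , drop = FALSE], y[match(sp$test, ids)],
                                    seed = config$seed)
    }
  }

  manifest <- list(
    comparison = config$comparison, scale = config$scale, mode = config$mode,
    exclude = exclude, protocol = config$protocol,
    size_matched = config$size_matched,
    n_samples = nrow(two$values), n_analytes = ncol(two$values),
    removed_analytes = fd$removed, pruned_samples = pruned,
    seed = config$seed,
    synth_seed = if (!is.null(config$synth)) config$synth$seed else NA)

  structure(list(signature = signature, report = report, ranking = ranking,
                 removed_analytes = fd$removed, pruned_samples = pruned,
                 truth = truth, manifest = manifest),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", paste(x$manifest$comparison, collapse = " vs "),
      "| mode", x$manifest$mode, "\n")
  if (!is.null(x$signature)) print(x$signature) else cat(" no signature (entropy filter empty)\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Write a run report (signature + evaluation + manifest) as JSON
#' @param report a `run_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- list(
    manifest = report$manifest,
    signature = if (!is.null(report$signature)) unclass(report$signature),
    evaluation = if (!is.null(report$report))
      list(protocol = report$report$protocol,
           sensitivity = report$report$sensitivity,
           specificity = report$report$specificity,
           mcc = report$report$mcc,
           per_classifier = report$report$per_classifier))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
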