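# Longitudinal change signatures: per-sample change between baseline and the
# 12-month follow-up, a control-stability filter that drops analytes drifting
# in healthy controls, and the composed change -> entropy filter -> feature
# set pipeline.

#' Per-sample change between baseline and follow-up
#'
#' On the log10 scale the change is `12m - baseline`; on the raw scale it is
#' `12m / baseline` (so the two are related by exact exponentiation). Samples
#' missing at either timepoint are dropped and reported.
#'
#' @param baseline,followup [analyte_panel()]s sharing the analyte set and
#'   both on the scale named by `scale`.
#' @param scale `"log10"` or `"raw"`.
#' @return a `change_panel`: list with `values` (samples x analytes change
#'   matrix), `scale`, `classes`, `dropped` (ids present at only one
#'   timepoint).
#' @export
compute_change <- function(baseline, followup, scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(baseline, "analyte_panel"), inherits(followup, "analyte_panel"))
  if (baseline$scale != scale || followup$scale != scale)
    stop("both panels must be on the '", scale, "' scale")
  if (!setequal(colnames(baseline$values), colnames(followup$values)))
    stop("panels differ in analytes: ",
         paste(union(setdiff(colnames(baseline$values), colnames(followup$values)),
                     setdiff(colnames(followup$values), colnames(baseline$values))),
               collapse = ", "))
  common <- intersect(rownames(baseline$values), rownames(followup$values))
  if (length(common) == 0) stop("no sample present at both timepoints")
  dropped <- union(setdiff(rownames(baseline$values), common),
                   setdiff(rownames(followup$values), common))
  an <- colnames(baseline$values)
  b <- baseline$values[common, an, drop = FALSE]
  f <- followup$values[common, an, drop = FALSE]
  vals <- if (scale == "log10") f - b else f / b
  structure(list(values = vals, scale = scale,
                 classes = panel_classes(baseline)[common],
                 dropped = dropped),
            class = "change_panel")
}

#' @export
print.change_panel <- function(x, ...) {
  cat("change_panel:", nrow(x$values), "samples x", ncol(x$values),
      "analytes (", x$scale, "scale )\n")
  invisible(x)
}

#' Control-stability filter on longitudinal changes
#'
#' Excludes any analyte whose average change in the control group exceeds the
#' threshold: the per-analyte statistic is the geometric mean fold change over
#' controls (for log10 changes, `10^mean(change)`), and an analyte is excluded
#' iff `|fold - 1| > threshold`. The statistic is returned for every analyte
#' so alternative rules can be audited.
#'
#' @param change a `change_panel`.
#' @param control_ids sample ids of the control group (non-empty subset of the
#'   change samples).
#' @param threshold maximum tolerated |fold change - 1| (default 0.20).
#' @return list with `retained`, `excluded` (analyte id vectors) and `stats`
#'   (data.frame: analyte, control_fold_change, excluded).
#' @export
stability_filter <- function(change, control_ids, threshold = 0.20) {
  stopifnot(inherits(change, "change_panel"))
  control_ids <- intersect(control_ids, rownames(change$values))
  if (length(control_ids) == 0) stop("no control samples in the change panel")
  cc <- change$values[control_ids, , drop = FALSE]
  fold <- if (change$scale == "log10") 10^colMeans(cc)
          else 10^colMeans(log10(cc))     # geometric mean ratio either way
  excl <- abs(fold - 1) > threshold
  list(retained = colnames(cc)[!excl],
       excluded = colnames(cc)[excl],
       stats = data.frame(analyte = colnames(cc), control_fold_change = fold,
                          excluded = excl, row.names = NULL))
}

#' Longitudinal change signature
#'
#' Composes the change pipeline: restrict to stability-filtered analytes,
#' entropy-filter the change matrix for a two-class comparison, build the
#' feature-set instance (pruning duplicate patterns if needed) and solve for
#' the minimum-k signature. In `metafeature_diff` mode, difference
#' meta-features are built from Z-scored changes before filtering.
#'
#' @param change a `change_panel` (already stability-filtered via
#'   `retained`, or pass `retain` here).
#' @param labels two-class labels (defaults to the panel classes, which must
#'   then be exactly two).
#' @param mode `"single"` (analyte changes) or `"metafeature_diff"`
#'   (differences of Z-scored changes).
#' @param retain optional analyte ids to restrict to (e.g. the `retained`
#'   list from [stability_filter()]).
#' @param top_m top-m restriction for meta-feature mode (default 100).
#' @return list with `signature` (an `absig_signature`, or NULL when nothing
#'   passes the entropy filter), `disc`, `pruned`.
#' @export
longitudinal_signature <- function(change, labels = NULL,
                                   mode = c("single", "metafeature_diff"),
                                   retain = NULL, top_m = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(change, "change_panel"))
  if (is.null(labels)) labels <- change$classes
  if (length(unique(labels)) != 2) stop("two-class labels required")
  vals <- change$values
  if (!is.null(retain)) vals <- vals[, retain, drop = FALSE]
  if (mode == "metafeature_diff") {
    mu <- colMeans(vals); sd_ <- apply(vals, 2, stats::sd)
    if (any(sd_ == 0)) {
      vals <- vals[, sd_ > 0, drop = FALSE]
      mu <- mu[sd_ > 0]; sd_ <- sd_[sd_ > 0]
    }
    z <- structure(list(zvalues = scale(vals, mu, sd_),
                        reference = rownames(vals), classes = labels),
                   class = "zpanel")
    mf <- make_metafeatures(z, "difference")
    top <- top_m_by_univariate(mf, labels, m = top_m)
    if (top$empty) return(list(signature = NULL, disc = top$disc, pruned = character(0)))
    disc <- top$disc
  } else {
    disc <- withCallingHandlers(entropy_filter(vals, labels),
                                warning = function(w) invokeRestart("muffleWarning"))
    if (disc$empty) return(list(signature = NULL, disc = disc, pruned = character(0)))
  }
  pr <- prune_duplicate_patterns(disc)
  sig <- solve_min_k(pr$instance)
  list(signature = sig, disc = disc, pruned = pr$pruned)
}
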