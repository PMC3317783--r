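#' Floor readings below half the least detectable dose
#'
#' Multiplex immunoassay readings below the assay's reliable range are noise;
#' every reading below LDD/2 is replaced by LDD/2 for its analyte. Readings
#' already at or above LDD/2 are untouched. The per-analyte count of floored
#' readings is recorded in `attr(panel, "floored")`.
#'
#' @param panel a raw-scale [analyte_panel()].
#' @return the panel with floored values; idempotent.
#' @export
apply_ldd_floor <- function(panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (panel$scale != "raw") stop("LDD flooring applies to raw-scale panels")
  half <- panel$analyte_meta$ldd / 2
  v <- panel$values
  floored <- integer(ncol(v))
  for (j in seq_len(ncol(v))) {
    below <- v[, j] < half[j]
    floored[j] <- sum(below)
    v[below, j] <- half[j]
  }
  out <- panel
  out$values <- v
  attr(out, "floored") <- stats::setNames(floored, colnames(v))
  out
}

#' Remove analytes undetectable in too many samples
#'
#' An analyte is removed when strictly more than `max_fraction` of its readings
#' fall strictly below its LDD (readings exactly at the LDD count as detected).
#' Retained analytes keep their original order.
#'
#' @param panel a raw-scale [analyte_panel()] (apply before log transform).
#' @param max_fraction maximum tolerated fraction of sub-LDD readings
#'   (default 0.10).
#' @return list with `panel` (filtered) and `removed` (character vector of
#'   removed analyte ids, possibly empty).
#' @export
filter_detectability <- function(panel, max_fraction = 0.10) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (panel$scale != "raw") stop("detectability filtering applies before log transform")
  if (nrow(panel$values) == 0L || ncol(panel$values) == 0L) stop("empty panel")
  frac <- colMeans(sweep(panel$values, 2, panel$analyte_meta$ldd, `<`))
  drop <- frac > max_fraction
  removed <- colnames(panel$values)[drop]
  if (all(drop)) stop("detectability filter removed every analyte")
  out <- if (any(drop)) subset_panel(panel, analytes = which(!drop)) else panel
  list(panel = out, removed = removed, sub_ldd_fraction = frac)
}

#' Log10-transform a panel
#'
#' @param panel a raw-scale [analyte_panel()] with strictly positive values
#'   (guaranteed after [apply_ldd_floor()]).
#' @return the panel on the log10 scale (`scale == "log10"`).
#' @export
log_transform <- function(panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (panel$scale == "log10") stop("panel is already log10-transformed")
  bad <- which(panel$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive value at sample ", rownames(panel$values)[bad[1, 1]],
         ", analyte ", colnames(panel$values)[bad[1, 2]])
  panel$values <- log10(panel$values)
  panel$scale <- "log10"
  panel
}

#' Invert [log_transform()]
#' @param panel a log10-scale [analyte_panel()].
#' @return the panel back on the raw scale.
#' @export
unlog_transform <- function(panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (panel$scale != "log10") stop("panel is not on the log10 scale")
  panel$values <- 10^panel$values
  panel$scale <- "raw"
  panel
}

#' Z-score a panel against a reference population
#'
#' Each analyte is centred and scaled by the mean and sample (n-1) standard
#' deviation computed over the reference samples; the transform is then applied
#' to all selected samples. The reference population is recorded in the result
#' so downstream meta-feature analyses can report their provenance.
#'
#' @param panel a log10-scale [analyte_panel()].
#' @param reference character vector of sample ids to centre/scale on
#'   (default: all samples in the panel).
#' @param samples samples to transform (default: all).
#' @return a `zpanel`: list with `zvalues` (matrix), `reference` (ids),
#'   `classes` (labels of transformed samples).
#' @export
zscore <- function(panel, reference = NULL, samples = NULL) {
  stopifnot(inherits(panel, "analyte_panel"))
  if (panel$scale != "log10") stop("zscore expects a log10-scale panel")
  all_ids <- rownames(panel$values)
  if (is.null(reference)) reference <- all_ids
  if (is.null(samples)) samples <- all_ids
  if (length(reference) < 2) stop("reference must select at least 2 samples")
  ref <- panel$values[reference, , drop = FALSE]
  mu <- colMeans(ref)
  sd_ <- apply(ref, 2, stats::sd)
  if (any(sd_ == 0))
    stop("constant analyte in reference: ",
         paste(colnames(ref)[sd_ == 0], collapse = ", "))
  z <- sweep(sweep(panel$values[samples, , drop = FALSE], 2, mu), 2, sd_, `/`)
  structure(list(zvalues = z, reference = reference,
                 classes = panel_classes(panel)[samples]),
            class = "zpanel")
}

#' @export
print.zpanel <- function(x, ...) {
  cat("zpanel:", nrow(x$zvalues), "samples x", ncol(x$zvalues),
      "analytes; reference n =", length(x$reference), "\n")
  invisible(x)
}
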