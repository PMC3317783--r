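# Analyte-pair meta-features: differences and sums of per-analyte Z-scores.
# On log10-scale data a Z-score difference is equivalent to the (scaled)
# log-ratio of the two analytes' relative abundances, and a sum to their
# log-product.

#' Build pairwise meta-features from a Z-scored panel
#'
#' Generates all `choose(n, 2)` analyte pairs in deterministic (i < j by panel
#' column order) order. `difference` meta-features are `z_i - z_j`; `sum`
#' meta-features are `z_i + z_j`.
#'
#' @param z a `zpanel` from [zscore()] with >= 2 analytes.
#' @param op `"difference"` or `"sum"`.
#' @param exclude analyte ids removed before pairing (e.g. an APOE analyte);
#'   every pair containing an excluded analyte is dropped.
#' @return a `metafeature_panel`: list with `values` (samples x meta-features),
#'   `defs` (data.frame: id, analyte_i, analyte_j, op), `classes`, `op`.
#' @export
make_metafeatures <- function(z, op = c("difference", "sum"), exclude = NULL) {
  stopifnot(inherits(z, "zpanel"))
  op <- match.arg(op)
  zm <- z$zvalues
  if (!is.null(exclude)) zm <- zm[, !colnames(zm) %in% exclude, drop = FALSE]
  p <- ncol(zm)
  if (p < 2) stop("need at least 2 analytes to form pairs")
  idx <- utils::combn(p, 2)
  i <- idx[1, ]; j <- idx[2, ]
  vals <- if (op == "difference") zm[, i, drop = FALSE] - zm[, j, drop = FALSE]
          else zm[, i, drop = FALSE] + zm[, j, drop = FALSE]
  sep <- if (op == "difference") "-" else "+"
  ids <- paste(colnames(zm)[i], colnames(zm)[j], sep = sep)
  colnames(vals) <- ids
  structure(list(values = vals,
                 defs = data.frame(id = ids, analyte_i = colnames(zm)[i],
                                   analyte_j = colnames(zm)[j], op = op,
                                   stringsAsFactors = FALSE),
                 classes = z$classes, op = op),
            class = "metafeature_panel")
}

#' @export
print.metafeature_panel <- function(x, ...) {
  cat("metafeature_panel:", nrow(x$values), "samples x", ncol(x$values),
      "pairs (", x$op, ")\n")
  invisible(x)
}

#' Keep the top-m meta-features by univariate MCC
#'
#' Entropy-filters the meta-features, ranks the accepted ones univariately by
#' MCC ([rank_univariate()]) and restricts the panel to the `m` best (fewer if
#' fewer were accepted). Restricting to a top list keeps the downstream
#' feature-set instance tractable. Ties are broken by pair definition order.
#'
#' @param mf a `metafeature_panel`.
#' @param labels two-class labels (defaults to the panel's stored classes).
#' @param m number of meta-features to retain (default 100).
#' @return list with `panel` (restricted `metafeature_panel`), `ranking`
#'   (the full ranking table), `disc` (the discretized top-m panel ready for
#'   [build_instance()]); when nothing passes the filter, `panel` is empty and
#'   `empty = TRUE`.
#' @export
top_m_by_univariate <- function(mf, labels = NULL, m = 100) {
  stopifnot(inherits(mf, "metafeature_panel"))
  if (is.null(labels)) labels <- mf$classes
  disc <- withCallingHandlers(
    entropy_filter(mf$values, labels),
    warning = function(w) invokeRestart("muffleWarning"))
  if (disc$empty) {
    warning("no meta-feature passed the entropy filter")
    return(list(panel = NULL, ranking = NULL, disc = disc, empty = TRUE))
  }
  rk <- rank_univariate(disc)
  # deterministic tie-break: MCC desc, then pair definition order
  ord <- order(-rk$mcc, match(rk$feature, mf$defs$id))
  keep <- rk$feature[ord][seq_len(min(m, nrow(rk)))]
  out <- mf
  out$values <- mf$values[, keep, drop = FALSE]
  out$defs <- mf$defs[match(keep, mf$defs$id), , drop = FALSE]
  disc_top <- disc
  disc_top$binary <- disc$binary[, keep, drop = FALSE]
  disc_top$cuts <- disc$cuts[match(keep, disc$cuts$feature), , drop = FALSE]
  list(panel = out, ranking = rk, disc = disc_top, empty = FALSE)
}
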