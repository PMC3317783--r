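# Single-cut supervised discretization: for each feature find the threshold
# with minimal weighted class-information entropy, then accept the feature only
# if its information gain exceeds a minimum-description-length criterion.
# Entropies are in bits throughout.

entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Best single cut by class-information entropy
#'
#' Scans every midpoint between consecutive distinct sorted values and returns
#' the cut minimizing the weighted class-information entropy
#' `E(T;S) = |S1|/|S| H(S1) + |S2|/|S| H(S2)`, where `S1`/`S2` are the samples
#' below/above the cut. Ties are broken towards the smallest midpoint, so the
#' result is deterministic and invariant to sample order.
#'
#' @param values numeric vector (>= 2 distinct values).
#' @param labels two-class label vector aligned with `values`.
#' @return list with `cut`, `entropy` (bits, the minimized E(T;S)),
#'   `left_counts` and `right_counts` (class counts on each side).
#' @export
best_cut <- function(values, labels) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (length(unique(values)) < 2) stop("all values identical: no cut exists")
  labels <- factor(labels)
  o <- order(values)
  v <- values[o]
  y <- as.integer(labels[o])   # 1 or 2
  n <- length(v)
  # cumulative class-1 counts after each sorted position
  c1 <- cumsum(y == 1L)
  c2 <- cumsum(y == 2L)
  # candidate boundaries: positions where the next value is distinct
  pos <- which(v[-n] < v[-1])
  nl <- pos
  l1 <- c1[pos]; l2 <- c2[pos]
  r1 <- c1[n] - l1; r2 <- c2[n] - l2
  h <- function(a, b) {
    tot <- a + b
    out <- numeric(length(a))
    nz <- a > 0 & b > 0
    pa <- a[nz] / tot[nz]; pb <- b[nz] / tot[nz]
    out[nz] <- -(pa * log2(pa) + pb * log2(pb))
    out
  }
  E <- (nl / n) * h(l1, l2) + ((n - nl) / n) * h(r1, r2)
  best <- which.min(E)  # which.min returns the first (smallest midpoint) on ties
  list(cut = (v[pos[best]] + v[pos[best] + 1]) / 2,
       entropy = E[best],
       left_counts = stats::setNames(c(l1[best], l2[best]), levels(labels)),
       right_counts = stats::setNames(c(r1[best], r2[best]), levels(labels)))
}

#' Minimum-description-length acceptance of a cut
#'
#' Computes the information gain of the cut, `gain = H(S) - E(T;S)`, and the
#' MDL criterion `(log2(N-1) + delta)/N` with
#' `delta = log2(3^c - 2) - (c H(S) - c1 H(S1) - c2 H(S2))`, where `c`, `c1`,
#' `c2` count the classes present in the full set and in each side. The cut is
#' accepted iff `gain > criterion`.
#'
#' @param values,labels as in [best_cut()].
#' @param cut threshold (typically from [best_cut()]); samples with
#'   `value > cut` fall on the right side.
#' @return list with `accepted`, `info_gain`, `mdl_criterion` (bits).
#' @export
mdl_accepts <- function(values, labels, cut) {
  labels <- factor(labels)
  n <- length(values)
  right <- values > cut
  cnt <- function(idx) as.numeric(table(labels[idx]))
  all_counts <- as.numeric(table(labels))
  hS <- entropy_bits(all_counts)
  cl <- cnt(!right); cr <- cnt(right)
  h1 <- entropy_bits(cl); h2 <- entropy_bits(cr)
  E <- sum(!right) / n * h1 + sum(right) / n * h2
  gain <- hS - E
  c_all <- sum(all_counts > 0)
  c1 <- sum(cl > 0); c2 <- sum(cr > 0)
  delta <- log2(3^c_all - 2) - (c_all * hS - c1 * h1 - c2 * h2)
  crit <- (log2(n - 1) + delta) / n
  list(accepted = gain > crit, info_gain = gain, mdl_criterion = crit)
}

#' Entropy-filter a feature matrix
#'
#' Applies [best_cut()] and [mdl_accepts()] to every feature of a panel (or any
#' numeric feature matrix) for a two-class comparison, returning the binary
#' matrix of accepted features (1 = value above the feature's cut) and a full
#' audit table of all cut results, including rejected features. Constant
#' features are recorded as rejected (no cut exists).
#'
#' @param x an [analyte_panel()], `zpanel`, or numeric sample x feature matrix.
#' @param labels two-class labels aligned with rows (taken from the panel
#'   metadata when `x` is a panel restricted to two classes and `labels` is
#'   missing).
#' @return a `discretized_panel`: list with `binary` (matrix of accepted
#'   features), `cuts` (data.frame: feature, cut, entropy, info_gain,
#'   mdl_criterion, accepted), `labels`, and `empty` flag (TRUE when no
#'   feature was accepted; a warning is raised).
#' @export
entropy_filter <- function(x, labels = NULL) {
  m <- feature_matrix(x)
  if (is.null(labels)) labels <- infer_labels(x)
  if (length(labels) != nrow(m)) stop("labels must align with rows")
  if (length(unique(labels)) != 2) stop("entropy_filter needs exactly two classes")
  labels <- factor(labels)
  nf <- ncol(m)
  res <- data.frame(feature = colnames(m), cut = NA_real_, entropy = NA_real_,
                    info_gain = NA_real_, mdl_criterion = NA_real_,
                    accepted = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(nf)) {
    v <- m[, j]
    if (length(unique(v)) < 2) next  # constant feature: rejected, no cut
    bc <- best_cut(v, labels)
    md <- mdl_accepts(v, labels, bc$cut)
    res$cut[j] <- bc$cut
    res$entropy[j] <- bc$entropy
    res$info_gain[j] <- md$info_gain
    res$mdl_criterion[j] <- md$mdl_criterion
    res$accepted[j] <- md$accepted
  }
  keep <- which(res$accepted)
  if (length(keep) == 0) {
    warning("no feature passed the entropy filter")
    binary <- matrix(integer(0), nrow = nrow(m), ncol = 0,
                     dimnames = list(rownames(m), NULL))
  } else {
    binary <- vapply(keep, function(j) as.integer(m[, j] > res$cut[j]),
                     integer(nrow(m)))
    dimnames(binary) <- list(rownames(m), colnames(m)[keep])
  }
  structure(list(binary = binary, cuts = res,
                 labels = stats::setNames(as.character(labels), rownames(m)),
                 empty = length(keep) == 0),
            class = "discretized_panel")
}

#' @export
print.discretized_panel <- function(x, ...) {
  cat("discretized_panel:", ncol(x$binary), "of", nrow(x$cuts),
      "features accepted;", nrow(x$binary), "samples\n")
  invisible(x)
}

feature_matrix <- function(x) {
  if (inherits(x, "analyte_panel")) return(x$values)
  if (inherits(x, "zpanel")) return(x$zvalues)
  if (inherits(x, "metafeature_panel")) return(x$values)
  as.matrix(x)
}

infer_labels <- function(x) {
  if (inherits(x, "analyte_panel")) return(panel_classes(x))
  if (inherits(x, "zpanel")) return(x$classes)
  if (inherits(x, "metafeature_panel")) return(x$classes)
  stop("labels must be supplied for a plain matrix")
}

#' Rank accepted features by univariate classification accuracy
#'
#' For each accepted feature the binary orientation (which side predicts which
#' class) is chosen to maximize the Matthews correlation coefficient; the table
#' reports per-class correct counts and percents (1 decimal) and is sorted by
#' MCC descending, ties broken by feature id. The second class in the factor
#' ordering of the stored labels is treated as the positive (disease) class.
#'
#' @param disc a `discretized_panel` from [entropy_filter()].
#' @return data.frame: feature, cut, correct/percent per class, mcc.
#' @export
rank_univariate <- function(disc) {
  stopifnot(inherits(disc, "discretized_panel"))
  if (disc$empty) stop("discretized panel is empty: nothing to rank")
  labs <- factor(disc$labels)
  neg <- levels(labs)[1]; pos <- levels(labs)[2]
  n_neg <- sum(labs == neg); n_pos <- sum(labs == pos)
  rows <- lapply(colnames(disc$binary), function(f) {
    b <- disc$binary[, f]
    # orientation A: predict positive when b == 1; orientation B: when b == 0
    score <- function(pred_pos) {
      TP <- sum(pred_pos & labs == pos); FN <- n_pos - TP
      TN <- sum(!pred_pos & labs == neg); FP <- n_neg - TN
      list(mcc = mcc(contingency(TP, TN, FP, FN)), TP = TP, TN = TN)
    }
    a <- score(b == 1); bb <- score(b == 0)
    best <- if (a$mcc >= bb$mcc) a else bb
    data.frame(feature = f,
               cut = disc$cuts$cut[match(f, disc$cuts$feature)],
               neg_correct = best$TN,
               neg_percent = round(100 * best$TN / n_neg, 1),
               pos_correct = best$TP,
               pos_percent = round(100 * best$TP / n_pos, 1),
               mcc = best$mcc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mcc, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "classes") <- c(negative = neg, positive = pos)
  out
}
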