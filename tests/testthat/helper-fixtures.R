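# Small in-code fixtures shared across the test files.

# a tiny raw-scale panel with explicit values and LDDs
toy_panel <- function(values, ldd = rep(1, ncol(values)),
                      classes = rep(c("Control", "MCI_Progressor"),
                                    length.out = nrow(values))) {
  n <- nrow(values); p <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("S%02d", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- sprintf("A%02d", seq_len(p))
  analyte_panel(
    values,
    sample_meta = data.frame(sample_id = rownames(values), class = classes,
                             age = seq(60, 90, length.out = n),
                             gender = rep_len(c("M", "F"), n),
                             genotype = "e3/e3", timepoint = "baseline"),
    analyte_meta = data.frame(analyte = colnames(values), ldd = ldd))
}

# a discretized_panel built directly from a binary matrix (cut at 0.5)
toy_disc <- function(binary, labels) {
  if (is.null(rownames(binary))) rownames(binary) <- sprintf("S%02d", seq_len(nrow(binary)))
  if (is.null(colnames(binary))) colnames(binary) <- sprintf("f%02d", seq_len(ncol(binary)))
  structure(list(
    binary = binary,
    cuts = data.frame(feature = colnames(binary), cut = 0.5, entropy = NA,
                      info_gain = NA, mdl_criterion = NA, accepted = TRUE),
    labels = stats::setNames(labels, rownames(binary)),
    empty = FALSE), class = "discretized_panel")
}

# independent brute-force scan over every midpoint between consecutive
# distinct values, recomputing the weighted class entropy from first
# principles; used as the oracle for best_cut
brute_best_cut <- function(values, labels) {
  h <- function(lab) {
    p <- table(lab) / length(lab)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  v <- sort(unique(values))
  cuts <- (v[-length(v)] + v[-1]) / 2
  E <- vapply(cuts, function(ct) {
    left <- values <= ct
    mean(left) * h(labels[left]) + mean(!left) * h(labels[!left])
  }, numeric(1))
  list(cut = cuts[which.min(E)], entropy = min(E))
}

# random two-class feature-set instance for solver cross-validation
random_instance <- function(n_features, n_samples, seed) {
  set.seed(seed)
  repeat {
    labels <- sample(c("A", "B"), n_samples, replace = TRUE)
    if (length(unique(labels)) == 2) break
  }
  B <- matrix(sample(0:1, n_samples * n_features, replace = TRUE),
              n_samples, n_features,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                              sprintf("f%02d", seq_len(n_features))))
  build_instance(toy_disc(B, labels))
}
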