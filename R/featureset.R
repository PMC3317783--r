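# The (alpha,beta)-k feature set problem: select k discretized features so
# that every between-class sample pair is distinguished by >= alpha selected
# features and every within-class pair agrees on >= beta selected features;
# minimize k, then maximize "coverage" (the total number of selected-feature /
# between-pair covering incidences). Solved exactly by branch and bound at
# desk scale, with a greedy + local-search fallback (labelled heuristic) for
# instances beyond the node budget.

#' Build a feature-set instance from a discretized panel
#'
#' Enumerates every between-class and within-class sample pair and records
#' which feature "covers" which pair: a feature covers a between-pair iff its
#' binary values differ across the pair, and covers a within-pair iff they are
#' equal.
#'
#' @param disc a `discretized_panel` from [entropy_filter()] with >= 1
#'   accepted feature and both classes present.
#' @return a `featureset_instance`: list with `features`, `covers` (logical
#'   pairs x features matrix), `pair_i`/`pair_j` (sample ids), `between`
#'   (logical per pair), `between_weight` (per-feature count of covered
#'   between-pairs), `labels`.
#' @export
build_instance <- function(disc) {
  stopifnot(inherits(disc, "discretized_panel"))
  if (disc$empty || ncol(disc$binary) == 0) stop("empty discretized panel")
  labs <- disc$labels
  if (length(unique(labs)) != 2) stop("instance requires both classes non-empty")
  B <- disc$binary
  n <- nrow(B)
  idx <- utils::combn(n, 2)
  pi_ <- idx[1, ]; pj_ <- idx[2, ]
  between <- labs[pi_] != labs[pj_]
  covers <- (B[pi_, , drop = FALSE] != B[pj_, , drop = FALSE])
  covers[!between, ] <- !covers[!between, , drop = FALSE]
  rownames(covers) <- NULL
  structure(list(features = colnames(B),
                 covers = covers,
                 pair_i = rownames(B)[pi_],
                 pair_j = rownames(B)[pj_],
                 between = between,
                 between_weight = colSums(covers[between, , drop = FALSE]),
                 labels = labs,
                 binary = B),
            class = "featureset_instance")
}

#' @export
print.featureset_instance <- function(x, ...) {
  cat("featureset_instance:", length(x$features), "features;",
      sum(x$between), "between-pairs,", sum(!x$between), "within-pairs\n")
  invisible(x)
}

#' Prune samples whose discretization patterns preclude a solution
#'
#' A between-class pair of samples with identical binary rows is covered by no
#' feature, and a within-class pair with fully complementary rows likewise;
#' either precludes any solution at alpha = beta = 1. Samples are removed
#' greedily (the sample participating in the most zero-cover pairs first)
#' until no uncoverable pair remains, and the pruned ids are reported so they
#' can be reinstated for classification.
#'
#' @param disc a `discretized_panel`.
#' @return list with `disc` (pruned), `instance` (rebuilt on the pruned
#'   samples), `pruned` (sample ids removed, possibly empty).
#' @export
prune_duplicate_patterns <- function(disc) {
  stopifnot(inherits(disc, "discretized_panel"))
  disc2 <- disc
  pruned <- character(0)
  repeat {
    inst <- build_instance(disc2)
    bad <- which(rowSums(inst$covers) == 0)
    if (length(bad) == 0) return(list(disc = disc2, instance = inst,
                                      pruned = pruned))
    tally <- sort(table(c(inst$pair_i[bad], inst$pair_j[bad])),
                  decreasing = TRUE)
    victim <- names(tally)[1]
    pruned <- c(pruned, victim)
    keep <- setdiff(rownames(disc2$binary), victim)
    if (length(unique(disc2$labels[keep])) < 2)
      stop("pruning exhausted a class: the instance is unsolvable")
    disc2$binary <- disc2$binary[keep, , drop = FALSE]
    disc2$labels <- disc2$labels[keep]
  }
}

new_signature <- function(instance, feats, status) {
  S <- match(feats, instance$features)
  cnt <- rowSums(instance$covers[, S, drop = FALSE])
  structure(list(features = feats,
                 k = length(feats),
                 achieved_alpha = min(cnt[instance$between]),
                 achieved_beta = if (any(!instance$between))
                   min(cnt[!instance$between]) else Inf,
                 coverage = sum(instance$between_weight[S]),
                 status = status),
            class = "absig_signature")
}

#' @export
print.absig_signature <- function(x, ...) {
  if (identical(x$status, "infeasible")) {
    cat("signature: INFEASIBLE (some pair covered by no feature)\n")
  } else {
    cat("signature: k =", x$k, " alpha =", x$achieved_alpha,
        " beta =", x$achieved_beta, " coverage =", x$coverage,
        " [", x$status, "]\n")
    cat(" features:", paste(x$features, collapse = ", "), "\n")
  }
  invisible(x)
}

infeasible_signature <- function(instance, req) {
  total <- rowSums(instance$covers)
  bad <- which(total < req)
  structure(list(features = character(0), k = NA_integer_,
                 achieved_alpha = NA, achieved_beta = NA, coverage = NA,
                 status = "infeasible",
                 uncoverable_pairs = data.frame(
                   i = instance$pair_i[bad], j = instance$pair_j[bad],
                   between = instance$between[bad])),
            class = "absig_signature")
}

greedy_cover <- function(M, req, weight) {
  nf <- ncol(M)
  deficit <- req
  sel <- integer(0)
  avail <- rep(TRUE, nf)
  while (any(deficit > 0)) {
    need <- deficit > 0
    gain <- colSums(M[need, , drop = FALSE] * pmin(1, deficit[need]))
    gain[!avail] <- -1
    best <- which(gain == max(gain))
    if (max(gain) <= 0) return(NULL)      # cannot progress: infeasible
    best <- best[order(-weight[best], best)][1]
    sel <- c(sel, best)
    avail[best] <- FALSE
    deficit <- pmax(0, deficit - M[, best])
  }
  sel
}

# Branch and bound minimizing k for the multicover instance (M: pairs x
# features, req: per-pair requirement). Returns list(k, one optimal selection)
# or NULL if the node budget is exhausted before the proof completes.
bb_min_k <- function(M, req, weight, ub_sel, node_budget = 2e5) {
  nf <- ncol(M)
  best_k <- length(ub_sel)
  best_sel <- ub_sel
  nodes <- 0L
  aborted <- FALSE
  colcov <- colSums(M)
  recurse <- function(sel, forbidden, deficit) {
    nodes <<- nodes + 1L
    if (nodes > node_budget) { aborted <<- TRUE; return() }
    if (aborted) return()
    if (!any(deficit > 0)) {
      if (length(sel) < best_k) { best_k <<- length(sel); best_sel <<- sel }
      return()
    }
    # lower bound: most-deficient pair needs that many more features, and the
    # total deficit divided by the best single-feature reduction
    avail <- setdiff(which(!forbidden), sel)
    if (length(avail) == 0) return()
    lb <- max(max(deficit), ceiling(sum(deficit) / max(colcov[avail])))
    if (length(sel) + lb >= best_k) return()
    # branch on the deficient pair with fewest available covering features
    need <- which(deficit > 0)
    ncov <- rowSums(M[need, avail, drop = FALSE])
    p <- need[which.min(ncov)]
    if (deficit[p] > sum(M[p, avail])) return()  # pair can no longer be met
    cand <- avail[M[p, avail]]
    cand <- cand[order(-colSums(M[deficit > 0, cand, drop = FALSE]),
                       -weight[cand], cand)]
    forb <- forbidden
    for (f in cand) {
      recurse(c(sel, f), forb, pmax(0, deficit - M[, f]))
      forb[f] <- TRUE   # avoid re-enumerating permutations of the same set
    }
  }
  recurse(integer(0), rep(FALSE, nf), req)
  if (aborted) NULL else list(k = best_k, sel = best_sel)
}

# Among covers of size exactly k, maximize the additive between-pair coverage
# weight: enumerate (with pruning) minimal covers of size <= k and top up with
# the highest-weight unused features.
bb_max_coverage <- function(M, req, weight, k, start_sel, node_budget = 2e5) {
  nf <- ncol(M)
  wsort <- sort(weight, decreasing = TRUE)
  fill_value <- function(sel) {
    slots <- k - length(sel)
    if (slots == 0) return(sum(weight[sel]))
    rest <- sort(weight[setdiff(seq_len(nf), sel)], decreasing = TRUE)
    sum(weight[sel]) + sum(rest[seq_len(slots)])
  }
  fill_features <- function(sel) {
    slots <- k - length(sel)
    if (slots == 0) return(sel)
    rest <- setdiff(order(-weight, seq_len(nf)), sel)
    c(sel, rest[seq_len(slots)])
  }
  best_val <- sum(weight[fill_features(start_sel)])
  best_sel <- fill_features(start_sel)
  nodes <- 0L; aborted <- FALSE
  recurse <- function(sel, forbidden, deficit) {
    nodes <<- nodes + 1L
    if (nodes > node_budget) { aborted <<- TRUE; return() }
    if (aborted) return()
    if (!any(deficit > 0)) {
      v <- fill_value(sel)
      if (v > best_val) { best_val <<- v; best_sel <<- fill_features(sel) }
      return()
    }
    if (length(sel) >= k) return()
    avail <- setdiff(which(!forbidden), sel)
    if (length(avail) == 0) return()
    # optimistic bound: finish with the globally heaviest remaining features
    ub <- sum(weight[sel]) +
      sum(sort(weight[avail], decreasing = TRUE)[seq_len(min(k - length(sel),
                                                             length(avail)))])
    if (ub <= best_val) return()
    need <- which(deficit > 0)
    ncov <- rowSums(M[need, avail, drop = FALSE])
    p <- need[which.min(ncov)]
    cand <- avail[M[p, avail]]
    if (length(cand) == 0) return()
    cand <- cand[order(-weight[cand], cand)]
    forb <- forbidden
    for (f in cand) {
      recurse(c(sel, f), forb, pmax(0, deficit - M[, f]))
      forb[f] <- TRUE
    }
  }
  recurse(integer(0), rep(FALSE, nf), req)
  list(sel = sort(best_sel), exact = !aborted)
}

#' Minimum-k feature set with maximum-coverage tie-break
#'
#' Finds a feature set of minimum cardinality `k*` such that every
#' between-class pair is covered at least `alpha` times and every within-class
#' pair at least `beta` times; among all sets of size `k*`, returns one
#' maximizing coverage. Returns an infeasible result (not an error) when some
#' pair is covered by no feature at all.
#'
#' @param instance a `featureset_instance` from [build_instance()].
#' @param alpha,beta minimum cover multiplicities (default 1 each).
#' @param node_budget branch-and-bound node budget per stage; beyond it the
#'   greedy + local-search solution is returned with `status = "heuristic"`.
#' @return an `absig_signature` (features, k, achieved alpha/beta, coverage,
#'   status "exact"/"heuristic"/"infeasible").
#' @export
solve_min_k <- function(instance, alpha = 1, beta = 1, node_budget = 2e5) {
  stopifnot(inherits(instance, "featureset_instance"))
  M <- instance$covers
  req <- ifelse(instance$between, alpha, beta)
  if (any(rowSums(M) < req)) return(infeasible_signature(instance, req))
  w <- instance$between_weight
  g <- greedy_cover(M, req, w)
  if (is.null(g)) return(infeasible_signature(instance, req))
  s1 <- bb_min_k(M, req, w, g, node_budget)
  if (is.null(s1)) {
    # proof of optimality not reached within budget: report greedy-improved set
    sel <- local_search_min(M, req, g)
    return(new_signature(instance, instance$features[sort(sel)], "heuristic"))
  }
  s2 <- bb_max_coverage(M, req, w, s1$k, s1$sel, node_budget)
  new_signature(instance, instance$features[s2$sel],
                if (s2$exact) "exact" else "heuristic")
}

local_search_min <- function(M, req, sel) {
  # drop-redundant pass: remove any feature whose removal keeps feasibility
  repeat {
    dropped <- FALSE
    for (f in sel) {
      rest <- setdiff(sel, f)
      cnt <- rowSums(M[, rest, drop = FALSE])
      if (all(cnt >= req)) { sel <- rest; dropped <- TRUE; break }
    }
    if (!dropped) break
  }
  sel
}

subset_stats <- function(instance, S) {
  cnt <- rowSums(instance$covers[, S, drop = FALSE])
  c(alpha = min(cnt[instance$between]),
    beta = if (any(!instance$between)) min(cnt[!instance$between]) else Inf,
    coverage = sum(instance$between_weight[S]))
}

#' Best feature set of fixed size k (lexicographic alpha, beta, coverage)
#'
#' Returns a size-`k` set maximizing, lexicographically, the achieved
#' (alpha, beta, coverage). Exhaustive over all `choose(n, k)` subsets when
#' that is tractable; otherwise a greedy + swap local search labelled
#' heuristic.
#'
#' @param instance a `featureset_instance`.
#' @param k signature size (1 <= k <= number of features).
#' @param enum_limit maximum number of subsets enumerated exactly
#'   (default 2e5).
#' @return an `absig_signature` with `k` features.
#' @export
solve_fixed_k <- function(instance, k, enum_limit = 2e5) {
  stopifnot(inherits(instance, "featureset_instance"))
  nf <- length(instance$features)
  if (k < 1 || k > nf) stop("k must be between 1 and the number of features")
  if (choose(nf, k) <= enum_limit) {
    combos <- utils::combn(nf, k)
    best <- NULL; best_stats <- c(-Inf, -Inf, -Inf)
    for (c_ in seq_len(ncol(combos))) {
      S <- combos[, c_]
      st <- subset_stats(instance, S)
      if (st[1] > best_stats[1] ||
          (st[1] == best_stats[1] && st[2] > best_stats[2]) ||
          (st[1] == best_stats[1] && st[2] == best_stats[2] &&
           st[3] > best_stats[3])) {
        best <- S; best_stats <- st
      }
    }
    return(new_signature(instance, instance$features[best], "exact"))
  }
  # heuristic: greedy max-min start then 1-swap hill climbing on the lex goal
  w <- instance$between_weight
  sel <- order(-w, seq_len(nf))[seq_len(k)]
  lex_gt <- function(a, b) {
    a[1] > b[1] || (a[1] == b[1] && (a[2] > b[2] ||
      (a[2] == b[2] && a[3] > b[3])))
  }
  cur <- subset_stats(instance, sel)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (out_f in sel) for (inn in setdiff(seq_len(nf), sel)) {
      cand <- c(setdiff(sel, out_f), inn)
      st <- subset_stats(instance, cand)
      if (lex_gt(st, cur)) { sel <- cand; cur <- st; improved <- TRUE; break }
    }
  }
  new_signature(instance, instance$features[sort(sel)], "heuristic")
}

#' Exhaustive oracle for the feature-set problem
#'
#' Exact answer by enumeration of subsets in increasing size; among sets of
#' minimum feasible size, returns one with maximal coverage. Refuses instances
#' with more than `max_features` features.
#'
#' @param instance a `featureset_instance`.
#' @param alpha,beta cover multiplicities.
#' @param max_features enumeration guard (default 20).
#' @return an `absig_signature` with `status = "oracle"`, or infeasible.
#' @export
exhaustive_oracle <- function(instance, alpha = 1, beta = 1, max_features = 20) {
  stopifnot(inherits(instance, "featureset_instance"))
  nf <- length(instance$features)
  if (nf > max_features) stop("instance too large for the exhaustive oracle")
  M <- instance$covers
  req <- ifelse(instance$between, alpha, beta)
  if (any(rowSums(M) < req)) return(infeasible_signature(instance, req))
  for (k in seq_len(nf)) {
    combos <- utils::combn(nf, k)
    best <- NULL; best_cov <- -Inf
    for (c_ in seq_len(ncol(combos))) {
      S <- combos[, c_]
      cnt <- rowSums(M[, S, drop = FALSE])
      if (all(cnt >= req)) {
        cov <- sum(instance$between_weight[S])
        if (cov > best_cov) { best <- S; best_cov <- cov }
      }
    }
    if (!is.null(best)) {
      sig <- new_signature(instance, instance$features[best], "oracle")
      return(sig)
    }
  }
  infeasible_signature(instance, req)
}

#' Serialize a signature to JSON
#' @param sig an `absig_signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  jsonlite::write_json(unclass(sig), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
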