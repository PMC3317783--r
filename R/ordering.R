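# Memetic seriation of a Z-score matrix for heat-map presentation: find row
# and column permutations minimizing the summed correlation distance
# (1 - Pearson r) between adjacent rows and adjacent columns. Because Pearson
# correlation between two rows ignores column order (and vice versa), the row
# and column problems are independent path-seriation problems over
# precomputed distance matrices, each solved by an elitist memetic algorithm
# (order crossover + pairwise-swap / segment-reversal local search).

row_distance <- function(m) {
  if (nrow(m) < 2) stop("matrix must have at least 2 rows")
  cm <- suppressWarnings(stats::cor(t(m)))
  if (anyNA(cm)) {
    bad <- which(apply(m, 1, stats::sd) == 0)
    stop("constant row (Pearson undefined): ",
         paste(rownames(m)[bad], collapse = ", "))
  }
  1 - cm
}

path_cost <- function(D, perm) {
  idx <- cbind(perm[-length(perm)], perm[-1])
  sum(D[idx])
}

#' Seriation objective of given row/column orders
#'
#' Sum over adjacent row pairs of `1 - cor(row_i, row_j)` plus the same over
#' adjacent column pairs.
#'
#' @param m numeric matrix (e.g. `zvalues` of a `zpanel`); no constant rows or
#'   columns.
#' @param row_perm,col_perm integer permutations of the rows and columns.
#' @return the objective value (>= 0 up to rounding of correlations).
#' @export
objective_value <- function(m, row_perm = seq_len(nrow(m)),
                            col_perm = seq_len(ncol(m))) {
  m <- feature_matrix(m)
  if (!setequal(row_perm, seq_len(nrow(m))) ||
      !setequal(col_perm, seq_len(ncol(m))))
    stop("permutations must be bijections on rows/columns")
  path_cost(row_distance(m), row_perm) + path_cost(row_distance(t(m)), col_perm)
}

order_crossover <- function(p1, p2) {
  n <- length(p1)
  cut <- sort(sample(n, 2))
  child <- integer(n)
  seg <- p1[cut[1]:cut[2]]
  child[cut[1]:cut[2]] <- seg
  rest <- p2[!p2 %in% seg]
  child[-(cut[1]:cut[2])] <- rest
  child
}

local_search_path <- function(D, perm, moves) {
  best <- path_cost(D, perm)
  n <- length(perm)
  for (iter in seq_len(moves)) {
    improved <- FALSE
    # pairwise swaps
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      cand <- perm; cand[c(i, j)] <- perm[c(j, i)]
      cc <- path_cost(D, cand)
      if (cc < best - 1e-12) { perm <- cand; best <- cc; improved <- TRUE }
    }
    # segment reversals (2-opt)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      cand <- perm; cand[i:j] <- rev(perm[i:j])
      cc <- path_cost(D, cand)
      if (cc < best - 1e-12) { perm <- cand; best <- cc; improved <- TRUE }
    }
    if (!improved) break
  }
  list(perm = perm, cost = best)
}

seriate_dimension <- function(D, pop_size, generations, local_search_moves) {
  n <- nrow(D)
  if (n == 1) return(list(perm = 1L, cost = 0, history = 0))
  pop <- c(list(seq_len(n)), replicate(pop_size - 1, sample(n), simplify = FALSE))
  cost <- vapply(pop, function(p) path_cost(D, p), numeric(1))
  # local search on the initial best (memetic: every elite is refined)
  b <- which.min(cost)
  ls <- local_search_path(D, pop[[b]], local_search_moves)
  pop[[b]] <- ls$perm; cost[b] <- ls$cost
  history <- min(cost)
  for (g in seq_len(generations)) {
    o <- order(cost)
    parents <- pop[o[seq_len(max(2, ceiling(pop_size / 2)))]]
    i1 <- sample(length(parents), 1); i2 <- sample(length(parents), 1)
    child <- order_crossover(parents[[i1]], parents[[i2]])
    ls <- local_search_path(D, child, local_search_moves)
    worst <- which.max(cost)
    if (ls$cost < cost[worst]) { pop[[worst]] <- ls$perm; cost[worst] <- ls$cost }
    history <- c(history, min(cost))
  }
  b <- which.min(cost)
  list(perm = pop[[b]], cost = cost[b], history = history)
}

#' Memetic seriation of a matrix
#'
#' Searches row and column permutations (independently, see above) minimizing
#' the adjacency correlation-distance objective. Elitist: the best objective
#' never worsens across generations, and the result is never worse than the
#' identity ordering. Deterministic given `seed`.
#'
#' @param m numeric matrix or `zpanel`.
#' @param pop_size population size (default 30).
#' @param generations number of generations (default 200).
#' @param local_search_moves maximum local-search sweeps per refinement
#'   (default 3).
#' @param seed RNG seed.
#' @return a `seriation_result`: `row_perm`, `col_perm`, `objective`,
#'   `row_history`, `col_history` (best-objective traces, non-increasing).
#' @export
seriate_memetic <- function(m, pop_size = 30, generations = 200,
                            local_search_moves = 3, seed = 1L) {
  m <- feature_matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("matrix must be at least 2 x 2")
  if (pop_size < 2 || local_search_moves < 1 || generations < 0)
    stop("params must be positive (generations may be 0)")
  Dr <- row_distance(m)
  Dc <- row_distance(t(m))
  with_local_seed(seed, {
    r <- seriate_dimension(Dr, pop_size, generations, local_search_moves)
    c_ <- seriate_dimension(Dc, pop_size, generations, local_search_moves)
    structure(list(row_perm = r$perm, col_perm = c_$perm,
                   objective = r$cost + c_$cost,
                   row_history = r$history, col_history = c_$history),
              class = "seriation_result")
  })
}

#' @export
print.seriation_result <- function(x, ...) {
  cat("seriation_result: objective", format(x$objective, digits = 6),
      "over", length(x$row_history), "recorded generations\n")
  invisible(x)
}

#' Exhaustive path seriation of one dimension (test oracle)
#'
#' Enumerates all orderings of the rows (up to reversal) and returns the
#' minimum adjacency cost. Guarded to small matrices.
#'
#' @param D symmetric distance matrix (<= 8 rows).
#' @return list with `perm` and `cost`.
#' @export
exhaustive_seriation <- function(D) {
  n <- nrow(D)
  if (n > 8) stop("exhaustive seriation is limited to 8 rows")
  perms <- all_permutations(n)
  best <- NULL; best_cost <- Inf
  for (p in perms) {
    if (p[1] > p[n]) next  # reversal symmetry
    cc <- path_cost(D, p)
    if (cc < best_cost) { best <- p; best_cost <- cc }
  }
  list(perm = best, cost = best_cost)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1)) {
    out[[length(out) + 1]] <- append(p, n, after = pos)
  }
  out
}

#' Render a seriated heat map
#'
#' Thin plotting helper over `pheatmap` with a green-red continuum; the
#' algorithmic deliverable is the permutations, not the picture.
#'
#' @param m matrix or `zpanel`.
#' @param res a `seriation_result` for `m`.
#' @param filename optional output file (PNG); NULL draws to the active device.
#' @return the pheatmap object, invisibly.
#' @export
plot_seriated_heatmap <- function(m, res, filename = NULL) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap is required for plotting")
  m <- feature_matrix(m)
  mm <- m[res$row_perm, res$col_perm, drop = FALSE]
  pal <- grDevices::colorRampPalette(c("green4", "black", "red"))(101)
  ph <- pheatmap::pheatmap(mm, cluster_rows = FALSE, cluster_cols = FALSE,
                           color = pal, filename = filename,
                           silent = !is.null(filename))
  invisible(ph)
}
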