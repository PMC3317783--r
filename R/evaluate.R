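# Classification evaluation harness: contingency metrics, a default set of 10
# classifiers spanning the standard model families, 10-fold cross-validation
# with score-then-average aggregation, covariate-matched train/test splits and
# size-matched subsampling, and the univariate Welch t-test table.

#' Construct a classification contingency
#' @param TP,TN,FP,FN non-negative counts; the disease class is positive.
#' @return a `contingency` object.
#' @export
contingency <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stop("contingency counts must be non-negative")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN), class = "contingency")
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any
#' factor of the denominator is zero the classifier carries no information and
#' 0 is returned.
#'
#' @param c a [contingency()].
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "contingency"))
  d <- (c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  if (d == 0) return(0)
  (c$TP * c$TN - c$FP * c$FN) / sqrt(d)
}

#' Sensitivity and specificity of a contingency, in percent
#' @param c a [contingency()].
#' @return named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(c) {
  stopifnot(inherits(c, "contingency"))
  c(sensitivity = 100 * c$TP / (c$TP + c$FN),
    specificity = 100 * c$TN / (c$TN + c$FP))
}

# --- default classifier set -------------------------------------------------
# Ten models spanning the families commonly screened for this kind of panel:
# Bayes, logistic/linear, margin-based, instance-based, tree, ensemble, rules.
# Each is a function(train_x, train_y, test_x) -> factor predictions with the
# levels of train_y.

oner_classifier <- function(train_x, train_y, test_x) {
  # single-feature threshold rule: pick the feature/orientation with the best
  # training MCC at its entropy-optimal cut
  lv <- levels(train_y)
  best <- list(mcc = -Inf)
  for (j in seq_len(ncol(train_x))) {
    v <- train_x[, j]
    if (length(unique(v)) < 2) next
    cut <- best_cut(v, train_y)$cut
    for (flip in c(FALSE, TRUE)) {
      pred_pos <- if (flip) v <= cut else v > cut
      TP <- sum(pred_pos & train_y == lv[2]); FN <- sum(train_y == lv[2]) - TP
      TN <- sum(!pred_pos & train_y == lv[1]); FP <- sum(train_y == lv[1]) - TN
      m <- mcc(contingency(TP, TN, FP, FN))
      if (m > best$mcc) best <- list(mcc = m, j = j, cut = cut, flip = flip)
    }
  }
  if (!is.finite(best$mcc)) return(factor(rep(lv[1], nrow(test_x)), levels = lv))
  v <- test_x[, best$j]
  pred_pos <- if (best$flip) v <= best$cut else v > best$cut
  factor(ifelse(pred_pos, lv[2], lv[1]), levels = lv)
}

#' The default 10-classifier set
#'
#' @return named list of classifier functions
#'   `function(train_x, train_y, test_x)`.
#' @export
default_classifiers <- function() {
  list(
    naive_bayes = function(xtr, ytr, xte) {
      fit <- e1071::naiveBayes(xtr, ytr)
      stats::predict(fit, xte)
    },
    logistic = function(xtr, ytr, xte) {
      df <- data.frame(.y = ytr, xtr, check.names = TRUE)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      p <- stats::predict(fit, data.frame(xte, check.names = TRUE), type = "response")
      factor(levels(ytr)[1 + (p > 0.5)], levels = levels(ytr))
    },
    lda = function(xtr, ytr, xte) {
      fit <- MASS::lda(xtr, grouping = ytr)
      stats::predict(fit, xte)$class
    },
    nearest_centroid = function(xtr, ytr, xte) {
      cen <- apply(xtr, 2, function(col) tapply(col, ytr, mean))
      d <- apply(xte, 1, function(r) {
        apply(cen, 1, function(m) sum((r - m)^2))
      })
      factor(rownames(cen)[apply(d, 2, which.min)], levels = levels(ytr))
    },
    svm_linear = function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, ytr, kernel = "linear", scale = TRUE)
      stats::predict(fit, xte)
    },
    svm_radial = function(xtr, ytr, xte) {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", scale = TRUE)
      stats::predict(fit, xte)
    },
    knn5 = function(xtr, ytr, xte) {
      mu <- colMeans(xtr); sd_ <- pmax(apply(xtr, 2, stats::sd), 1e-12)
      class::knn(scale(xtr, mu, sd_), scale(xte, mu, sd_), ytr, k = 5)
    },
    cart = function(xtr, ytr, xte) {
      df <- data.frame(.y = ytr, xtr, check.names = TRUE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      stats::predict(fit, data.frame(xte, check.names = TRUE), type = "class")
    },
    random_forest = function(xtr, ytr, xte) {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 200)
      stats::predict(fit, xte)
    },
    one_rule = oner_classifier
  )
}

#' Cross-validated multi-classifier evaluation
#'
#' Random 10-fold cross-validation: each classifier is trained on 9 folds and
#' predicts the held-out fold; out-of-fold predictions are pooled into one
#' contingency per classifier, scored (sensitivity, specificity, MCC), and the
#' per-classifier scores are averaged. Classification uses the original
#' (non-discretized) feature values. A classifier that fails on any fold is
#' excluded with a warning. Deterministic given `seed`.
#'
#' @param x numeric sample x feature matrix (original scale), e.g. a panel's
#'   values restricted to a signature's features.
#' @param labels two-class labels; the second factor level is the positive
#'   (disease) class.
#' @param classifiers named list of classifier functions (default
#'   [default_classifiers()]).
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return a `classification_report`: per-classifier data.frame
#'   (`per_classifier`), averaged `sensitivity`, `specificity`, `mcc`,
#'   protocol descriptor and seed.
#' @export
crossvalidate <- function(x, labels, classifiers = default_classifiers(),
                          folds = 10, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("crossvalidate needs exactly two classes")
  n <- nrow(x)
  fold_of <- with_local_seed(seed, sample(rep_len(seq_len(folds), n)))
  per <- list()
  for (nm in names(classifiers)) {
    pred <- factor(rep(NA_character_, n), levels = levels(y))
    ok <- TRUE
    for (f in seq_len(folds)) {
      te <- which(fold_of == f); tr <- which(fold_of != f)
      if (length(te) == 0) next
      p <- try(with_local_seed(seed + 1000L * f,
                               classifiers[[nm]](x[tr, , drop = FALSE], y[tr],
                                                 x[te, , drop = FALSE])),
               silent = TRUE)
      if (inherits(p, "try-error") || length(p) != length(te)) {
        warning("classifier '", nm, "' failed on a fold and was excluded")
        ok <- FALSE
        break
      }
      pred[te] <- p
    }
    if (!ok) next
    per[[nm]] <- score_predictions(pred, y)
  }
  if (length(per) == 0) stop("every classifier failed")
  tab <- do.call(rbind, per)
  tab <- data.frame(classifier = names(per), tab, row.names = NULL)
  structure(list(per_classifier = tab,
                 sensitivity = mean(tab$sensitivity),
                 specificity = mean(tab$specificity),
                 mcc = mean(tab$mcc),
                 protocol = sprintf("cv-%dfold", folds), seed = seed),
            class = "classification_report")
}

score_predictions <- function(pred, y) {
  lv <- levels(y)
  TP <- sum(pred == lv[2] & y == lv[2]); FN <- sum(pred != lv[2] & y == lv[2])
  TN <- sum(pred == lv[1] & y == lv[1]); FP <- sum(pred != lv[1] & y == lv[1])
  ct <- contingency(TP, TN, FP, FN)
  data.frame(TP = TP, TN = TN, FP = FP, FN = FN,
             sensitivity = sens_spec(ct)[["sensitivity"]],
             specificity = sens_spec(ct)[["specificity"]],
             mcc = mcc(ct))
}

#' Train on one set, score on another
#'
#' @param xtr,ytr training features and labels.
#' @param xte,yte test features and labels.
#' @param classifiers as in [crossvalidate()].
#' @param seed RNG seed passed to stochastic classifiers.
#' @return a `classification_report` for the test set.
#' @export
evaluate_train_test <- function(xtr, ytr, xte, yte,
                                classifiers = default_classifiers(),
                                seed = 1L) {
  ytr <- factor(ytr); yte <- factor(yte, levels = levels(ytr))
  per <- list()
  for (nm in names(classifiers)) {
    p <- try(with_local_seed(seed, classifiers[[nm]](as.matrix(xtr), ytr,
                                                     as.matrix(xte))),
             silent = TRUE)
    if (inherits(p, "try-error")) {
      warning("classifier '", nm, "' failed and was excluded")
      next
    }
    per[[nm]] <- score_predictions(factor(p, levels = levels(ytr)), yte)
  }
  tab <- data.frame(classifier = names(per), do.call(rbind, per),
                    row.names = NULL)
  structure(list(per_classifier = tab,
                 sensitivity = mean(tab$sensitivity),
                 specificity = mean(tab$specificity),
                 mcc = mean(tab$mcc),
                 protocol = "train/test", seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification_report (", x$protocol, "), averaged over",
      nrow(x$per_classifier), "classifiers:\n")
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  MCC %.3f\n",
              x$sensitivity, x$specificity, x$mcc))
  invisible(x)
}

# greedy nearest-age pairing within a stratum; returns a two-column matrix of
# indices (pairs), leftover indices are attributed randomly by the caller
greedy_age_pairs <- function(age_a, age_b) {
  used_b <- logical(length(age_b))
  out <- matrix(integer(0), ncol = 2)
  for (i in order(age_a)) {
    d <- abs(age_b - age_a[i]); d[used_b] <- Inf
    if (all(!is.finite(d))) break
    j <- which.min(d)
    used_b[j] <- TRUE
    out <- rbind(out, c(i, j))
  }
  out
}

#' Covariate-matched 50/50 train/test split
#'
#' Each class is split into two halves. Within strata of gender x genotype,
#' samples are greedily paired by nearest age and each pair is split randomly
#' across the halves; stratum leftovers are assigned randomly (with a warning
#' for singleton strata).
#'
#' @param panel an [analyte_panel()] restricted to the two comparison classes.
#' @param covariates metadata columns defining the strata
#'   (default gender and genotype).
#' @param seed RNG seed.
#' @return list with `train` and `test` (sample id vectors) and `balance`
#'   (per-half mean age and covariate tables).
#' @export
split_train_test_matched <- function(panel, covariates = c("gender", "genotype"),
                                     seed = 1L) {
  stopifnot(inherits(panel, "analyte_panel"))
  sm <- panel$sample_meta
  cls <- unique(sm$class)
  if (length(cls) != 2) stop("panel must contain exactly two classes")
  covariates <- intersect(covariates, names(sm))
  with_local_seed(seed, {
    train <- character(0); test <- character(0)
    for (cl in cls) {
      sub <- sm[sm$class == cl, , drop = FALSE]
      strat <- if (length(covariates))
        interaction(sub[covariates], drop = TRUE) else factor(rep(1, nrow(sub)))
      leftover <- character(0)
      for (s in levels(strat)) {
        ids <- sub$sample_id[strat == s]
        ages <- sub$age[strat == s]
        if (length(ids) == 1) {
          warning("stratum of size 1 assigned randomly: ", s)
          leftover <- c(leftover, ids)
          next
        }
        o <- order(ages)
        ids <- ids[o]
        # consecutive age pairs, each split randomly across the halves
        for (p in seq(1, length(ids) - 1, by = 2)) {
          if (stats::runif(1) < 0.5) {
            train <- c(train, ids[p]); test <- c(test, ids[p + 1])
          } else {
            train <- c(train, ids[p + 1]); test <- c(test, ids[p])
          }
        }
        if (length(ids) %% 2 == 1) leftover <- c(leftover, ids[length(ids)])
      }
      # stratum leftovers alternate across the halves so each class splits
      # as evenly as possible
      leftover <- sample(leftover)
      flip <- stats::runif(1) < 0.5
      for (i in seq_along(leftover)) {
        to_train <- xor(i %% 2 == 1, flip)
        if (to_train) train <- c(train, leftover[i]) else test <- c(test, leftover[i])
      }
    }
    balance <- data.frame(
      half = c("train", "test"),
      mean_age = c(mean(sm$age[sm$sample_id %in% train]),
                   mean(sm$age[sm$sample_id %in% test])))
    list(train = train, test = test, balance = balance)
  })
}

#' Size-matched subsample of the majority class
#'
#' Returns all minority-class samples plus an equal number of majority-class
#' samples chosen by gender-stratified greedy nearest-age matching (seeded
#' random tie-breaks). If a gender stratum of the majority class is too small,
#' matching falls back across strata with a warning.
#'
#' @param panel an [analyte_panel()] restricted to two classes.
#' @param covariates stratification column(s), default `"gender"`.
#' @param seed RNG seed.
#' @return character vector of selected sample ids (minority + matched
#'   majority).
#' @export
size_match <- function(panel, covariates = "gender", seed = 1L) {
  stopifnot(inherits(panel, "analyte_panel"))
  sm <- panel$sample_meta
  tab <- table(sm$class)
  if (length(tab) != 2) stop("panel must contain exactly two classes")
  if (tab[1] == tab[2]) return(sm$sample_id)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  covariates <- intersect(covariates, names(sm))
  with_local_seed(seed, {
    mino <- sm[sm$class == minority, , drop = FALSE]
    majo <- sm[sm$class == majority, , drop = FALSE]
    majo <- majo[sample(nrow(majo)), , drop = FALSE]  # seeded tie-break order
    strat_min <- if (length(covariates))
      interaction(mino[covariates], drop = TRUE) else factor(rep(1, nrow(mino)))
    chosen <- character(0)
    unmatched <- list()
    for (s in levels(strat_min)) {
      need <- mino[strat_min == s, , drop = FALSE]
      pool_idx <- if (length(covariates))
        which(interaction(majo[covariates], drop = FALSE) %in% s &
                !majo$sample_id %in% chosen)
      else which(!majo$sample_id %in% chosen)
      pool <- majo[pool_idx, , drop = FALSE]
      if (nrow(pool) < nrow(need)) {
        warning("insufficient majority samples in stratum ", s,
                ": falling back to cross-stratum age matching")
        unmatched[[s]] <- need
        next
      }
      pr <- greedy_age_pairs(need$age, pool$age)
      chosen <- c(chosen, pool$sample_id[pr[, 2]])
    }
    for (need in unmatched) {
      pool <- majo[!majo$sample_id %in% chosen, , drop = FALSE]
      pr <- greedy_age_pairs(need$age, pool$age)
      chosen <- c(chosen, pool$sample_id[pr[, 2]])
    }
    c(mino$sample_id, chosen)
  })
}

#' Per-analyte Welch two-sample t-test table
#'
#' Welch (unequal variance) two-tailed t-test per analyte on the panel's
#' analysis scale, sorted by p ascending. A Bonferroni-adjusted column is
#' included for information; ranking and reporting use the unadjusted p.
#' Analytes with zero variance in both classes get `p = NA` and a flag.
#'
#' @param panel an [analyte_panel()] restricted to two classes.
#' @return data.frame: analyte, per-class means, t, p, p_bonferroni, flag.
#' @export
welch_ttest_table <- function(panel) {
  stopifnot(inherits(panel, "analyte_panel"))
  cls <- panel_classes(panel)
  lv <- unique(cls)
  if (length(lv) != 2) stop("welch_ttest_table needs exactly two classes")
  a <- panel$values[cls == lv[1], , drop = FALSE]
  b <- panel$values[cls == lv[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("each class needs >= 2 samples")
  rows <- lapply(colnames(panel$values), function(an) {
    va <- a[, an]; vb <- b[, an]
    if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
      return(data.frame(analyte = an, mean_1 = mean(va), mean_2 = mean(vb),
                        t = if (mean(va) == mean(vb)) 0 else NA_real_,
                        p = if (mean(va) == mean(vb)) 1 else NA_real_,
                        degenerate = TRUE))
    }
    tt <- stats::t.test(va, vb, var.equal = FALSE)
    data.frame(analyte = an, mean_1 = mean(va), mean_2 = mean(vb),
               t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("mean_", make.names(lv))
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p), , drop = FALSE]
}
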