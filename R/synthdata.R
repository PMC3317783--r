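#' Configuration for the synthetic plasma-panel generator
#'
#' The generator emulates the structure of a multiplex plasma proteomics study
#' of pre-clinical Alzheimer's disease: four diagnostic groups of unequal size
#' (cognitively normal controls, stable MCI, MCI progressors, AD), ~190
#' analytes with approximately log10-normal concentrations, detection-limit
#' censoring, an APOE-like analyte whose level is graded by an APOE-like
#' genotype, a planted subset of class-discriminative analytes, and a 12-month
#' follow-up with disease-linked drift in progressors.
#'
#' @param n_per_group named integer vector of samples per diagnostic class.
#'   Defaults mirror the study cohort: 54 Control, 233 MCI_Other,
#'   163 MCI_Progressor, 112 AD.
#' @param n_analytes number of analytes on the panel (default 190).
#' @param n_informative number of planted class-discriminative analytes
#'   (default 10, capped at `n_analytes`).
#' @param effect_size shift applied to informative analytes in affected
#'   classes, in within-group SD units on the log10 scale (default 1.5).
#' @param affected_classes classes receiving the planted shift
#'   (default MCI_Progressor and AD).
#' @param informative_directions `"up"` (all planted shifts positive, the
#'   default), `"down"`, or `"mixed"` (random signs). Down-shifted analytes
#'   interact with detection-limit censoring: a large negative shift pushes
#'   much of the affected class below the LDD, and the detectability filter
#'   then removes the analyte before selection — mirroring how heavily
#'   censored analytes are excluded from real panels a priori.
#' @param genotype_effect per-risk-allele shift (log10 SD units) on the
#'   designated APOE-like analyte; negative reproduces the observed
#'   e2 > e3 > e4 plasma concentration gradient (default -1).
#' @param e4_freq named per-class probability that a single allele draw is e4;
#'   defaults follow the cohort's reported frequencies (9/43/67/68%).
#' @param e2_freq probability an allele is e2 given it is not e4 (default 0.05).
#' @param ldd_quantile fraction of the Control-class distribution of each
#'   analyte falling below its detection limit (default 0.001; must be
#'   < 0.5). Detectable plasma analytes sit well above their LDD; larger
#'   values emulate poorly detectable analytes.
#' @param followup_drift additional log10 shift applied at 12 months to
#'   informative analytes of MCI_Progressor samples, signed by each analyte's
#'   planted direction (default 1).
#' @param noise_sd residual within-group SD on the log10 scale (default 0.3).
#' @param block_rho within-block exchangeable correlation of analytes
#'   (default 0.2; in [0,1)).
#' @param block_size analytes per correlation block (default 10).
#' @param age_range age range (years), sampled uniformly and group-balanced.
#' @param seed RNG seed; identical configs produce bit-identical panels.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_per_group = c(Control = 54, MCI_Other = 233,
                                         MCI_Progressor = 163, AD = 112),
                         n_analytes = 190,
                         n_informative = NULL,
                         effect_size = 1.5,
                         affected_classes = c("MCI_Progressor", "AD"),
                         informative_directions = c("up", "down", "mixed"),
                         genotype_effect = -1,
                         e4_freq = c(Control = 0.09, MCI_Other = 0.43,
                                     MCI_Progressor = 0.67, AD = 0.68),
                         e2_freq = 0.05,
                         ldd_quantile = 0.001,
                         followup_drift = 1,
                         noise_sd = 0.3,
                         block_rho = 0.2,
                         block_size = 10,
                         age_range = c(62, 90),
                         seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("invalid config: n_per_group must be a named vector of class sizes")
  if (any(n_per_group < 1)) stop("invalid config: n_per_group counts must be >= 1")
  if (n_analytes < 1) stop("invalid config: n_analytes must be >= 1")
  if (is.null(n_informative)) n_informative <- min(10L, n_analytes)
  if (n_informative < 0 || n_informative > n_analytes)
    stop("invalid config: n_informative must be in [0, n_analytes]")
  if (ldd_quantile < 0 || ldd_quantile >= 0.5)
    stop("invalid config: ldd_quantile must be in [0, 0.5)")
  if (block_rho < 0 || block_rho >= 1)
    stop("invalid config: block_rho must be in [0, 1)")
  if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  informative_directions <- match.arg(informative_directions)
  structure(list(n_per_group = n_per_group, n_analytes = n_analytes,
                 n_informative = n_informative, effect_size = effect_size,
                 affected_classes = affected_classes,
                 informative_directions = informative_directions,
                 genotype_effect = genotype_effect, e4_freq = e4_freq,
                 e2_freq = e2_freq, ldd_quantile = ldd_quantile,
                 followup_drift = followup_drift, noise_sd = noise_sd,
                 block_rho = block_rho, block_size = block_size,
                 age_range = age_range, seed = as.integer(seed)),
            class = "synth_config")
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

sample_genotypes <- function(classes, cfg) {
  p4 <- cfg$e4_freq[classes]
  p4[is.na(p4)] <- mean(cfg$e4_freq)
  draw_allele <- function(p) {
    u <- stats::runif(length(p))
    ifelse(u < p, "e4", ifelse(stats::runif(length(p)) < cfg$e2_freq, "e2", "e3"))
  }
  a1 <- draw_allele(p4)
  a2 <- draw_allele(p4)
  swap <- a1 > a2
  paste(ifelse(swap, a2, a1), ifelse(swap, a1, a2), sep = "/")
}

#' Count a given allele in a "ex/ey" genotype string
#' @param genotype character vector like `"e3/e4"`.
#' @param allele allele to count (`"e4"` or `"e2"`).
#' @return integer vector of allele counts (0, 1 or 2).
#' @export
allele_count <- function(genotype, allele = "e4") {
  vapply(strsplit(genotype, "/", fixed = TRUE),
         function(a) sum(a == allele), integer(1))
}

#' Generate a synthetic baseline plasma panel with planted truth
#'
#' Concentrations are log10-normal per analyte, with analyte-specific baseline
#' means drawn once per seed, exchangeable within-block correlation, planted
#' mean shifts on informative analytes in affected classes, and a
#' genotype-graded APOE-like analyte. Each analyte's LDD is set to the
#' configured quantile of its Control-class (theoretical) distribution.
#'
#' @param config a [synth_config()].
#' @return list with `panel` (an [analyte_panel()], raw scale) and `truth`
#'   (planted ground truth: `informative_analytes` data.frame with `analyte`,
#'   `direction`, `classes`; `apoe_like_analyte`; per-sample allele counts).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    classes <- rep(names(cfg$n_per_group), cfg$n_per_group)
    n <- length(classes)
    p <- cfg$n_analytes
    ids <- sprintf("S%03d", seq_len(n))
    analytes <- sprintf("analyte_%03d", seq_len(p))

    # analyte-specific log10 baselines and common residual SD
    mu <- stats::rnorm(p, mean = 1.5, sd = 0.8)
    sdv <- rep(cfg$noise_sd, p)

    # planted informative analytes; the APOE-like analyte is drawn from the
    # remaining analytes so its class signal comes only through genotype
    info_idx <- if (cfg$n_informative > 0) seq_len(cfg$n_informative) else integer(0)
    direction <- if (length(info_idx)) switch(cfg$informative_directions,
      up = rep(1, length(info_idx)),
      down = rep(-1, length(info_idx)),
      mixed = sample(c(-1, 1), length(info_idx), replace = TRUE))
    else numeric(0)
    apoe_idx <- if (p > cfg$n_informative) cfg$n_informative + 1L else p

    genotype <- sample_genotypes(classes, cfg)
    n_e4 <- allele_count(genotype, "e4")
    n_e2 <- allele_count(genotype, "e2")

    # block-correlated log10 noise
    blocks <- rep(seq_len(ceiling(p / cfg$block_size)), each = cfg$block_size)[seq_len(p)]
    eps <- matrix(stats::rnorm(n * p), n, p)
    if (cfg$block_rho > 0) {
      fac <- matrix(stats::rnorm(n * max(blocks)), n, max(blocks))
      eps <- sqrt(cfg$block_rho) * fac[, blocks, drop = FALSE] +
        sqrt(1 - cfg$block_rho) * eps
    }
    logv <- sweep(sweep(eps, 2, sdv, `*`), 2, mu, `+`)

    # planted class effects, in SD units
    if (length(info_idx)) {
      affected <- classes %in% cfg$affected_classes
      for (i in seq_along(info_idx)) {
        j <- info_idx[i]
        logv[affected, j] <- logv[affected, j] +
          direction[i] * cfg$effect_size * sdv[j]
      }
    }
    # genotype gradient on the APOE-like analyte (e4 lowers, e2 raises when
    # genotype_effect < 0), in SD units per allele
    logv[, apoe_idx] <- logv[, apoe_idx] +
      cfg$genotype_effect * sdv[apoe_idx] * (n_e4 - n_e2)

    # LDD: configured quantile of the Control-class theoretical distribution
    ctrl_mu <- mu
    q <- if (cfg$ldd_quantile > 0) stats::qnorm(cfg$ldd_quantile) else -12
    ldd <- 10^(ctrl_mu + q * sdv)

    values <- 10^logv
    dimnames(values) <- list(ids, analytes)

    n_grp <- table(factor(classes, levels = names(cfg$n_per_group)))
    age <- numeric(n); gender <- character(n)
    for (cl in names(cfg$n_per_group)) {
      sel <- which(classes == cl)
      age[sel] <- stats::runif(length(sel), cfg$age_range[1], cfg$age_range[2])
      gender[sel] <- rep_len(c("M", "F"), length(sel))
    }

    panel <- analyte_panel(
      values,
      sample_meta = data.frame(sample_id = ids, class = classes, age = age,
                               gender = gender, genotype = genotype,
                               timepoint = "baseline",
                               stringsAsFactors = FALSE),
      analyte_meta = data.frame(analyte = analytes, ldd = ldd,
                                stringsAsFactors = FALSE),
      scale = "raw")
    truth <- list(
      informative_analytes = if (length(info_idx))
        data.frame(analyte = analytes[info_idx], direction = direction,
                   classes = paste(cfg$affected_classes, collapse = ";"),
                   stringsAsFactors = FALSE)
      else
        data.frame(analyte = character(0), direction = numeric(0),
                   classes = character(0)),
      apoe_like_analyte = analytes[apoe_idx],
      genotype = stats::setNames(genotype, ids),
      n_e4 = stats::setNames(n_e4, ids),
      n_e2 = stats::setNames(n_e2, ids))
    list(panel = panel, truth = truth)
  })
}

#' Generate a 12-month follow-up panel
#'
#' Follow-up concentrations drift from baseline by within-subject log10 noise
#' (`noise_sd`); informative analytes of MCI_Progressor samples additionally
#' shift by `followup_drift` (log10 units, signed by each analyte's planted
#' direction). Sample ids match baseline.
#'
#' @param panel baseline [analyte_panel()] from [generate_panel()].
#' @param truth the planted truth from [generate_panel()].
#' @param config the [synth_config()] used at baseline.
#' @param sample_ids samples retained at follow-up (default: all).
#' @return an [analyte_panel()] with `timepoint = "m12"`.
#' @export
generate_followup <- function(panel, truth, config, sample_ids = NULL) {
  stopifnot(inherits(panel, "analyte_panel"), inherits(config, "synth_config"))
  if (panel$scale != "raw") stop("follow-up is generated from the raw-scale baseline")
  if (is.null(sample_ids)) sample_ids <- rownames(panel$values)
  if (!all(sample_ids %in% rownames(panel$values)))
    stop("requested follow-up subset contains samples absent from baseline")
  with_local_seed(config$seed + 1L, {
    base_log <- log10(panel$values[sample_ids, , drop = FALSE])
    n <- nrow(base_log); p <- ncol(base_log)
    drift <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
    fl <- base_log + drift
    cls <- panel_classes(panel)[sample_ids]
    prog <- cls == "MCI_Progressor"
    if (any(prog) && nrow(truth$informative_analytes) > 0) {
      for (i in seq_len(nrow(truth$informative_analytes))) {
        j <- truth$informative_analytes$analyte[i]
        fl[prog, j] <- fl[prog, j] +
          config$followup_drift * truth$informative_analytes$direction[i]
      }
    }
    sm <- panel$sample_meta[panel$sample_meta$sample_id %in% sample_ids, , drop = FALSE]
    sm$timepoint <- "m12"
    analyte_panel(10^fl, sm, panel$analyte_meta, scale = "raw")
  })
}

#' Write the planted truth as JSON
#' @param truth the `truth` component of [generate_panel()] output.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(informative_analytes = truth$informative_analytes,
         apoe_like_analyte = truth$apoe_like_analyte,
         genotype = as.list(truth$genotype)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
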