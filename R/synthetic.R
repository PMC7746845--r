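# Synthetic matched cell-line / tissue data with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: RMA-style log-scale Gaussian expression, a two-group cell-line
# contrast with planted up/down genes, and tissue cohorts whose survival
# follows a proportional-hazards model driven by planted gene coefficients
# (and, optionally, by planted gene-pair order indicators). A tunable fraction
# of planted cell-line sign labels agrees with the planted tissue signs, which
# makes the tissue/cell-line concordance hypothesis itself a dial with known
# truth.

#' Deterministic child seed derivation
#'
#' One master seed drives a whole pipeline run; every stochastic stage consumes
#' a child seed derived as `(seed * 48271 + offset) mod (2^31 - 1)` (a
#' Lehmer-style mixing step), so stages are independently reproducible.
#'
#' @param seed master seed (non-negative integer).
#' @param offset integer stage offset.
#' @return integer child seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(offset)) %% 2147483647)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Configuration for a two-group cell-line simulation
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (>= 2); groups are labelled
#'   sensitive/resistant.
#' @param n_de number of differentially expressed genes planted.
#' @param lfc log-unit mean shift of planted genes, resistant minus sensitive
#'   (each group is shifted by `lfc/2` in opposite directions).
#' @param noise_sd within-group Gaussian noise standard deviation (> 0).
#' @param seed RNG seed.
#' @param de_signs optional named +1/-1 vector forcing which genes are planted
#'   and with which direction (used by [simulate_matched()]); overrides random
#'   selection and must contain exactly `n_de` genes.
#' @return validated config list of class `cellline_sim_config`.
#' @export
cellline_sim_config <- function(n_genes, n_per_group, n_de, lfc = 2,
                                noise_sd = 0.5, seed = 1L, de_signs = NULL) {
  stopifnot(n_genes >= 1, n_per_group >= 2, n_de >= 0, n_de <= n_genes,
            noise_sd > 0)
  if (!is.null(de_signs)) {
    de_signs <- signed_gene_list(names(de_signs), de_signs)
    if (length(de_signs) != n_de) stop("de_signs must contain exactly n_de genes")
    if (!all(names(de_signs) %in% gene_ids(n_genes))) {
      stop("de_signs names outside the simulated gene universe")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 n_de = as.integer(n_de), lfc = lfc, noise_sd = noise_sd,
                 seed = as.integer(seed), de_signs = de_signs),
            class = "cellline_sim_config")
}

#' Simulate a resistant-vs-sensitive cell-line expression dataset
#'
#' Each gene gets a baseline level drawn once (`N(7, 1)`, log2-scale
#' microarray-like); planted genes are shifted by `±lfc/2` per group according
#' to their planted sign (+1 = up in resistant); Gaussian noise with
#' `noise_sd` is added per cell. Identical config and seed give identical
#' output.
#'
#' @param config [cellline_sim_config()].
#' @return list with `expr` (matrix genes x samples), `design` (data.frame
#'   sample/label) and `truth` (named +1/-1 vector of planted genes).
#' @export
simulate_cellline <- function(config) {
  stopifnot(inherits(config, "cellline_sim_config"))
  set.seed(config$seed)
  genes <- gene_ids(config$n_genes)
  n <- 2L * config$n_per_group
  samples <- c(sprintf("S%02d", seq_len(config$n_per_group)),
               sprintf("R%02d", seq_len(config$n_per_group)))
  labels <- rep(c("sensitive", "resistant"), each = config$n_per_group)
  baseline <- rnorm(config$n_genes, mean = 7, sd = 1)
  if (is.null(config$de_signs)) {
    de_genes <- sort(sample(genes, config$n_de))
    truth <- signed_gene_list(de_genes,
                              sample(c(-1L, 1L), config$n_de, replace = TRUE))
  } else {
    truth <- config$de_signs[order(names(config$de_signs))]
  }
  shift <- matrix(0, nrow = config$n_genes, ncol = n,
                  dimnames = list(genes, samples))
  if (length(truth)) {
    half <- outer(unname(truth) * config$lfc / 2,
                  ifelse(labels == "resistant", 1, -1))
    shift[names(truth), ] <- half
  }
  expr <- baseline + shift +
    matrix(rnorm(config$n_genes * n, sd = config$noise_sd),
           nrow = config$n_genes)
  dimnames(expr) <- list(genes, samples)
  list(expr = expr,
       design = data.frame(sample = samples, label = labels,
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Configuration for a proportional-hazards tissue simulation
#'
#' @param n_genes number of genes.
#' @param n_samples number of patients.
#' @param beta_map named numeric vector of true per-gene Cox log hazard ratios
#'   (genes not named have coefficient 0). May be empty for a null cohort.
#' @param baseline baseline hazard: `list(dist = "exponential", rate = ...)`
#'   or `list(dist = "weibull", shape = ..., scale = ...)`.
#' @param censor_horizon upper bound of the uniform administrative censoring
#'   time (months); `Inf` disables censoring.
#' @param seed RNG seed.
#' @param planted_signature optional planted REO signature:
#'   `list(pairs = data.frame(gene_hi, gene_lo), beta = <log HR>)`. Samples in
#'   which more than half of the pairs show the risky orientation
#'   (`x_hi > x_lo`) — the signature's own majority-vote high-risk group —
#'   get `beta` added to the linear predictor, so the planted signature's risk
#'   groups differ by a true log hazard ratio of `beta`.
#' @return validated config list of class `tissue_sim_config`.
#' @export
tissue_sim_config <- function(n_genes, n_samples, beta_map = numeric(0),
                              baseline = list(dist = "exponential", rate = 0.05),
                              censor_horizon = 60, seed = 1L,
                              planted_signature = NULL) {
  stopifnot(n_genes >= 1, n_samples >= 2, censor_horizon > 0)
  beta_map <- unlist(beta_map)
  if (length(beta_map) && is.null(names(beta_map))) stop("beta_map must be named")
  if (!all(names(beta_map) %in% gene_ids(n_genes))) {
    stop("beta_map keys outside the simulated gene universe")
  }
  baseline$dist <- match.arg(baseline$dist, c("exponential", "weibull"))
  if (baseline$dist == "exponential") {
    stopifnot(baseline$rate > 0)
  } else {
    stopifnot(baseline$shape > 0, baseline$scale > 0)
  }
  if (!is.null(planted_signature)) {
    ps <- planted_signature
    stopifnot(is.list(ps), is.data.frame(ps$pairs),
              all(c("gene_hi", "gene_lo") %in% colnames(ps$pairs)),
              all(c(ps$pairs$gene_hi, ps$pairs$gene_lo) %in% gene_ids(n_genes)),
              is.numeric(ps$beta), length(ps$beta) == 1L)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 beta_map = beta_map, baseline = baseline,
                 censor_horizon = censor_horizon, seed = as.integer(seed),
                 planted_signature = planted_signature),
            class = "tissue_sim_config")
}

# Analytic baseline survivor function S0(t) = exp(-H0(t)) for a tissue config.
#' Baseline survivor function of a tissue simulation
#' @param config [tissue_sim_config()].
#' @param times evaluation times.
#' @return numeric vector `S0(times)`.
#' @export
tissue_baseline_survival <- function(config, times) {
  b <- config$baseline
  H0 <- if (b$dist == "exponential") b$rate * times else (times / b$scale)^b$shape
  exp(-H0)
}

#' Simulate a tissue cohort with proportional-hazards survival
#'
#' Expression is Gaussian per gene (`N(7, 1)`); the linear predictor is
#' `eta_s = sum_g beta_g x_{g,s}` plus any planted pair-indicator terms; the
#' event time is drawn by inverse-transform sampling,
#' `T = H0^{-1}(-log(U) / exp(eta))`, which satisfies the Cox model by
#' construction; censoring is uniform on `(0, censor_horizon)` and independent
#' of covariates.
#'
#' @param config [tissue_sim_config()].
#' @return list with `expr`, `cohort` (data.frame sample/time/event) and
#'   `truth` (the `beta_map`).
#' @export
simulate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_sim_config"))
  set.seed(config$seed)
  genes <- gene_ids(config$n_genes)
  samples <- sprintf("P%04d", seq_len(config$n_samples))
  expr <- matrix(rnorm(config$n_genes * config$n_samples, mean = 7, sd = 1),
                 nrow = config$n_genes, dimnames = list(genes, samples))
  eta <- rep(0, config$n_samples)
  if (length(config$beta_map)) {
    eta <- eta + drop(crossprod(expr[names(config$beta_map), , drop = FALSE],
                                unname(config$beta_map)))
  }
  if (!is.null(config$planted_signature)) {
    ps <- config$planted_signature
    risky <- vapply(seq_len(nrow(ps$pairs)),
                    function(i) as.numeric(expr[ps$pairs$gene_hi[i], ] >
                                             expr[ps$pairs$gene_lo[i], ]),
                    numeric(config$n_samples))
    high <- rowSums(as.matrix(risky)) > nrow(ps$pairs) / 2
    eta <- eta + ps$beta * as.numeric(high)
  }
  u <- runif(config$n_samples)
  b <- config$baseline
  chaz <- -log(u) / exp(eta)          # H0(T) target
  t_ev <- if (b$dist == "exponential") chaz / b$rate else b$scale * chaz^(1 / b$shape)
  if (is.finite(config$censor_horizon)) {
    t_cens <- runif(config$n_samples, 0, config$censor_horizon)
    time <- pmin(t_ev, t_cens)
    event <- as.numeric(t_ev <= t_cens)
  } else {
    time <- t_ev
    event <- rep(1, config$n_samples)
  }
  if (sum(event) == 0) {
    stop("no events produced; increase censor_horizon")
  }
  list(expr = expr,
       cohort = data.frame(sample = samples, time = time, event = event,
                           stringsAsFactors = FALSE),
       truth = config$beta_map)
}

#' Configuration for a matched cell-line / tissue simulation
#'
#' @param consistency_rho fraction in `[0, 1]` of planted cell-line DEG signs
#'   that agree with the planted tissue coefficient signs.
#' @param cellline [cellline_sim_config()]; its `n_de` must equal the number
#'   of genes in the tissue `beta_map`, and both configs must share `n_genes`.
#' @param tissue [tissue_sim_config()] with a non-empty `beta_map`.
#' @return validated config list of class `matched_sim_config`.
#' @export
matched_sim_config <- function(consistency_rho, cellline, tissue) {
  stopifnot(inherits(cellline, "cellline_sim_config"),
            inherits(tissue, "tissue_sim_config"),
            consistency_rho >= 0, consistency_rho <= 1)
  if (cellline$n_genes != tissue$n_genes) {
    stop("cell-line and tissue configs must share n_genes")
  }
  if (cellline$n_de != length(tissue$beta_map)) {
    stop("planted gene counts differ: cell-line n_de = ", cellline$n_de,
         ", tissue beta_map has ", length(tissue$beta_map))
  }
  structure(list(consistency_rho = consistency_rho,
                 cellline = cellline, tissue = tissue),
            class = "matched_sim_config")
}

#' Simulate a matched tissue + cell-line pair with tunable sign concordance
#'
#' The tissue cohort is generated first; its planted coefficient signs define
#' the tissue truth. The cell-line simulation then plants the same genes, with
#' signs agreeing with the tissue signs for exactly
#' `round(consistency_rho * n_planted)` genes (the first ones in sorted
#' gene-id order) and disagreeing for the rest.
#'
#' @param config [matched_sim_config()].
#' @return list with elements `tissue` (from [simulate_tissue()]) and
#'   `cellline` (from [simulate_cellline()]).
#' @export
simulate_matched <- function(config) {
  stopifnot(inherits(config, "matched_sim_config"))
  tis <- simulate_tissue(config$tissue)
  planted <- sort(names(config$tissue$beta_map))
  tissue_signs <- sign(config$tissue$beta_map[planted])
  n_agree <- round(config$consistency_rho * length(planted))
  cell_signs <- -tissue_signs
  if (n_agree > 0) cell_signs[seq_len(n_agree)] <- tissue_signs[seq_len(n_agree)]
  cl_cfg <- config$cellline
  cl_cfg$de_signs <- signed_gene_list(planted, cell_signs)
  cell <- simulate_cellline(cl_cfg)
  list(tissue = tis, cellline = cell)
}
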