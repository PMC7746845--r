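# SAM-style moderated differential expression with permutation FDR.
#
# d_g = (mean_resistant - mean_sensitive) / (s_g + s0), where s_g is the
# two-group pooled standard error and s0 a small exchangeability constant that
# stabilises low-variance genes. The null distribution of |d| comes from
# group-label permutations (exhaustive when the number of distinct label
# assignments is small enough), and per-gene q-values use the classic
# median-false-call estimate with pi0 fixed at 1 (conservative).

# mean difference r_g and pooled standard error s_g for a two-group design
sam_moments <- function(expr, is_res) {
  n1 <- sum(is_res); n2 <- sum(!is_res)
  m1 <- rowMeans(expr[, is_res, drop = FALSE])
  m2 <- rowMeans(expr[, !is_res, drop = FALSE])
  ss1 <- rowSums((expr[, is_res, drop = FALSE] - m1)^2)
  ss2 <- rowSums((expr[, !is_res, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(r = m1 - m2, s = s)
}

# Tusher-style exchangeability constant: among candidate percentiles of s,
# pick the one minimising the coefficient of variation of mad(d) across
# windows of s; fall back to median(s) when the search degenerates.
choose_s0 <- function(r, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- unname(quantile(s, alphas))
  breaks <- unique(quantile(s, seq(0, 1, length.out = 21)))
  if (length(breaks) < 3L) return(median(s))
  bin <- cut(s, breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, bin, mad)
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2L) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  if (!any(is.finite(cv))) return(median(s))
  cand[which.min(cv)]
}

resolve_design <- function(expr, design) {
  validate_design(design)
  keep <- design$sample %in% colnames(expr)
  if (!all(keep)) stop("design sample(s) absent from expression matrix: ",
                       paste(design$sample[!keep], collapse = ", "))
  expr <- expr[, design$sample, drop = FALSE]
  list(expr = expr, is_res = design$label == "resistant")
}

#' SAM moderated difference statistics
#'
#' Computes, per gene, `d = (mean_resistant - mean_sensitive) / (s + s0)` with
#' the two-group pooled standard error `s`. `s0 = "auto"` selects the
#' exchangeability constant by minimising the coefficient of variation of
#' `mad(d)` across windows of `s` over candidate percentiles of `s`.
#'
#' @param expr expression matrix (genes x samples).
#' @param design data.frame sample/label with >= 2 samples per group.
#' @param s0 non-negative number, or `"auto"`.
#' @return data.frame gene/d/s/sign with the chosen `s0` as attribute `"s0"`.
#' @export
sam_statistics <- function(expr, design, s0 = "auto") {
  validate_expression_matrix(expr)
  rd <- resolve_design(expr, design)
  mom <- sam_moments(rd$expr, rd$is_res)
  if (identical(s0, "auto")) {
    s0 <- choose_s0(mom$r, mom$s)
  }
  stopifnot(is.numeric(s0), s0 >= 0)
  if (s0 == 0 && any(mom$s == 0)) {
    stop("zero-variance gene(s) with s0 = 0 (division by zero); use s0 > 0, e.g. s0 = \"auto\"")
  }
  d <- mom$r / (mom$s + s0)
  out <- data.frame(gene = rownames(expr), d = d, s = mom$s,
                    sign = ifelse(d > 0, 1L, ifelse(d < 0, -1L, 0L)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "s0") <- s0
  out
}

#' SAM statistics with permutation q-values
#'
#' The null `|d*|` distribution comes from permutations of the group labels:
#' exhaustive enumeration of all `choose(n, n_resistant)` assignments when
#' that count is `<= n_perm` (logged), otherwise `n_perm` uniformly random
#' label permutations. The per-gene q-value is
#' `median_perm #( |d*| >= |d_g| ) / #( observed |d| >= |d_g| )`, clipped to
#' `[0, 1]` and made monotone non-increasing in `|d|`; the proportion of true
#' nulls is fixed at 1 (conservative).
#'
#' @inheritParams sam_statistics
#' @param n_perm maximum number of permutations (>= 10).
#' @param seed RNG seed for the random-permutation branch.
#' @return data.frame gene/d/s/sign/q, attributes `"s0"`, `"n_perm_used"` and
#'   `"exhaustive"`.
#' @export
sam_fdr <- function(expr, design, n_perm = 1000L, seed = 1L, s0 = "auto") {
  if (n_perm < 10L) stop("n_perm must be >= 10")
  res <- sam_statistics(expr, design, s0 = s0)
  s0_used <- attr(res, "s0")
  rd <- resolve_design(expr, design)
  n <- ncol(rd$expr)
  n_res <- sum(rd$is_res)
  n_assign <- choose(n, n_res)
  if (n_assign <= n_perm) {
    assigns <- combn(n, n_res, simplify = FALSE)
    log_msg("sam_fdr: exhaustive permutation mode, %d label assignments", length(assigns))
  } else {
    set.seed(seed)
    assigns <- replicate(n_perm, sample.int(n, n_res), simplify = FALSE)
  }
  abs_obs <- abs(res$d)
  ord <- order(abs_obs)            # ascending |d|
  sorted_abs <- abs_obs[ord]
  # counts of observed |d| >= |d_g| (inclusive)
  denom <- nrow(res) - findInterval(sorted_abs, sorted_abs, left.open = TRUE)
  # per permutation: for each gene threshold, count permuted |d*| >= threshold
  counts <- vapply(assigns, function(idx) {
    is_res_p <- logical(n); is_res_p[idx] <- TRUE
    mom <- sam_moments(rd$expr, is_res_p)
    dstar <- sort(abs(mom$r / (mom$s + s0_used)))
    length(dstar) - findInterval(sorted_abs, dstar, left.open = TRUE)
  }, numeric(nrow(res)))
  med_false <- apply(counts, 1L, median)
  q_sorted <- pmin(pmax(med_false / pmax(denom, 1L), 0), 1)
  # enforce monotone non-increasing q in |d|: scan from largest |d| downwards
  q_sorted <- rev(cummax(rev(q_sorted)))
  q <- numeric(nrow(res))
  q[ord] <- q_sorted
  res$q <- q
  attr(res, "s0") <- s0_used
  attr(res, "n_perm_used") <- length(assigns)
  attr(res, "exhaustive") <- n_assign <= n_perm
  res
}

#' Select differentially expressed genes from a SAM result
#'
#' @param result data.frame from [sam_fdr()] (columns gene/d/q).
#' @param fdr q-value cutoff in (0, 1]; genes with `q < fdr` are returned.
#' @return signed gene list (named +1/-1 vector, sign of `d`); possibly empty.
#' @export
select_degs <- function(result, fdr = 0.2) {
  stopifnot(fdr > 0, fdr <= 1)
  keep <- (if (fdr >= 1) TRUE else result$q < fdr) & result$d != 0
  signed_gene_list(result$gene[keep], ifelse(result$d[keep] > 0, 1L, -1L))
}
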