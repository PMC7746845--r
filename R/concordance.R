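# Tissue / cell-line sign-concordance evaluation.
#
# Two signed gene lists (tissue: sign of the Cox coefficient; cell line: DEG
# direction) are compared on their overlapping genes. Under the null that
# directions agree at random, the number of sign-consistent genes k among n
# overlapping genes is Binomial(n, 0.5); the one-sided upper tail P(X >= k)
# measures consistency above chance.

#' Exact one-sided binomial tail P(X >= k), X ~ Binomial(n, 1/2)
#'
#' Computed with the exact regularised incomplete beta implementation behind
#' `pbinom` (log-space stable; values down to ~1e-300 do not underflow).
#' `k = 0` gives 1 (empty sum).
#'
#' @param n number of trials (>= 1).
#' @param k threshold, `0 <= k <= n`.
#' @return upper-tail probability.
#' @export
binomial_tail <- function(n, k) {
  stopifnot(length(n) == 1L, length(k) == 1L)
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  pbinom(k - 1, size = n, prob = 0.5, lower.tail = FALSE)
}

#' Sign concordance of two signed gene lists
#'
#' @param tissue,cell named +1/-1 vectors ([signed_gene_list()]).
#' @return data.frame with one row: n_overlap, n_consistent, ratio, p
#'   (one-sided binomial tail), p_adj = NA (set by [evaluate_panel()]).
#' @export
overlap_consistency <- function(tissue, cell) {
  if (!length(tissue) || !length(cell)) stop("signed gene lists must be non-empty")
  shared <- intersect(names(tissue), names(cell))
  if (!length(shared)) stop("no overlapping genes between the two lists")
  n <- length(shared)
  k <- sum(tissue[shared] == cell[shared])
  data.frame(n_overlap = n, n_consistent = k, ratio = k / n,
             p = binomial_tail(n, k), p_adj = NA_real_)
}

#' Concordance of a tissue list against a panel of cell-line lists
#'
#' One row per panel member; BH adjustment is applied across the members that
#' have a non-empty overlap (members with empty overlap are reported as NA
#' rows and excluded from the BH family).
#'
#' @param tissue signed gene list.
#' @param panel named list of signed gene lists.
#' @return data.frame dataset / n_overlap / n_consistent / ratio / p / p_adj.
#' @export
evaluate_panel <- function(tissue, panel) {
  if (!length(panel)) stop("panel must be non-empty")
  if (is.null(names(panel)) || any(!nzchar(names(panel)))) {
    stop("panel members must be named")
  }
  rows <- lapply(panel, function(cell) {
    tryCatch(overlap_consistency(tissue, cell),
             error = function(e) data.frame(n_overlap = 0L, n_consistent = NA_integer_,
                                            ratio = NA_real_, p = NA_real_,
                                            p_adj = NA_real_))
  })
  out <- cbind(data.frame(dataset = names(panel), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out
}

#' Pairwise sign concordance among a panel of signed gene lists
#'
#' All `choose(m, 2)` unordered pairs; raw one-sided binomial p-values (no
#' multiplicity adjustment, mirroring how such cross-dataset tables are
#' usually reported). Pairs with empty overlap become NA rows.
#'
#' @param panel named list of >= 2 signed gene lists.
#' @return data.frame dataset1 / dataset2 / n_overlap / n_consistent / ratio / p.
#' @export
pairwise_dataset_consistency <- function(panel) {
  if (length(panel) < 2L) stop("need >= 2 panel members")
  if (is.null(names(panel))) stop("panel members must be named")
  idx <- combn(length(panel), 2L)
  rows <- lapply(seq_len(ncol(idx)), function(j) {
    a <- idx[1, j]; b <- idx[2, j]
    res <- tryCatch(overlap_consistency(panel[[a]], panel[[b]]),
                    error = function(e) data.frame(n_overlap = 0L,
                                                   n_consistent = NA_integer_,
                                                   ratio = NA_real_, p = NA_real_,
                                                   p_adj = NA_real_))
    cbind(data.frame(dataset1 = names(panel)[a], dataset2 = names(panel)[b],
                     stringsAsFactors = FALSE),
          res[, c("n_overlap", "n_consistent", "ratio", "p")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format small p-values the way concordance tables print them
#'
#' Values below `1e-16` are shown as `"<1.00E-16"`; the numeric value is kept
#' by the caller.
#'
#' @param p numeric vector of probabilities.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-16, "<1.00E-16", sprintf("%.2E", p)))
}
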