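# The REO (relative expression ordering) gene-pair signature engine.
#
# A rule is an oriented gene pair (gene_hi, gene_lo): observing
# Expr(gene_hi) > Expr(gene_lo) within a sample votes "high risk". Rules are
# screened by univariate Cox regression on their 0/1 order indicator
# (Step 1), and the signature is the subset of retained rules whose
# majority-vote risk classification maximises Harrell's C-index under
# exhaustive enumeration (Step 2). Because only within-sample order is used,
# every output is invariant to strictly increasing per-sample transforms of
# the expression values.

#' Within-sample gene-pair order indicator
#'
#' 1 iff `Expr(a) > Expr(b)` strictly in that sample; an exact tie gives 0
#' (deterministic sensitive-leaning rule; ties have probability zero on
#' continuous data).
#'
#' @param expr expression matrix (genes x samples).
#' @param a,b gene ids, both present in `expr`.
#' @return named 0/1 integer vector, one per sample.
#' @export
pair_indicator <- function(expr, a, b) {
  miss <- setdiff(c(a, b), rownames(expr))
  if (length(miss)) stop("gene(s) missing from expression matrix: ",
                         paste(miss, collapse = ", "))
  setNames(as.integer(expr[a, ] > expr[b, ]), colnames(expr))
}

#' Construct a gene-pair signature
#'
#' @param rules data.frame with columns gene_hi / gene_lo (and optionally
#'   beta / p / q); at least one rule; duplicated unordered pairs are an error.
#'   A rule supplied with `beta < 0` is normalised by swapping its genes and
#'   negating `beta`, so `gene_hi` above `gene_lo` always votes high risk.
#' @return object of class `pair_signature` with the at-least-half
#'   majority-vote rule.
#' @export
pair_signature <- function(rules) {
  stopifnot(is.data.frame(rules), nrow(rules) >= 1L,
            all(c("gene_hi", "gene_lo") %in% colnames(rules)))
  if (any(rules$gene_hi == rules$gene_lo)) stop("a rule must involve two distinct genes")
  if (!is.null(rules$beta)) {
    flip <- !is.na(rules$beta) & rules$beta < 0
    if (any(flip)) {
      tmp <- rules$gene_hi[flip]
      rules$gene_hi[flip] <- rules$gene_lo[flip]
      rules$gene_lo[flip] <- tmp
      rules$beta[flip] <- -rules$beta[flip]
    }
  }
  key <- apply(cbind(pmin(rules$gene_hi, rules$gene_lo),
                     pmax(rules$gene_hi, rules$gene_lo)), 1L, paste, collapse = "|")
  if (anyDuplicated(key)) stop("duplicated gene pair(s) in signature")
  for (col in c("beta", "p", "q")) if (is.null(rules[[col]])) rules[[col]] <- NA_real_
  structure(list(rules = rules[, c("gene_hi", "gene_lo", "beta", "p", "q")],
                 vote_rule = "at_least_half_sensitive_low"),
            class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("REO gene-pair signature: %d rule(s), vote rule '%s'\n",
              nrow(x$rules), x$vote_rule))
  print(x$rules, row.names = FALSE)
  invisible(x)
}

#' Step 1: screen all gene-pair order indicators for survival association
#'
#' Builds all `choose(n, 2)` order indicators over the candidate genes, drops
#' constant indicators (all 0 or all 1; logged), fits a univariate Cox model
#' per remaining indicator, BH-adjusts across tested pairs and keeps pairs
#' with `q < fdr`. Retained pairs are orientation-normalised: if `beta < 0`
#' the genes are swapped and the model refitted on the flipped indicator, so
#' `gene_hi` above `gene_lo` always votes high risk (`beta > 0`).
#'
#' @param expr expression matrix.
#' @param cohort data.frame sample/time/event (joined by sample id).
#' @param candidates character vector (>= 2) of genes present in `expr`.
#' @param fdr q-value cutoff (default 0.10).
#' @return list of class `pair_screen`: `set1_size` (`choose(n, 2)`),
#'   `set2` (data.frame gene_hi/gene_lo/beta/se/p/q, ascending q),
#'   `n_constant`, `n_excluded`, `n_tested`.
#' @export
screen_pairs <- function(expr, cohort, candidates, fdr = 0.10) {
  stopifnot(fdr > 0, fdr <= 1)
  candidates <- unique(as.character(candidates))
  if (length(candidates) < 2L) stop("need >= 2 candidate genes")
  miss <- setdiff(candidates, rownames(expr))
  if (length(miss)) stop("candidate gene(s) missing from expression matrix: ",
                         paste(miss, collapse = ", "))
  al <- align_cohort(expr[candidates, , drop = FALSE], cohort)
  pairs <- combn(sort(candidates), 2L)
  set1_size <- ncol(pairs)
  n_constant <- 0L
  n_excluded <- 0L
  rows <- vector("list", set1_size)
  for (j in seq_len(set1_size)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ind <- as.numeric(al$expr[a, ] > al$expr[b, ])
    if (var(ind) == 0) { n_constant <- n_constant + 1L; next }
    fit <- cox_univariate(ind, al$cohort)
    if (!fit$converged) { n_excluded <- n_excluded + 1L; next }
    if (fit$beta < 0) {           # flip orientation and refit exactly
      tmp <- a; a <- b; b <- tmp
      fit <- cox_univariate(as.numeric(al$expr[a, ] > al$expr[b, ]), al$cohort)
      if (!fit$converged) { n_excluded <- n_excluded + 1L; next }
    }
    rows[[j]] <- data.frame(gene_hi = a, gene_lo = b, beta = fit$beta,
                            se = fit$se, p = fit$p, stringsAsFactors = FALSE)
  }
  if (n_constant > 0L) log_msg("screen_pairs: dropped %d constant indicator(s)", n_constant)
  if (n_excluded > 0L) log_msg("screen_pairs: excluded %d non-converged fit(s)", n_excluded)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no testable gene pairs")
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  set2 <- tab[tab$q < fdr, , drop = FALSE]
  set2 <- set2[order(set2$q, set2$p, set2$gene_hi, set2$gene_lo), , drop = FALSE]
  rownames(set2) <- NULL
  structure(list(set1_size = set1_size, set2 = set2,
                 n_constant = n_constant, n_excluded = n_excluded,
                 n_tested = nrow(tab)),
            class = "pair_screen")
}

# risk-oriented indicator matrix: rules x samples
rule_indicator_matrix <- function(expr, rules) {
  miss <- setdiff(unique(c(rules$gene_hi, rules$gene_lo)), rownames(expr))
  if (length(miss)) stop("signature gene(s) missing from expression matrix: ",
                         paste(miss, collapse = ", "))
  out <- t(vapply(seq_len(nrow(rules)),
                  function(i) as.numeric(expr[rules$gene_hi[i], ] > expr[rules$gene_lo[i], ]),
                  numeric(ncol(expr))))
  dimnames(out) <- list(NULL, colnames(expr))
  out
}

#' Majority-vote risk classification
#'
#' A rule votes "sensitive" for a sample when its risk-oriented indicator is 0
#' (the ordering associated with lower hazard). A sample is low risk when at
#' least half of the rules vote sensitive (inclusive: with an even rule count,
#' exactly half suffices), otherwise high risk.
#'
#' @param expr expression matrix containing every signature gene.
#' @param signature [pair_signature()].
#' @return factor with levels `low`, `high`, named by sample.
#' @export
vote_classify <- function(expr, signature) {
  stopifnot(inherits(signature, "pair_signature"))
  ind <- rule_indicator_matrix(expr, signature$rules)
  n_rules <- nrow(signature$rules)
  sensitive <- n_rules - colSums(ind)
  cls <- ifelse(sensitive >= n_rules / 2, "low", "high")
  factor(setNames(cls, colnames(expr)), levels = c("low", "high"))
}

# C-index of a binary 0/1 risk vector given a precomputed comparability
# matrix (comp[i, j] = 1 iff t_i < t_j and event_i = 1).
cindex_binary <- function(comp, row_tot, n_comp, r) {
  a <- drop(comp %*% r)            # comparable j with r_j = 1
  b <- row_tot - a                 # comparable j with r_j = 0
  conc <- sum(r * b)
  ties <- sum(r * a) + sum((1 - r) * b)
  (conc + 0.5 * ties) / n_comp
}

#' Step 2: exhaustive signature optimisation by C-index
#'
#' Enumerates every non-empty subset of the retained rules (optionally capped
#' at `max_size` rules), classifies samples with [vote_classify()] and scores
#' the binary risk label (high = 1) with Harrell's C-index; returns the
#' maximiser. Ties are broken in favour of the smaller subset, then the
#' lexicographically earlier rule combination (enumeration runs in that order
#' and only a strictly larger C-index replaces the incumbent). With more than
#' 20 rules and no `max_size` the call refuses (2^m blow-up); use `max_size`
#' or `method = "greedy"` (forward selection that adds the best rule until no
#' improvement).
#'
#' @param set2 data.frame of rules (gene_hi/gene_lo/beta/p/q), e.g.
#'   `screen_pairs(...)$set2`, or a `pair_screen` object.
#' @param expr expression matrix.
#' @param cohort data.frame sample/time/event.
#' @param max_size largest subset size considered (default unlimited).
#' @param method `"exhaustive"` (default) or `"greedy"`.
#' @return list: `signature` ([pair_signature()]), `cindex`, `n_subsets`
#'   (number of combinations scored).
#' @export
optimize_combination <- function(set2, expr, cohort, max_size = Inf,
                                 method = c("exhaustive", "greedy")) {
  method <- match.arg(method)
  if (inherits(set2, "pair_screen")) set2 <- set2$set2
  stopifnot(is.data.frame(set2))
  if (!nrow(set2)) stop("Set 2 is empty: no rules to combine")
  m <- nrow(set2)
  if (method == "exhaustive" && m > 20L && is.infinite(max_size)) {
    stop("refusing exhaustive enumeration of 2^", m, " - 1 subsets; ",
         "set max_size or use method = \"greedy\"")
  }
  al <- align_cohort(expr, cohort)
  ind <- rule_indicator_matrix(al$expr, set2)
  comp <- outer(al$cohort$time, al$cohort$time, `<`) * (al$cohort$event == 1)
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs in the cohort")
  row_tot <- rowSums(comp)
  score_subset <- function(idx) {
    k <- length(idx)
    votes <- if (k == 1L) ind[idx, ] else colSums(ind[idx, , drop = FALSE])
    r <- as.numeric(votes > k / 2)  # high risk iff sensitive votes < half
    cindex_binary(comp, row_tot, n_comp, r)
  }
  best_idx <- NULL
  best_c <- -Inf
  n_subsets <- 0L
  if (method == "exhaustive") {
    for (size in seq_len(min(m, max_size))) {
      subsets <- combn(m, size, simplify = FALSE)
      n_subsets <- n_subsets + length(subsets)
      for (idx in subsets) {
        cc <- score_subset(idx)
        if (cc > best_c) { best_c <- cc; best_idx <- idx }
      }
    }
    log_msg("optimize_combination: scored %d subset(s) of %d rule(s)", n_subsets, m)
  } else {
    current <- integer(0)
    repeat {
      cand <- setdiff(seq_len(m), current)
      if (!length(cand) || length(current) >= max_size) break
      scores <- vapply(cand, function(j) score_subset(sort(c(current, j))), numeric(1))
      n_subsets <- n_subsets + length(cand)
      if (max(scores) > best_c) {
        current <- sort(c(current, cand[which.max(scores)]))
        best_c <- max(scores)
        best_idx <- current
      } else break
    }
    log_msg("optimize_combination: greedy search scored %d candidate(s)", n_subsets)
  }
  if (is.null(best_idx)) stop("no subset yields a valid C-index")
  list(signature = pair_signature(set2[best_idx, , drop = FALSE]),
       cindex = best_c, n_subsets = n_subsets)
}

#' Number of non-empty rule subsets an exhaustive search enumerates
#'
#' @param n_rules number of retained rules.
#' @param max_size optional cap on subset size.
#' @return `sum_{k=1}^{min(n_rules, max_size)} choose(n_rules, k)`
#'   (`2^n_rules - 1` when uncapped).
#' @export
n_enumerable_subsets <- function(n_rules, max_size = Inf) {
  sizes <- seq_len(min(n_rules, max_size))
  sum(choose(n_rules, sizes))
}

#' Evaluate a signature on a cohort
#'
#' Classifies samples with [vote_classify()] and summarises the separation of
#' the two risk groups: hazard ratio with 95% CI (binary Cox), log-rank test,
#' and a Kaplan-Meier table per group. If every sample lands in one group the
#' metrics are NA with a warning, but group sizes are still reported.
#'
#' @param signature [pair_signature()].
#' @param expr expression matrix (must contain every signature gene).
#' @param cohort data.frame sample/time/event.
#' @return list: groups (factor), group_sizes, hr, ci95, logrank_chi2, p_cox,
#'   p_logrank, km (named list of KM tables), cindex.
#' @export
evaluate_signature <- function(signature, expr, cohort) {
  al <- align_cohort(expr, cohort)
  groups <- vote_classify(al$expr, signature)
  sizes <- table(groups)
  if (any(sizes == 0)) {
    warning("all samples classified into one risk group; survival metrics are NA")
    return(list(groups = groups, group_sizes = sizes, hr = NA_real_,
                ci95 = c(NA_real_, NA_real_), logrank_chi2 = NA_real_,
                p_cox = NA_real_, p_logrank = NA_real_,
                km = NULL, cindex = NA_real_))
  }
  hrfit <- cox_hr_binary(ifelse(groups == "high", "high", "low"), al$cohort)
  lr <- logrank_test(groups, al$cohort)
  km <- lapply(split(al$cohort, groups), km_curve)
  ci <- concordance_index(as.numeric(groups == "high"), al$cohort)
  list(groups = groups, group_sizes = sizes, hr = hrfit$hr, ci95 = hrfit$ci95,
       logrank_chi2 = lr$chi2, p_cox = hrfit$p, p_logrank = lr$p,
       km = km, cindex = ci)
}

#' Write a signature as JSON
#'
#' Schema: `{"rules": [{"gene_hi": ..., "gene_lo": ..., "beta": ..., "p": ...,
#' "q": ...}], "vote_rule": "at_least_half_sensitive_low"}`.
#'
#' @param signature [pair_signature()].
#' @param path output file path.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "pair_signature"))
  jsonlite::write_json(list(rules = signature$rules,
                            vote_rule = signature$vote_rule),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a signature from JSON
#' @param path file path written by [write_signature()].
#' @return [pair_signature()].
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- pair_signature(as.data.frame(obj$rules, stringsAsFactors = FALSE))
  if (!is.null(obj$vote_rule) && !identical(obj$vote_rule, sig$vote_rule)) {
    stop("unsupported vote rule: ", obj$vote_rule)
  }
  sig
}
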