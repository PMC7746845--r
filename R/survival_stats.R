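# Survival-analysis primitives: univariate Cox screening, BH adjustment,
# Harrell's C-index, log-rank test, Kaplan-Meier curve, binary hazard ratio.
#
# Cox fits, the log-rank test and the product-limit estimator are delegated to
# the survival package (Efron tie handling, the field's default); the C-index
# is implemented here because its comparability rule (pair comparable iff
# t_i < t_j and event_i = 1; risk ties contribute 0.5) is part of the
# signature-selection contract.

#' Univariate Cox proportional-hazards fit
#'
#' Wald inference from the Efron partial likelihood. A constant covariate is
#' degenerate: `beta = 0`, `p = 1`, `converged = FALSE`. Monotone likelihood
#' (separation) is flagged when `|beta| > 15`: the fit is marked
#' non-converged, `beta` is clamped to `sign(beta) * 15` and `p` set to `NA`
#' so screening can exclude it.
#'
#' @param x numeric covariate, one value per cohort sample (in cohort order).
#' @param cohort data.frame sample/time/event with >= 1 event.
#' @return list of class `cox_fit`: beta, se, z, p, converged, reason.
#' @export
cox_univariate <- function(x, cohort) {
  validate_cohort(cohort, require_event = TRUE)
  if (length(x) != nrow(cohort)) {
    stop("covariate length ", length(x), " does not match cohort size ", nrow(cohort))
  }
  if (!all(is.finite(x))) stop("covariate contains non-finite values")
  if (var(x) == 0) {
    return(structure(list(beta = 0, se = NA_real_, z = NA_real_, p = 1,
                          converged = FALSE, reason = "degenerate"),
                     class = "cox_fit"))
  }
  fit <- suppressWarnings(
    coxph(Surv(cohort$time, cohort$event) ~ x, ties = "efron",
          control = coxph.control(iter.max = 50, eps = 1e-9)))
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || abs(beta) > 15) {
    return(structure(list(beta = sign(beta) * 15, se = se, z = NA_real_,
                          p = NA_real_, converged = FALSE,
                          reason = "separation"),
                     class = "cox_fit"))
  }
  z <- beta / se
  structure(list(beta = beta, se = se, z = z, p = 2 * pnorm(-abs(z)),
                 converged = TRUE, reason = "ok"),
            class = "cox_fit")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted values, order-preserving with the input.
#' @export
bh_adjust <- function(p) {
  if (!all(is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-gene univariate Cox screening with FDR control
#'
#' Fits [cox_univariate()] for every gene, BH-adjusts the Wald p-values across
#' all converged genes, and returns both the full table and the signed list of
#' genes with `q < fdr` (sign of beta: +1 = expression increases hazard).
#' Degenerate / separated genes are excluded from the BH family and logged.
#'
#' @param expr expression matrix (genes x samples).
#' @param cohort data.frame sample/time/event (joined to `expr` by sample id).
#' @param fdr q-value cutoff in (0, 1].
#' @return list with `table` (data.frame gene/beta/se/p/q) and `genes`
#'   (signed gene list).
#' @export
screen_survival_genes <- function(expr, cohort, fdr = 0.2) {
  stopifnot(fdr > 0, fdr <= 1)
  validate_expression_matrix(expr)
  al <- align_cohort(expr, cohort)
  fits <- lapply(seq_len(nrow(al$expr)),
                 function(i) cox_univariate(al$expr[i, ], al$cohort))
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (any(!ok)) {
    log_msg("screen_survival_genes: excluded %d degenerate/separated gene(s)", sum(!ok))
  }
  tab <- data.frame(gene = rownames(al$expr),
                    beta = vapply(fits, `[[`, numeric(1), "beta"),
                    se = vapply(fits, `[[`, numeric(1), "se"),
                    p = vapply(fits, `[[`, numeric(1), "p"),
                    q = NA_real_, stringsAsFactors = FALSE, row.names = NULL)
  tab$q[ok] <- bh_adjust(tab$p[ok])
  keep <- ok & !is.na(tab$q) & (if (fdr >= 1) TRUE else tab$q < fdr) & tab$beta != 0
  list(table = tab,
       genes = signed_gene_list(tab$gene[keep], ifelse(tab$beta[keep] > 0, 1L, -1L)))
}

#' Harrell's concordance index
#'
#' A pair `(i, j)` is comparable iff `t_i < t_j` and sample `i` had the event;
#' it is concordant when `risk_i > risk_j`; tied predicted risks contribute
#' 0.5. Returns `(concordant + 0.5 * ties) / comparable`.
#'
#' @param risk numeric predicted risk, one value per cohort sample.
#' @param cohort data.frame sample/time/event.
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(risk, cohort) {
  validate_cohort(cohort)
  if (length(risk) != nrow(cohort)) stop("risk length does not match cohort size")
  comp <- outer(cohort$time, cohort$time, `<`) & (cohort$event == 1)
  n_comp <- sum(comp)
  if (n_comp == 0) stop("no comparable pairs (need an event observed before another follow-up)")
  conc <- sum(comp & outer(risk, risk, `>`))
  ties <- sum(comp & outer(risk, risk, `==`))
  (conc + 0.5 * ties) / n_comp
}

#' Two-group log-rank test
#'
#' @param groups factor/character with two levels (e.g. "high"/"low"), one per
#'   cohort sample.
#' @param cohort data.frame sample/time/event with >= 1 event.
#' @return list with `chi2` (1 df statistic) and `p`.
#' @export
logrank_test <- function(groups, cohort) {
  validate_cohort(cohort, require_event = TRUE)
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L) stop("need exactly two non-empty groups")
  sd_ <- survdiff(Surv(cohort$time, cohort$event) ~ groups)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit curve
#'
#' @param cohort data.frame sample/time/event.
#' @return data.frame time / n_risk / n_event / survival (step-function table;
#'   survival starts at 1 and is non-increasing).
#' @export
km_curve <- function(cohort) {
  validate_cohort(cohort)
  fit <- survfit(Surv(cohort$time, cohort$event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Hazard ratio between two groups from a binary-covariate Cox model
#'
#' Fits [cox_univariate()] on the indicator `high = 1`; the 95% CI is
#' `exp(beta +/- 1.96 se)`.
#'
#' @param groups two-level grouping ("high"/"low"), one per cohort sample.
#' @param cohort data.frame sample/time/event.
#' @return list: hr, ci95 (length-2 vector), p, beta, se.
#' @export
cox_hr_binary <- function(groups, cohort) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L) stop("need exactly two non-empty groups")
  if (!all(groups %in% c("high", "low"))) stop("groups must be 'high'/'low'")
  fit <- cox_univariate(as.numeric(groups == "high"), cohort)
  list(hr = exp(fit$beta),
       ci95 = exp(fit$beta + c(-1.96, 1.96) * fit$se),
       p = fit$p, beta = fit$beta, se = fit$se)
}
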