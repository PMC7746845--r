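test_that("degenerate and antisymmetric Cox cases behave as specified", {
  coh <- tiny_cohort(c(2, 4, 6, 8), c(1, 1, 1, 1))
  flat <- cox_univariate(rep(3, 4), coh)
  expect_false(flat$converged)
  expect_equal(flat$beta, 0)
  expect_equal(flat$p, 1)
  expect_equal(flat$reason, "degenerate")

  x <- c(0.5, 1.0, -0.5, -1.0)
  f1 <- cox_univariate(x, coh)
  f2 <- cox_univariate(-x, coh)
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-8)
  expect_equal(f2$p, f1$p, tolerance = 1e-8)
})

test_that("cox_univariate matches the Efron partial-likelihood grid oracle", {
  fixtures <- list(
    list(time = c(2, 4, 6, 8), event = c(1, 1, 1, 1),
         x = c(0.5, 1.0, -0.5, -1.0)),
    list(time = c(1, 3, 3, 5, 7, 9), event = c(1, 1, 0, 1, 0, 1),
         x = c(1.2, -0.3, 0.8, 0.1, -1.0, -0.6)),
    list(time = c(2, 2, 5, 5, 8, 9), event = c(1, 1, 1, 1, 1, 0),
         x = c(0.9, 0.4, -0.2, 0.7, -1.1, 0.3)))  # tied event times
  for (fx in fixtures) {
    coh <- tiny_cohort(fx$time, fx$event)
    fit <- cox_univariate(fx$x, coh)
    oracle <- cox_grid_oracle(fx$x, fx$time, fx$event)
    expect_lt(abs(fit$beta - oracle), 1e-3)
  }
})

test_that("separation is flagged rather than reported as a finite effect", {
  coh <- tiny_cohort(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 1, 1, 1))
  x <- c(1, 1, 1, 0, 0, 0)   # perfectly orders events
  fit <- cox_univariate(x, coh)
  expect_false(fit$converged)
  expect_true(is.na(fit$p))
})

test_that("BH adjustment matches the hand step-up calculation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.9, 0.001, 0.5, 0.04)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the concordance index matches closed forms and the brute-force loop", {
  coh <- tiny_cohort(c(1, 2, 3), c(1, 1, 1))
  expect_equal(concordance_index(c(3, 2, 1), coh), 1.0)
  expect_equal(concordance_index(c(5, 5, 5), coh), 0.5)

  coh4 <- tiny_cohort(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_equal(concordance_index(c(4, 1, 3, 2), coh4), 3 / 5)

  set.seed(21)
  for (i in 1:10) {
    time <- sample(1:20, 8)
    event <- rbinom(8, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    risk <- sample(c(rnorm(6), 0, 0))
    coh8 <- tiny_cohort(time, event)
    expect_equal(concordance_index(risk, coh8),
                 cindex_brute(risk, time, event))
  }
})

test_that("C-index of a tie-free risk vector complements under negation", {
  set.seed(31)
  time <- rexp(12) + 0.1
  event <- rbinom(12, 1, 0.8)
  event[1] <- 1
  risk <- rnorm(12)
  coh <- tiny_cohort(time, event)
  expect_equal(concordance_index(risk, coh), 1 - concordance_index(-risk, coh))
})

test_that("log-rank test is symmetric, null under identical groups, and matches the O-E oracle", {
  coh <- tiny_cohort(c(1, 2, 3, 1, 2, 3), c(1, 0, 1, 1, 0, 1))
  same <- rep(c("high", "low"), each = 3)
  lr <- logrank_test(same, coh)
  expect_lt(lr$chi2, 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-10)

  coh6 <- tiny_cohort(c(1, 2, 4, 5, 7, 9), c(1, 1, 1, 0, 1, 1))
  g <- c("high", "high", "low", "high", "low", "low")
  lr1 <- logrank_test(g, coh6)
  lr2 <- logrank_test(ifelse(g == "high", "low", "high"), coh6)
  expect_equal(lr1$chi2, lr2$chi2)
  expect_equal(lr1$chi2, logrank_oracle(g, coh6$time, coh6$event),
               tolerance = 1e-8)
  expect_error(logrank_test(rep("high", 6), coh6), "two")
})

test_that("Kaplan-Meier tables reproduce closed-form steps", {
  none <- km_curve(tiny_cohort(c(2, 5, 9), c(0, 0, 0)))
  expect_true(all(none$survival == 1))

  two <- km_curve(tiny_cohort(c(1, 2), c(1, 1)))
  expect_equal(two$survival, c(0.5, 0))

  tail_cens <- km_curve(tiny_cohort(c(1, 2, 3, 4), c(1, 0, 0, 0)))
  expect_equal(tail_cens$survival[1], 0.75)
  expect_true(all(tail_cens$survival[-1] == 0.75))
})

test_that("binary hazard ratios invert exactly under group swap and reject one group", {
  set.seed(13)
  coh <- tiny_cohort(rexp(40) + 0.01, rbinom(40, 1, 0.8))
  g <- rep(c("high", "low"), 20)
  h1 <- cox_hr_binary(g, coh)
  h2 <- cox_hr_binary(ifelse(g == "high", "low", "high"), coh)
  expect_equal(h2$hr, 1 / h1$hr, tolerance = 1e-6)
  expect_error(cox_hr_binary(rep("high", 40), coh), "two")
})

test_that("a null cohort yields a near-unit hazard ratio between arbitrary groups", {
  tis <- simulate_tissue(tissue_sim_config(1, 200, seed = 3))
  set.seed(derive_seed(3, 7))
  grp <- sample(rep(c("high", "low"), 100))
  hr <- cox_hr_binary(grp, tis$cohort)
  expect_lt(abs(log(hr$hr)), 0.3)
})

test_that("survival-gene screening recovers strong planted effects with correct signs", {
  genes <- sprintf("g%05d", 1:20)
  bm <- setNames(rep(c(1, -1), 10), genes)
  tis <- simulate_tissue(tissue_sim_config(300, 300, beta_map = bm,
                                           seed = derive_seed(1, 201)))
  scr <- suppressMessages(screen_survival_genes(tis$expr, tis$cohort, 0.2))
  hits <- intersect(names(scr$genes), genes)
  expect_gte(length(hits), 12L)
  # every recovered planted gene carries the planted sign
  expect_true(all(scr$genes[hits] == sign(bm[hits])))
  # false positives among the 280 null genes stay rare
  expect_lte(length(setdiff(names(scr$genes), genes)), 8L)
})

test_that("screening at FDR 1 returns every non-degenerate gene", {
  tis <- simulate_tissue(tissue_sim_config(20, 60, seed = 9))
  scr <- suppressMessages(screen_survival_genes(tis$expr, tis$cohort, 1))
  expect_length(scr$genes, 20L)
})

test_that("null survival screens stay near-empty at FDR 0.2", {
  frac <- vapply(1:10, function(s) {
    tis <- simulate_tissue(tissue_sim_config(200, 100, seed = s))
    length(suppressMessages(
      screen_survival_genes(tis$expr, tis$cohort, 0.2))$genes) / 200
  }, numeric(1))
  expect_lte(mean(frac), 0.02)
})
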