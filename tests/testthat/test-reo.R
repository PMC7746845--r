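test_that("pair indicators implement the strict-order tie rule and rank invariance", {
  expr <- tiny_expr(c(5, 2, 3, 3, 1, 4), c("A", "B", "C"), c("s1", "s2"))
  expect_equal(unname(pair_indicator(expr, "A", "B")), c(1L, 0L))
  expect_equal(unname(pair_indicator(expr, "B", "C")), c(1L, 0L))  # tie in s1 -> 0? B=3,C=1 s1; B=3,C=4 s2
  expect_equal(unname(pair_indicator(expr, "A", "C")), c(1L, 0L))
  tied <- tiny_expr(c(2, 2), c("A", "B"), "s1")
  expect_equal(unname(pair_indicator(tied, "A", "B")), 0L)
  expect_error(pair_indicator(expr, "A", "Z"), "Z")

  # strictly increasing per-sample transforms leave the indicator unchanged
  set.seed(2)
  x <- matrix(rnorm(40, 7), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  y <- x
  for (j in 1:10) y[, j] <- exp(0.3 * j * x[, j]) + j
  for (pair in list(c("g1", "g2"), c("g3", "g4"))) {
    expect_identical(pair_indicator(x, pair[1], pair[2]),
                     pair_indicator(y, pair[1], pair[2]))
  }
})

test_that("screen_pairs builds all pairs, drops constant indicators, and orients rules", {
  fx <- planted_pair_fixture()
  scr <- suppressMessages(screen_pairs(fx$train$expr, fx$train$cohort,
                                       fx$candidates, fdr = 0.10))
  expect_equal(scr$set1_size, choose(4, 2))
  expect_true(all(scr$set2$beta > 0))
  expect_true(all(c("g00001>g00002", "g00003>g00004") %in%
                    paste(scr$set2$gene_hi, scr$set2$gene_lo, sep = ">")))

  # a gene pair with a constant indicator never reaches Set 2
  expr <- rbind(fx$train$expr[1:3, ],
                always_low = min(fx$train$expr) - 1)
  scr2 <- suppressMessages(screen_pairs(expr, fx$train$cohort,
                                        c("g00001", "g00002", "always_low"),
                                        fdr = 1))
  keys <- paste(pmin(scr2$set2$gene_hi, scr2$set2$gene_lo),
                pmax(scr2$set2$gene_hi, scr2$set2$gene_lo))
  expect_false(any(grepl("always_low", keys)))
  expect_equal(scr2$n_constant, 2L)
})

test_that("majority voting classifies by the at-least-half sensitive rule", {
  rules <- data.frame(gene_hi = c("A", "C"), gene_lo = c("B", "D"),
                      stringsAsFactors = FALSE)
  sig <- pair_signature(rules)
  # s1: both rules risky; s2: one risky; s3: none risky
  expr <- tiny_expr(c(5, 5, 1,
                      1, 1, 5,
                      5, 1, 1,
                      1, 5, 5), c("A", "B", "C", "D"), c("s1", "s2", "s3"))
  cls <- vote_classify(expr, sig)
  expect_equal(as.character(cls), c("high", "low", "low"))
})

test_that("re-orienting an input rule leaves classification unchanged after normalisation", {
  fwd <- pair_signature(data.frame(gene_hi = c("A", "C"), gene_lo = c("B", "D"),
                                   beta = c(0.8, 0.5), stringsAsFactors = FALSE))
  rev <- pair_signature(data.frame(gene_hi = c("B", "C"), gene_lo = c("A", "D"),
                                   beta = c(-0.8, 0.5), stringsAsFactors = FALSE))
  set.seed(4)
  expr <- matrix(rnorm(40, 7), nrow = 4,
                 dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:10)))
  expect_identical(vote_classify(expr, fwd), vote_classify(expr, rev))
})

test_that("signatures reject degenerate rule sets and round trip through JSON", {
  expect_error(pair_signature(data.frame(gene_hi = "A", gene_lo = "A")),
               "distinct")
  expect_error(pair_signature(data.frame(gene_hi = c("A", "B"),
                                         gene_lo = c("B", "A"))),
               "duplicated")
  sig <- pair_signature(data.frame(gene_hi = c("A", "C"), gene_lo = c("B", "D"),
                                   beta = c(1.2, 0.4), p = c(1e-5, 1e-3),
                                   q = c(1e-4, 1e-2), stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$rules, sig$rules)
  expect_equal(back$vote_rule, sig$vote_rule)
})

test_that("the optimizer returns the single rule when Set 2 has one member", {
  fx <- planted_pair_fixture()
  scr <- suppressMessages(screen_pairs(fx$train$expr, fx$train$cohort,
                                       fx$candidates, fdr = 0.10))
  one <- scr$set2[1, , drop = FALSE]
  opt <- suppressMessages(optimize_combination(one, fx$train$expr, fx$train$cohort))
  expect_equal(opt$signature$rules$gene_hi, one$gene_hi)
  expect_equal(opt$n_subsets, 1L)
  groups <- vote_classify(fx$train$expr, opt$signature)
  expect_equal(opt$cindex,
               concordance_index(as.numeric(groups == "high"), fx$train$cohort))
})

test_that("exhaustive optimisation agrees with the naive subset-loop oracle", {
  for (master in 1:5) {
    fx <- planted_pair_fixture(master, n_samples = 60L)
    scr <- suppressMessages(screen_pairs(fx$train$expr, fx$train$cohort,
                                         fx$candidates, fdr = 1))
    set2 <- utils::head(scr$set2, 6L)
    opt <- suppressMessages(optimize_combination(set2, fx$train$expr, fx$train$cohort))
    oracle <- naive_optimize(set2, fx$train$expr, fx$train$cohort)
    expect_equal(opt$cindex, oracle$cindex, tolerance = 1e-12)
    expect_equal(pair_key(opt$signature$rules), pair_key(set2[oracle$idx, ]))
    expect_equal(opt$n_subsets, n_enumerable_subsets(nrow(set2)))
  }
})

test_that("the planted two-pair signature is recovered exactly and validates", {
  fx <- planted_pair_fixture()
  scr <- suppressMessages(screen_pairs(fx$train$expr, fx$train$cohort,
                                       fx$candidates, fdr = 0.10))
  opt <- suppressMessages(optimize_combination(scr, fx$train$expr, fx$train$cohort))
  expect_equal(pair_key(opt$signature$rules),
               c("g00001>g00002", "g00003>g00004"))
  expect_gt(opt$cindex, 0.55)
  ev <- evaluate_signature(opt$signature, fx$validation$expr, fx$validation$cohort)
  expect_gt(ev$hr, 2)
  expect_lt(ev$p_logrank, 0.01)
})

test_that("subset enumeration counts and guards are correct", {
  expect_equal(n_enumerable_subsets(20), 2^20 - 1)
  expect_equal(n_enumerable_subsets(3), 7)
  expect_equal(n_enumerable_subsets(5, max_size = 2), 5 + 10)
  big <- data.frame(gene_hi = paste0("a", 1:21), gene_lo = paste0("b", 1:21),
                    beta = 1, p = 0.001, q = 0.01, stringsAsFactors = FALSE)
  expect_error(optimize_combination(big, tiny_expr(1, "x", "s1"),
                                    tiny_cohort(1, 1)),
               "refusing")
})

test_that("greedy forward selection finds the planted pair set", {
  fx <- planted_pair_fixture()
  scr <- suppressMessages(screen_pairs(fx$train$expr, fx$train$cohort,
                                       fx$candidates, fdr = 0.10))
  greedy <- suppressMessages(optimize_combination(scr, fx$train$expr,
                                                  fx$train$cohort,
                                                  method = "greedy"))
  exhaustive <- suppressMessages(optimize_combination(scr, fx$train$expr,
                                                      fx$train$cohort))
  expect_lte(greedy$cindex, exhaustive$cindex + 1e-12)
  expect_gt(greedy$cindex, 0.55)
})

test_that("evaluating a signature on a cohort without both groups degrades gracefully", {
  sig <- pair_signature(data.frame(gene_hi = "A", gene_lo = "B"))
  expr <- tiny_expr(c(5, 6, 7, 1, 2, 3), c("A", "B"), paste0("s", 1:3))
  coh <- tiny_cohort(c(1, 2, 3), c(1, 1, 0), samples = paste0("s", 1:3))
  expect_warning(ev <- evaluate_signature(sig, expr, coh), "one risk group")
  expect_true(is.na(ev$hr))
  expect_equal(sum(ev$group_sizes), 3)

  missing_sig <- pair_signature(data.frame(gene_hi = "A", gene_lo = "ZZ"))
  expect_error(evaluate_signature(missing_sig, expr, coh), "ZZ")
})

test_that("monotone per-sample transforms leave Set 2, the signature, and risk calls identical", {
  fx <- planted_pair_fixture()
  expr <- fx$train$expr
  warped <- expr
  set.seed(77)
  for (j in seq_len(ncol(expr))) {
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    warped[, j] <- a * expr[, j]^3 + b   # strictly increasing (values > 0)
  }
  scr1 <- suppressMessages(screen_pairs(expr, fx$train$cohort, fx$candidates))
  scr2 <- suppressMessages(screen_pairs(warped, fx$train$cohort, fx$candidates))
  expect_equal(scr1$set2, scr2$set2)
  opt1 <- suppressMessages(optimize_combination(scr1, expr, fx$train$cohort))
  opt2 <- suppressMessages(optimize_combination(scr2, warped, fx$train$cohort))
  expect_equal(opt1$signature$rules, opt2$signature$rules)
  expect_identical(vote_classify(expr, opt1$signature),
                   vote_classify(warped, opt1$signature))
})
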