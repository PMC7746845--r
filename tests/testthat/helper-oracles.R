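# Independent brute-force oracles and tiny fixture builders used across the
# suite. Everything here is deliberately naive: enumeration, grid search and
# direct summation, sharing no code with the implementation under test.

tiny_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

tiny_cohort <- function(time, event, samples = sprintf("s%02d", seq_along(time))) {
  data.frame(sample = samples, time = time, event = event,
             stringsAsFactors = FALSE)
}

# Exact binomial upper tail by direct summation of the pmf (n small).
binom_tail_naive <- function(n, k) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * 0.5^n, numeric(1)))
}

# Hypergeometric upper tail by enumerating every draw of n items from N.
hyper_tail_enum <- function(N, n, m, k) {
  draws <- combn(N, n)
  in_set <- colSums(draws <= m)  # set = items 1..m
  mean(in_set >= k)
}

# Harrell C by an explicit double loop over ordered pairs.
cindex_brute <- function(risk, time, event) {
  num <- 0; den <- 0
  for (i in seq_along(time)) {
    for (j in seq_along(time)) {
      if (event[i] == 1 && time[i] < time[j]) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# Efron partial log-likelihood for a single covariate, then a grid search.
efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    er <- sum(exp(beta * x[r_idx]))
    ed <- sum(exp(beta * x[d_idx]))
    ll <- ll + beta * sum(x[d_idx])
    for (l in seq_len(d) - 1L) ll <- ll - log(er - (l / d) * ed)
  }
  ll
}

cox_grid_oracle <- function(x, time, event, lo = -5, hi = 5) {
  grid <- seq(lo, hi, by = 1e-3)
  ll <- vapply(grid, efron_loglik, numeric(1), x = x, time = time, event = event)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-5)
  llf <- vapply(fine, efron_loglik, numeric(1), x = x, time = time, event = event)
  fine[which.max(llf)]
}

# Two-group log-rank chi-square by direct O-E/V accumulation over event times.
logrank_oracle <- function(groups, time, event) {
  g1 <- groups == unique(groups)[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Naive subset-enumeration optimiser: vote counting and C-index computed from
# first principles (no shared code with optimize_combination).
naive_optimize <- function(set2, expr, cohort, max_size = Inf) {
  m <- nrow(set2)
  best <- NULL; best_c <- -Inf
  for (size in seq_len(min(m, max_size))) {
    for (cols in combn(m, size, simplify = FALSE)) {
      risk <- vapply(seq_len(ncol(expr)), function(s) {
        sens <- 0L
        for (i in cols) {
          if (!(expr[set2$gene_hi[i], s] > expr[set2$gene_lo[i], s])) sens <- sens + 1L
        }
        as.numeric(sens < size / 2)   # high risk iff sensitive votes below half
      }, numeric(1))
      cc <- cindex_brute(risk, cohort$time, cohort$event)
      if (cc > best_c) { best_c <- cc; best <- cols }
    }
  }
  list(idx = best, cindex = best_c)
}

# Planted 2-pair signature fixture used by the REO recovery tests: the
# signature's majority-vote high-risk group carries a true log HR of log(4).
planted_pair_fixture <- function(master_seed = 1L, n_samples = 250L) {
  ps <- list(pairs = data.frame(gene_hi = c("g00001", "g00003"),
                                gene_lo = c("g00002", "g00004"),
                                stringsAsFactors = FALSE),
             beta = log(4))
  train_cfg <- tissue_sim_config(30, n_samples, planted_signature = ps,
                                 seed = derive_seed(master_seed, 300L))
  val_cfg <- tissue_sim_config(30, n_samples, planted_signature = ps,
                               seed = derive_seed(master_seed, 401L))
  list(planted = ps, train = simulate_tissue(train_cfg),
       validation = simulate_tissue(val_cfg),
       candidates = sprintf("g%05d", 1:4))
}

pair_key <- function(rules) sort(paste(rules$gene_hi, rules$gene_lo, sep = ">"))
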