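# Independent oracles used across the suite. These deliberately use naive,
# loop-heavy formulations (or a different library) so they share no code
# with the package implementation they check.

# Naive Efron log partial likelihood: direct double loop over death times.
efron_loglik_naive <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- which(time >= t)
    tied <- which(time == t & event == 1)
    d <- length(tied)
    r0 <- sum(exp(beta * x[risk]))
    t0 <- sum(exp(beta * x[tied]))
    ll <- ll + beta * sum(x[tied])
    for (l in seq_len(d)) ll <- ll - log(r0 - (l - 1) / d * t0)
  }
  ll
}

# Brute-force maximizer of the naive likelihood over a wide bracket.
cox_beta_bruteforce <- function(time, event, x, lower = -8, upper = 8) {
  stats::optimize(function(b) efron_loglik_naive(b, time, event, x),
                  lower = lower, upper = upper, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Literal step-up BH definition: q_i = min_{j >= i} p_(j) * m / j.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i)
    min(ps[i:m] * m / (i:m)), numeric(1))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Hypergeometric upper tail by full enumeration with choose().
hyper_tail_enum <- function(k, K, N, n) {
  kmax <- min(K, n)
  total <- choose(N, n)
  sum(vapply(k:kmax, function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / total
}

# Small reproducible survival dataset without ties.
random_survival_data <- function(n, seed, true_beta = 0.5) {
  set.seed(seed)
  x <- stats::rnorm(n)
  tm <- stats::rexp(n, rate = 0.3 * exp(true_beta * x))
  cens <- stats::rexp(n, rate = 0.15)
  while (any(duplicated(pmin(tm, cens)))) tm <- tm + stats::runif(n, 0, 1e-9)
  list(time = pmin(tm, cens), event = as.numeric(tm <= cens), x = x)
}

# Tiny expression matrix builder.
toy_expr <- function(values, scale = "log2_tpm",
                     genes = paste0("g", seq_len(nrow(values))),
                     samples = paste0("s", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, scale = scale)
}
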