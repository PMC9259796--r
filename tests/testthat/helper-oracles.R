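# Independent oracles: deliberately naive re-derivations (double loops,
# grids, exhaustive enumeration) kept separate from the package's
# implementations so the two routes can disagree.

# Harrell's C by explicit pair enumeration: comparable iff the strictly
# shorter observed time ends in an event; risk ties score 0.5.
oracle_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Efron partial log-likelihood for one covariate, transcribed with plain
# loops over risk sets.
oracle_efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + beta * sum(x[D])
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    for (l in seq_len(d) - 1)
      ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# Dense grid maximizer of the Efron partial likelihood: coarse pass over
# [-5, 5] then a fine pass at step 1e-4.
oracle_cox_beta_grid <- function(x, time, event) {
  coarse <- seq(-5, 5, by = 0.01)
  ll <- vapply(coarse, oracle_efron_loglik, numeric(1), x = x, time = time,
               event = event)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  llf <- vapply(fine, oracle_efron_loglik, numeric(1), x = x, time = time,
                event = event)
  fine[which.max(llf)]
}

# Two-group log-rank by direct O/E/V tabulation over event times.
oracle_logrank_chisq <- function(time, event, groups) {
  lev <- sort(unique(groups))
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & groups == lev[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & groups == lev[1])
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Total within-cluster sum of squares of the best 2-partition of a point
# set, by exhaustive enumeration.
oracle_best_wss_k2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {    # fix point 1 in cluster 0
    g <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (!any(g) || all(g)) next
    wss <- 0
    for (side in list(g, !g)) {
      ctr <- colMeans(X[side, , drop = FALSE])
      wss <- wss + sum(sweep(X[side, , drop = FALSE], 2, ctr, "-")^2)
    }
    best <- min(best, wss)
  }
  best
}

# Small random survival fixture generator used across tests.
make_fixture <- function(n, seed, cens = 0.3, ties = FALSE) {
  withr::with_seed(seed, {
    time <- if (ties) sample(1:5, n, replace = TRUE) else rexp(n, 0.3)
    event <- as.integer(runif(n) > cens)
    if (sum(event) < 2) event[1:2] <- 1L
    clinical_table(sprintf("P%03d", seq_len(n)), time, event)
  })
}

# Transcription of the penalized autoencoder objective for a hand-checkable
# fixture, written without reusing any package internals.
oracle_ae_loss <- function(W, b, X, l1, l2, aa) {
  a <- X
  acts <- list()
  for (i in 1:3) {
    a <- tanh(sweep(a %*% W[[i]], 2, b[[i]], "+"))
    acts[[i]] <- a
  }
  xh <- 1 / (1 + exp(-sweep(a %*% W[[4]], 2, b[[4]], "+")))
  acts[[4]] <- xh
  xh <- pmin(pmax(xh, 1e-7), 1 - 1e-7)
  ll <- -sum(X * log(xh) + (1 - X) * log(1 - xh)) / nrow(X)
  wpen <- sum(sapply(W, function(w) l1 * sum(abs(w)) + l2 * sum(w^2)))
  apen <- aa * sum(sapply(acts, function(a) sum(a^2))) / nrow(X)
  ll + wpen + apen
}

# Tiny trained-shape model fixture for the autoencoder tests.
tiny_ae <- function(input_dim = 5, hidden = c(4, 2, 4), seed = 1) {
  init_autoencoder(input_dim,
                   ae_config(bottleneck = hidden[2], hidden_sizes = hidden,
                             epochs = 3, batch_size = 4, seed = seed))
}

# Adjusted Rand index between two partitions (contingency-table formula).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

expect_no_condition <- function(expr) expect_error(expr, NA)
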