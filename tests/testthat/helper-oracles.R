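# Independent oracles coded from first principles, kept deliberately naive
# (explicit loops over risk sets) so they share nothing with the package's
# vectorised implementations.

# Cox log partial likelihood by direct evaluation of the definition.
oracle_cox_loglik <- function(time, event, x, beta, ties = "efron") {
  x <- as.matrix(x)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    wr <- exp(drop(x[R, , drop = FALSE] %*% beta))
    wd <- exp(drop(x[D, , drop = FALSE] %*% beta))
    d <- length(D)
    ll <- ll + sum(x[D, , drop = FALSE] %*% beta)
    if (ties == "breslow") {
      ll <- ll - d * log(sum(wr))
    } else {
      for (k in seq_len(d) - 1) ll <- ll - log(sum(wr) - (k / d) * sum(wd))
    }
  }
  ll
}

# Two-group log-rank O, E, V by explicit risk-set tables.
oracle_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2)
  event <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, statistic = (O - E)^2 / V)
}

# Spearman rho as rank-then-Pearson with the textbook product-moment formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Schoenfeld residuals + Grambsch-Therneau correlation statistics by loops.
oracle_zph <- function(time, event, x, beta, V, gt) {
  x <- as.matrix(x)
  p <- ncol(x)
  dt <- sort(time[event == 1])
  res <- matrix(NA_real_, length(dt), p)
  r <- 1L
  for (t in unique(dt)) {
    R <- which(time >= t)
    w <- exp(drop(x[R, , drop = FALSE] %*% beta))
    xbar <- colSums(x[R, , drop = FALSE] * w) / sum(w)
    for (i in which(event == 1 & time == t)) {
      res[r, ] <- x[i, ] - xbar
      r <- r + 1L
    }
  }
  d <- length(dt)
  gc <- gt - mean(gt)
  w <- drop(t(res) %*% gc)
  vw <- drop(V %*% w)
  list(
    residuals = res,
    per = d * vw^2 / (diag(V) * sum(gc^2)),
    global = d * sum(w * vw) / sum(gc^2)
  )
}

# Small helper: simulated records under a single-lab reduced design.
small_design <- function(flies_per_cell = 30L, seed = 1L, ...) {
  sim_params(
    n_labs = 1L, n_cohorts = 2L,
    genotypes = c("gA", "gB"), flies_per_cell = flies_per_cell,
    seed = seed, ...
  )
}
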