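#' Two-group log-rank test
#'
#' At each distinct event time the observed number of deaths in group 1 is
#' compared with its hypergeometric expectation given the margins of the
#' 2 x 2 risk-set table; the sums O, E and hypergeometric variance V give
#' the statistic (O - E)^2 / V, referred to a chi-square with 1 df. This is
#' the score test of the Cox model at beta = 0 for the group indicator
#' (Breslow ties), a property the test-suite exercises.
#'
#' @param group1,group2 `data.frame`s with `time_days` and `event` columns
#'   (see [km_estimate()]).
#' @return An object of class `"logrank_test"`: `observed`, `expected`,
#'   `variance` (all accumulated for group 1), `statistic`, `p_value`,
#'   `n`, `n_events`, and `degenerate` (TRUE when the variance is zero, in
#'   which case the statistic is defined as 0 with p = 1).
#' @examples
#' g1 <- data.frame(time_days = c(1, 2), event = 1)
#' g2 <- data.frame(time_days = c(3, 4), event = 1)
#' logrank_test(g1, g2)$statistic
#' @export
logrank_test <- function(group1, group2) {
  a <- .as_time_event(group1)
  b <- .as_time_event(group2)
  if (length(a$time) == 0L || length(b$time) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  time <- c(a$time, b$time)
  status <- c(a$event, b$event)
  grp <- rep(c(1L, 0L), c(length(a$time), length(b$time)))
  if (!any(status == 1L)) stop("no events in either group", call. = FALSE)

  ut <- sort(unique(time[status == 1L]))
  st <- sort(time)
  st1 <- sort(time[grp == 1L])
  n_tot <- length(time) - findInterval(ut, st, left.open = TRUE)
  n1 <- length(st1) - findInterval(ut, st1, left.open = TRUE)
  f <- factor(time[status == 1L], levels = ut)
  d_tot <- as.integer(rowsum(rep(1L, sum(status == 1L)), f))
  d1 <- as.integer(rowsum(as.integer(status == 1L & grp == 1L)[status == 1L], f))

  e1 <- d_tot * n1 / n_tot
  v <- ifelse(n_tot > 1,
              d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
                (n_tot - d_tot) / (n_tot - 1),
              0)
  O <- sum(d1); E <- sum(e1); V <- sum(v)
  degenerate <- V <= 0
  stat <- if (degenerate) 0 else (O - E)^2 / V
  p <- if (degenerate) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  out <- list(
    observed = O, expected = E, variance = V,
    statistic = stat, p_value = p,
    n = length(time), n_events = sum(status == 1L), degenerate = degenerate
  )
  class(out) <- "logrank_test"
  out
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-group log-rank test\n")
  cat(sprintf("  O = %.4g, E = %.4g, V = %.4g\n", x$observed, x$expected,
              x$variance))
  cat(sprintf("  chi-square(1) = %.4g, p = %.3g%s\n", x$statistic, x$p_value,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}
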