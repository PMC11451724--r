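#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric survival-curve estimate from right-censored times, with
#' Greenwood variance, the median lifespan (smallest event time with
#' S(t) <= 0.5) and a Brookmeyer-Crowley style 95% confidence interval for
#' the median obtained by inverting a log(-log) transformed pointwise band
#' at 0.5 (the convention behind R's `survfit(conf.type = "log-log")`).
#'
#' Ties between deaths and censorings at the same time follow the standard
#' risk-set convention: deaths precede censorings, i.e. a fly censored at
#' time t is still at risk for a death at t.
#'
#' @param records A `data.frame` with numeric `time_days` (>= 0) and binary
#'   `event` columns (1 = death, 0 = censored), e.g. rows of
#'   [simulate_lifespans()] output. Alternatively a numeric vector of times,
#'   with events supplied via `event`.
#' @param event Optional event indicator vector when `records` is a bare
#'   numeric time vector.
#' @param conf_level Confidence level for the pointwise band and median CI.
#' @return An object of class `"km_estimate"`: `times` (distinct event
#'   times), `survival`, `greenwood_var`, `n_risk`, `n_event`, `n_censor`,
#'   `median`, `median_ci`, `n`, `n_events`, and `all_censored` (TRUE when
#'   the input contained no deaths, in which case S is identically 1 and the
#'   median undefined — flagged, not an error).
#' @examples
#' km <- km_estimate(data.frame(time_days = 1:5, event = 1))
#' km$survival   # 0.8 0.6 0.4 0.2 0.0
#' km$median     # 3
#' @export
km_estimate <- function(records, event = NULL, conf_level = 0.95) {
  te <- .as_time_event(records, event)
  time <- te$time
  status <- te$event
  n <- length(time)
  if (n == 0L) stop("no observations", call. = FALSE)

  if (!any(status == 1L)) {
    out <- list(
      times = numeric(0), survival = numeric(0), greenwood_var = numeric(0),
      n_risk = integer(0), n_event = integer(0), n_censor = integer(0),
      median = NA_real_, median_ci = c(NA_real_, NA_real_),
      n = n, n_events = 0L, all_censored = TRUE, conf_level = conf_level
    )
    class(out) <- "km_estimate"
    return(out)
  }

  ut <- sort(unique(time[status == 1L]))
  # n at risk at t: everyone with observed time >= t
  st <- sort(time)
  n_risk <- n - findInterval(ut, st, left.open = TRUE)
  n_event <- as.integer(rowsum(rep(1L, sum(status == 1L)),
                               factor(time[status == 1L], levels = ut)))
  frac <- 1 - n_event / n_risk
  surv <- cumprod(frac)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d))); 0/0 when S hits 0
  gsum <- cumsum(ifelse(n_risk > n_event,
                        n_event / (n_risk * (n_risk - n_event)), NA_real_))
  gvar <- surv^2 * gsum
  gvar[surv == 0] <- NaN               # undefined once the curve hits 0

  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1L]] else NA_real_

  # log(-log) pointwise band, then invert at 0.5 for the median CI
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_ll <- rep(NA_real_, length(ut))
  ok <- surv > 0 & surv < 1 & is.finite(gsum)
  se_ll[ok] <- sqrt(gsum[ok]) / abs(log(surv[ok]))
  lcl <- ucl <- surv                     # 0 where S = 0: band has collapsed
  lcl[ok] <- surv[ok]^exp(z * se_ll[ok])
  ucl[ok] <- surv[ok]^exp(-z * se_ll[ok])
  ci_lo <- if (any(lcl <= 0.5, na.rm = TRUE)) {
    ut[which(lcl <= 0.5)[1L]]
  } else NA_real_
  ci_hi <- if (any(ucl <= 0.5, na.rm = TRUE)) {
    ut[which(ucl <= 0.5)[1L]]
  } else NA_real_
  # exposed band follows the survfit convention: undefined once S hits 0
  lcl[surv == 0] <- NA_real_
  ucl[surv == 0] <- NA_real_

  cens <- time[status == 0L]
  n_censor <- if (length(cens)) {
    # censorings in [t_j, t_{j+1})
    as.integer(table(cut(cens, c(ut, Inf), right = FALSE,
                         include.lowest = FALSE)))
  } else {
    integer(length(ut))
  }

  out <- list(
    times = ut, survival = surv, greenwood_var = gvar,
    n_risk = n_risk, n_event = n_event, n_censor = n_censor,
    median = med, median_ci = c(ci_lo, ci_hi),
    n = n, n_events = sum(status == 1L), all_censored = FALSE,
    conf_level = conf_level, lower = lcl, upper = ucl
  )
  class(out) <- "km_estimate"
  out
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate:", x$n, "subjects,", x$n_events, "events\n")
  if (x$all_censored) {
    cat("All observations censored; S(t) = 1 throughout, median undefined\n")
  } else {
    cat(sprintf("Median lifespan: %s days (%.0f%% CI %s-%s)\n",
                format(x$median), 100 * x$conf_level,
                format(x$median_ci[1]), format(x$median_ci[2])))
  }
  invisible(x)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to `tau`; used as the tie-break when
#' two arms have equal medians.
#'
#' @param km A [km_estimate()] object.
#' @param tau Upper integration limit (days).
#' @return Restricted mean in days.
#' @export
km_rmst <- function(km, tau) {
  if (km$all_censored) return(tau)
  tt <- c(0, km$times[km$times <= tau], tau)
  ss <- c(1, km$survival[km$times <= tau])
  sum(diff(tt) * ss)
}

# Coerce the two accepted input shapes to a (time, event) pair and validate.
.as_time_event <- function(records, event = NULL) {
  if (is.data.frame(records)) {
    if (!all(c("time_days", "event") %in% names(records))) {
      stop("`records` must have `time_days` and `event` columns",
           call. = FALSE)
    }
    time <- records$time_days
    status <- records$event
  } else {
    time <- records
    status <- event
    if (is.null(status)) stop("`event` must be supplied", call. = FALSE)
  }
  time <- as.numeric(time)
  status <- as.integer(status)
  if (length(time) != length(status)) {
    stop("time and event lengths differ", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and nonnegative", call. = FALSE)
  }
  if (!all(status %in% c(0L, 1L))) {
    stop("event indicator must be 0 or 1", call. = FALSE)
  }
  list(time = time, event = status)
}
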