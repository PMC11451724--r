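#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Cox log partial likelihood over treatment-coded indicators
#' of the requested categorical terms, with Efron's (default) or Breslow's
#' approximation for tied death times. Newton-Raphson with step-halving;
#' convergence when the gradient max-norm falls below `tol_grad` or the
#' relative log-likelihood change falls below `tol_loglik`.
#'
#' Monotone likelihood (perfect separation) is detected by diverging
#' coefficients and reported as `converged = FALSE` with a diagnostic
#' message — never silently. Rank-deficient designs raise an error naming
#' the collinear columns.
#'
#' @param records `data.frame` with `time_days`, `event` and one column per
#'   model term.
#' @param terms Character vector of covariate (column) names; each must be
#'   categorical with >= 2 observed levels.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param reference Optional named list/character vector giving the
#'   reference level per term; default is the first level in lexicographic
#'   order. The maximized log likelihood is invariant to this choice.
#' @param tol_grad,tol_loglik,max_iter Convergence controls.
#' @return Object of class `"cox_fit"`: `beta` (named log-hazard
#'   coefficients), `se`, `loglik`, `loglik_null`, `var` (inverse
#'   information), `covariate_spec`, `ties_method`, `n_subjects`,
#'   `n_events`, `converged`, `n_iter`, `message`.
#' @examples
#' rec <- simulate_lifespans(sim_params(flies_per_cell = 20L, seed = 3L))
#' fit <- cox_fit(rec, c("genotype", "sex"))
#' fit$beta
#' @export
cox_fit <- function(records, terms, ties = c("efron", "breslow"),
                    reference = NULL, tol_grad = 1e-9, tol_loglik = 1e-12,
                    max_iter = 50L) {
  ties <- match.arg(ties)
  te <- .as_time_event(records)
  if (!any(te$event == 1L)) stop("no events in the data", call. = FALSE)
  mm <- .cox_model_matrix(records, terms, reference)
  X <- mm$X
  if (ncol(X) == 0L) stop("model has no estimable coefficients", call. = FALSE)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear model terms: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  eng <- .cox_engine_setup(X, te$time, te$event, ties)
  p <- ncol(X)
  beta <- rep(0, p)
  cur <- .cox_engine_eval(eng, beta)
  loglik_null <- cur$loglik
  converged <- FALSE
  msg <- ""
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$info, cur$grad),
                     error = function(e) NULL)
    if (is.null(step)) {
      msg <- "singular information matrix"
      break
    }
    new_beta <- beta + step
    new <- .cox_engine_eval(eng, new_beta)
    halvings <- 0L
    while ((!is.finite(new$loglik) || new$loglik < cur$loglik) &&
           halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new <- .cox_engine_eval(eng, new_beta)
      halvings <- halvings + 1L
    }
    rel <- abs(new$loglik - cur$loglik) / (abs(cur$loglik) + 1)
    beta <- new_beta
    cur <- new
    if (max(abs(cur$grad)) < tol_grad || rel < tol_loglik) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 20) {
      msg <- paste0(
        "coefficients diverging (|beta| > 20): likely monotone ",
        "likelihood / perfect separation in ",
        paste(colnames(X)[abs(beta) > 20], collapse = ", ")
      )
      break
    }
  }
  if (!converged && msg == "") msg <- "iteration limit reached"

  V <- tryCatch(solve(cur$info), error = function(e) matrix(NA_real_, p, p))
  out <- list(
    beta = stats::setNames(beta, colnames(X)),
    se = sqrt(pmax(diag(V), 0)),
    loglik = cur$loglik, loglik_null = loglik_null,
    grad = cur$grad, info = cur$info, var = V,
    covariate_spec = mm$spec, ties_method = ties,
    n_subjects = length(te$time), n_events = sum(te$event == 1L),
    converged = converged, n_iter = iter, message = msg,
    engine = eng
  )
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): %d subjects, %d events\n",
              x$ties_method, x$n_subjects, x$n_events))
  tab <- data.frame(coef = x$beta, `exp(coef)` = exp(x$beta), se = x$se,
                    z = x$beta / x$se, check.names = FALSE)
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  print(round(tab, 4))
  cat(sprintf("log partial likelihood: %.4f (null %.4f); %s in %d iterations\n",
              x$loglik, x$loglik_null,
              if (x$converged) "converged" else paste("NOT converged:", x$message),
              x$n_iter))
  invisible(x)
}

#' Evaluate the Cox log partial likelihood, score and information
#'
#' Exposed for score tests and diagnostics: evaluates the Efron or Breslow
#' partial likelihood at an arbitrary coefficient vector.
#'
#' @inheritParams cox_fit
#' @param beta Coefficient vector (default all zero).
#' @return List with `loglik`, `grad` (score vector) and `info`
#'   (observed information matrix).
#' @export
cox_loglik <- function(records, terms, beta = NULL,
                       ties = c("efron", "breslow"), reference = NULL) {
  ties <- match.arg(ties)
  te <- .as_time_event(records)
  mm <- .cox_model_matrix(records, terms, reference)
  if (is.null(beta)) beta <- rep(0, ncol(mm$X))
  eng <- .cox_engine_setup(mm$X, te$time, te$event, ties)
  .cox_engine_eval(eng, beta)[c("loglik", "grad", "info")]
}

# ---- internals ------------------------------------------------------------

# Treatment-coded indicator matrix for categorical terms.
.cox_model_matrix <- function(records, terms, reference = NULL) {
  missing_terms <- setdiff(terms, names(records))
  if (length(missing_terms)) {
    stop("terms not found in data: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  spec <- list()
  cols <- list()
  for (tm in terms) {
    v <- as.character(records[[tm]])
    lev <- sort(unique(v))
    if (length(lev) < 2L) {
      stop("term `", tm, "` has fewer than 2 observed levels", call. = FALSE)
    }
    ref <- if (!is.null(reference) && !is.null(reference[[tm]])) {
      as.character(reference[[tm]])
    } else {
      lev[1L]
    }
    if (!ref %in% lev) {
      stop("reference level `", ref, "` not observed for term `", tm, "`",
           call. = FALSE)
    }
    others <- setdiff(lev, ref)
    m <- matrix(0, nrow = length(v), ncol = length(others),
                dimnames = list(NULL, paste0(tm, "=", others)))
    for (j in seq_along(others)) m[, j] <- as.numeric(v == others[j])
    spec[[tm]] <- list(levels = lev, reference = ref)
    cols[[tm]] <- m
  }
  list(X = do.call(cbind, cols), spec = spec)
}

# Precompute the sort order, risk-set indices and tied-death bookkeeping so
# repeated likelihood evaluations only do cumulative sums.
.cox_engine_setup <- function(X, time, event, ties) {
  o <- order(time)
  tt <- time[o]
  ev <- event[o]
  Xs <- X[o, , drop = FALSE]
  p <- ncol(X)
  dt <- tt[ev == 1L]
  ut <- unique(dt)                    # sorted: dt is sorted
  first <- match(ut, tt)              # first index with tt >= ut[j]
  g <- factor(dt, levels = ut)        # death -> unique-time group
  d <- as.integer(table(g))
  # expansion over (event time, k) pairs for the Efron correction
  idx <- rep(seq_along(ut), d)
  kf <- unlist(lapply(d, function(m) (seq_len(m) - 1) / m), use.names = FALSE)
  if (ties == "breslow") kf <- rep(0, length(kf))
  # column pairs for the second-moment matrix (upper triangle)
  pr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  list(Xs = Xs, ev = ev == 1L, p = p, first = first, g = g, d = d,
       idx = idx, kf = kf, pi1 = pr[, 1L], pi2 = pr[, 2L],
       death_x = Xs[ev == 1L, , drop = FALSE], ut = ut)
}

.revcumsum <- function(m) {
  if (is.matrix(m)) {
    m <- m[nrow(m):1L, , drop = FALSE]
    m <- apply(m, 2L, cumsum)
    m[nrow(m):1L, , drop = FALSE]
  } else {
    rev(cumsum(rev(m)))
  }
}

.cox_engine_eval <- function(eng, beta) {
  Xs <- eng$Xs
  p <- eng$p
  eta <- drop(Xs %*% beta)
  eta <- eta - mean(eta)              # numerical centring; cancels in the PL
  w <- exp(eta)
  wX <- Xs * w
  wXX <- Xs[, eng$pi1, drop = FALSE] * Xs[, eng$pi2, drop = FALSE] * w

  R0 <- .revcumsum(w)
  R1 <- .revcumsum(wX)
  R2 <- .revcumsum(wXX)
  S0 <- R0[eng$first]
  S1 <- R1[eng$first, , drop = FALSE]
  S2 <- R2[eng$first, , drop = FALSE]

  D0 <- drop(rowsum(w[eng$ev], eng$g))
  D1 <- rowsum(wX[eng$ev, , drop = FALSE], eng$g)
  D2 <- rowsum(wXX[eng$ev, , drop = FALSE], eng$g)

  i <- eng$idx
  kf <- eng$kf
  S0k <- S0[i] - kf * D0[i]
  S1k <- S1[i, , drop = FALSE] - kf * D1[i, , drop = FALSE]
  S2k <- S2[i, , drop = FALSE] - kf * D2[i, , drop = FALSE]

  loglik <- sum(eta[eng$ev]) - sum(log(S0k))
  U <- S1k / S0k
  grad <- colSums(eng$death_x) - colSums(U)
  M2 <- colSums(S2k / S0k)
  info <- matrix(0, p, p)
  info[cbind(eng$pi1, eng$pi2)] <- M2
  info[cbind(eng$pi2, eng$pi1)] <- M2
  info <- info - crossprod(U)
  list(loglik = loglik, grad = grad, info = info,
       S0k = S0k, S1k = S1k, eta = eta, w = w)
}
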