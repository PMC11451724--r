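#' Cox-Snell pseudo R-squared
#'
#' Likelihood-based R-squared for survival models:
#' \deqn{R^2 = 1 - \exp\{(2/n)(\ell_0 - \ell)\},}
#' where \eqn{\ell_0} is the null (beta = 0) log partial likelihood,
#' \eqn{\ell} the maximized one and `n` the number of subjects (the common
#' convention; the number of events can be substituted via `n`).
#'
#' @param loglik_null Null-model log likelihood.
#' @param loglik_model Fitted-model log likelihood (>= `loglik_null` up to
#'   numerical tolerance).
#' @param n Sample size used in the normalization (>= 1).
#' @return R-squared in [0, 1).
#' @examples
#' cox_snell_r2(-100, -90, 50)  # 1 - exp(-0.4)
#' @export
cox_snell_r2 <- function(loglik_null, loglik_model, n) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (loglik_model < loglik_null - 1e-8) {
    stop("loglik_model < loglik_null: not a nested/converged fit",
         call. = FALSE)
  }
  1 - exp((2 / n) * min(loglik_null - loglik_model, 0))
}

#' Normalized likelihood-drop contributions
#'
#' Given per-covariate log-likelihood drops (full-model log likelihood minus
#' the log likelihood of the model refitted without that covariate), returns
#' each drop divided by the sum of all drops — the share of the jointly
#' explained likelihood attributable to each covariate.
#'
#' @param drops Named nonnegative numeric vector, at least one entry > 0.
#' @return Named vector summing to 1.
#' @examples
#' contribution(c(genotype = 68, cohort = 16.4, sex = 14.6,
#'                lab = 3.3, diet = 0.76))
#' @export
contribution <- function(drops) {
  drops <- unlist(drops)
  if (any(!is.finite(drops)) || any(drops < 0)) {
    stop("all drops must be finite and >= 0", call. = FALSE)
  }
  tot <- sum(drops)
  if (tot <= 0) {
    stop("no covariate carries likelihood information (all drops zero)",
         call. = FALSE)
  }
  drops / tot
}

#' Likelihood-based variance partition across Cox covariates
#'
#' Fits the full Cox model on all requested covariates and one reduced model
#' per covariate (that covariate excluded), then assembles: the
#' log-likelihood drop of each covariate, its normalized contribution
#' ([contribution()]), and Cox-Snell R-squared for the full and every
#' reduced model (all against the same beta = 0 null, so the values are
#' comparable). A proportional-hazards diagnostic ([ph_test()]) on the full
#' model is attached; its violations are reported, not fatal, mirroring how
#' such large-sample fits are read in practice.
#'
#' @param records `data.frame` of fly-level survival records.
#' @param covariates Character vector of model terms (default the five
#'   design factors: lab, sex, cohort, genotype, diet).
#' @param ties Tie handling for all fits.
#' @param r2_n `"subjects"` (default) or `"events"`: the n used in
#'   [cox_snell_r2()].
#' @param ph_diagnostic Attach the Schoenfeld-residual test (default TRUE).
#' @return Object of class `"variance_partition"`: `covariates`,
#'   `loglik_full`, `loglik_null`, `loglik_reduced`, `drops`,
#'   `contributions`, `r2_full`, `r2_reduced`, `n`, `n_events`, `fits`
#'   (the full fit), `ph` (diagnostic or NULL).
#' @examples
#' rec <- simulate_lifespans(sim_params(flies_per_cell = 15L, seed = 2L))
#' vp <- partition_pipeline(rec, ph_diagnostic = FALSE)
#' round(vp$contributions, 3)
#' @export
partition_pipeline <- function(records,
                               covariates = c("lab", "sex", "cohort",
                                              "genotype", "diet"),
                               ties = c("efron", "breslow"),
                               r2_n = c("subjects", "events"),
                               ph_diagnostic = TRUE) {
  ties <- match.arg(ties)
  r2_n <- match.arg(r2_n)
  if (length(covariates) < 2L) {
    stop("need at least two covariates to partition", call. = FALSE)
  }

  full <- cox_fit(records, covariates, ties = ties)
  if (!full$converged) {
    stop("full model did not converge: ", full$message, call. = FALSE)
  }
  n <- if (r2_n == "subjects") full$n_subjects else full$n_events

  ll_red <- r2_red <- stats::setNames(numeric(length(covariates)), covariates)
  for (cv in covariates) {
    red <- cox_fit(records, setdiff(covariates, cv), ties = ties)
    if (!red$converged) {
      stop("reduced model without `", cv, "` did not converge: ",
           red$message, call. = FALSE)
    }
    ll_red[cv] <- red$loglik
    r2_red[cv] <- cox_snell_r2(full$loglik_null, red$loglik, n)
  }

  drops <- full$loglik - ll_red
  neg <- drops < 0
  if (any(drops < -1e-6)) {
    stop("reduced model beats the full model for: ",
         paste(covariates[drops < -1e-6], collapse = ", "),
         " (non-nested or failed fit)", call. = FALSE)
  }
  if (any(neg)) {
    warning("clamping tiny negative likelihood drops to 0 for: ",
            paste(covariates[neg], collapse = ", "))
    drops[neg] <- 0
  }

  ph <- if (ph_diagnostic) ph_test(full, records) else NULL
  out <- list(
    covariates = covariates,
    loglik_full = full$loglik, loglik_null = full$loglik_null,
    loglik_reduced = ll_red,
    drops = drops,
    contributions = contribution(drops),
    r2_full = cox_snell_r2(full$loglik_null, full$loglik, n),
    r2_reduced = r2_red,
    n = n, n_events = full$n_events, r2_n = r2_n, ties_method = ties,
    fit_full = full, ph = ph
  )
  class(out) <- "variance_partition"
  out
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Likelihood-based variance partition (", x$ties_method, " ties, n = ",
      x$n, ", events = ", x$n_events, ")\n", sep = "")
  tab <- data.frame(
    drop = x$drops,
    `contribution (%)` = 100 * x$contributions,
    `R2 reduced` = x$r2_reduced,
    check.names = FALSE
  )
  print(round(tab[order(-tab$drop), ], 4))
  cat(sprintf("Full model: logLik %.2f (null %.2f), Cox-Snell R2 %.4f\n",
              x$loglik_full, x$loglik_null, x$r2_full))
  if (!is.null(x$ph)) {
    cat(sprintf("PH diagnostic (global): chi-square(%d) = %.3g, p = %.3g\n",
                x$ph$global$df, x$ph$global$chisq, x$ph$global$p))
  }
  invisible(x)
}
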