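#' Bonferroni familywise threshold
#'
#' @param alpha Familywise error rate in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return alpha / m. For the 64-pair grid, `bonferroni_threshold(0.05, 64)`
#'   is 0.00078125, i.e. 0.00078 to two significant figures.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (length(m) != 1L || !is.finite(m) || m < 1) {
    stop("`m` must be a positive count", call. = FALSE)
  }
  alpha / m
}

#' Per-stratum DR-vs-AL comparison grid
#'
#' Runs a two-group log-rank test for every (lab, cohort, genotype, sex)
#' stratum that contains both diet arms, and calls the longer-lived arm by
#' comparing Kaplan-Meier medians (restricted-mean tie-break; if still equal
#' the direction is `"none"`). Strata missing a diet arm are skipped with a
#' warning; strata whose test is degenerate (e.g. an all-censored arm) get
#' `p_value = NA` and direction `"none"`.
#'
#' @param records Fly-level survival records with the design columns `lab`,
#'   `cohort`, `genotype`, `sex`, `diet` plus `time_days`, `event`.
#' @param diets Length-2 character vector naming the restricted and rich
#'   arms (default `c("DR", "AL")`).
#' @return `data.frame` of class `"pair_grid"`, one row per stratum: the
#'   four stratum labels, `n_dr`, `n_al`, `statistic`, `p_value`,
#'   `median_dr`, `median_al`, `delta_l` (median DR - median AL) and
#'   `direction` ("DR", "AL" or "none").
#' @export
pair_grid <- function(records, diets = c("DR", "AL")) {
  need <- c("lab", "cohort", "genotype", "sex", "diet", "time_days", "event")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- interaction(records$lab, records$cohort, records$genotype,
                     records$sex, drop = TRUE, lex.order = TRUE, sep = "\r")
  out <- list()
  skipped <- character(0)
  for (k in levels(key)) {
    sub <- records[key == k, , drop = FALSE]
    lbl <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    dr <- sub[sub$diet == diets[1L], , drop = FALSE]
    al <- sub[sub$diet == diets[2L], , drop = FALSE]
    if (nrow(dr) == 0L || nrow(al) == 0L) {
      skipped <- c(skipped, paste(lbl, collapse = "/"))
      next
    }
    km_dr <- km_estimate(dr)
    km_al <- km_estimate(al)
    lr <- tryCatch(logrank_test(dr, al), error = function(e) NULL)
    pval <- if (is.null(lr) || lr$degenerate) NA_real_ else lr$p_value
    stat <- if (is.null(lr)) NA_real_ else lr$statistic
    dirn <- .pair_direction(km_dr, km_al, pval, diets)
    out[[k]] <- data.frame(
      lab = lbl[1L], cohort = lbl[2L], genotype = lbl[3L], sex = lbl[4L],
      n_dr = nrow(dr), n_al = nrow(al),
      statistic = stat, p_value = pval,
      median_dr = km_dr$median, median_al = km_al$median,
      delta_l = km_dr$median - km_al$median,
      direction = dirn, stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning("skipped strata missing a diet arm: ",
            paste(skipped, collapse = "; "))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pair_grid", class(res))
  res
}

# Longer-lived arm: KM medians, then restricted means, then "none".
.pair_direction <- function(km_dr, km_al, pval, diets) {
  if (is.na(pval)) return("none")
  m1 <- km_dr$median
  m2 <- km_al$median
  if (is.na(m1) && is.na(m2)) return("none")
  if (is.na(m1)) return(diets[1L])    # DR curve never reaches 0.5: longest
  if (is.na(m2)) return(diets[2L])
  if (m1 != m2) return(if (m1 > m2) diets[1L] else diets[2L])
  tau <- min(max(km_dr$times), max(km_al$times))
  r1 <- km_rmst(km_dr, tau)
  r2 <- km_rmst(km_al, tau)
  if (r1 == r2) "none" else if (r1 > r2) diets[1L] else diets[2L]
}

#' Summarize a comparison grid under Bonferroni correction
#'
#' Applies the familywise threshold `alpha / n_pairs` to the grid, counts
#' DR-favoring and AL-favoring significant pairs, and tabulates the same
#' counts by genotype, sex, lab, cohort and lab x cohort. `nominal` holds
#' the analogous rollups at unadjusted p < 0.05 (counting every pair below
#' 0.05 regardless of direction, the convention used when tallying
#' per-genotype "responses").
#'
#' @param results A [pair_grid()] result, or any `data.frame` with at least
#'   `p_value` and `direction` columns plus the stratum labels (e.g. the
#'   packaged printed-grid fixture, [table3_fixture()]).
#' @param alpha Familywise level (default 0.05).
#' @return Object of class `"pair_summary"`: `n_pairs`, `alpha_family`,
#'   `bonferroni_threshold`, `n_significant_dr`, `n_significant_al`,
#'   `rollups` (list of count tables by genotype / sex / lab / cohort /
#'   lab_cohort) and `nominal` (`threshold`, `n_significant`, rollup list).
#' @export
summarize_pairs <- function(results, alpha = 0.05) {
  if (!is.data.frame(results) || nrow(results) == 0L) {
    stop("`results` must be a nonempty data.frame", call. = FALSE)
  }
  m <- nrow(results)
  thr <- bonferroni_threshold(alpha, m)
  p <- results$p_value
  dirn <- as.character(results$direction)
  sig <- !is.na(p) & p <= thr
  nom <- !is.na(p) & p < 0.05

  roll <- function(flag_dr, flag_al, by) {
    groups <- lapply(by, function(v) results[[v]])
    agg <- stats::aggregate(
      cbind(dr = as.integer(flag_dr), al = as.integer(flag_al)),
      by = stats::setNames(groups, by), FUN = sum
    )
    agg[do.call(order, agg[by]), , drop = FALSE]
  }
  rollups <- list(
    genotype = roll(sig & dirn == "DR", sig & dirn == "AL", "genotype"),
    sex = roll(sig & dirn == "DR", sig & dirn == "AL", "sex"),
    lab = roll(sig & dirn == "DR", sig & dirn == "AL", "lab"),
    cohort = roll(sig & dirn == "DR", sig & dirn == "AL", "cohort"),
    lab_cohort = roll(sig & dirn == "DR", sig & dirn == "AL",
                      c("lab", "cohort")),
    genotype_sex = roll(sig & dirn == "DR", sig & dirn == "AL",
                        c("genotype", "sex"))
  )
  nom_roll <- function(by) {
    groups <- lapply(by, function(v) results[[v]])
    agg <- stats::aggregate(
      cbind(n_sig = as.integer(nom), n_pairs = 1L),
      by = stats::setNames(groups, by), FUN = sum
    )
    agg[do.call(order, agg[by]), , drop = FALSE]
  }
  out <- list(
    n_pairs = m, alpha_family = alpha, bonferroni_threshold = thr,
    n_significant_dr = sum(sig & dirn == "DR"),
    n_significant_al = sum(sig & dirn == "AL"),
    rollups = rollups,
    nominal = list(
      threshold = 0.05,
      n_significant = sum(nom),
      genotype = nom_roll("genotype"),
      sex = nom_roll("sex"),
      lab = nom_roll("lab"),
      cohort = nom_roll("cohort")
    )
  )
  class(out) <- "pair_summary"
  out
}

#' @export
print.pair_summary <- function(x, ...) {
  cat(sprintf("%d DR/AL pairs; Bonferroni threshold %.3g (familywise alpha %.2f)\n",
              x$n_pairs, x$bonferroni_threshold, x$alpha_family))
  cat(sprintf("Significant pairs: %d favoring DR, %d favoring AL (%d at nominal p < 0.05)\n",
              x$n_significant_dr, x$n_significant_al,
              x$nominal$n_significant))
  cat("By genotype (Bonferroni DR/AL):\n")
  print(x$rollups$genotype, row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation of matched summaries
#'
#' Spearman rho with average ranks for ties, i.e. the Pearson correlation of
#' the rank vectors; the two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 df.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), e.g. per-stratum
#'   median lifespans from two laboratories matched on
#'   cohort x genotype x sex x diet.
#' @return Object of class `"correlation_result"`: `rho`, `p_value`, `n`.
#' @export
cross_lab_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 matched pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  out <- list(rho = rho, p_value = p, n = n)
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.3g (n = %d)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Per-stratum median lifespans
#'
#' Kaplan-Meier median (or mean, since the motivating study labels its
#' cross-lab correlation both ways) for every combination of the grouping
#' columns.
#'
#' @param records Fly-level survival records.
#' @param by Grouping columns.
#' @param summary `"median"` (KM median, default) or `"mean"` (restricted
#'   mean up to the stratum's last observed time).
#' @return `data.frame` of group labels plus `n`, `n_events`, `lifespan`.
#' @export
stratum_medians <- function(records,
                            by = c("lab", "cohort", "genotype", "sex", "diet"),
                            summary = c("median", "mean")) {
  summary <- match.arg(summary)
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    sub <- records[key == k, , drop = FALSE]
    km <- km_estimate(sub)
    val <- if (summary == "median") {
      km$median
    } else if (km$all_censored) {
      NA_real_
    } else {
      km_rmst(km, max(sub$time_days))
    }
    cbind(
      stats::setNames(as.data.frame(as.list(strsplit(k, "\r", fixed = TRUE)[[1L]]),
                                    stringsAsFactors = FALSE), by),
      data.frame(n = km$n, n_events = km$n_events, lifespan = val)
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Cross-laboratory correlation of DR-effect sizes
#'
#' Matches the strata of two laboratories' [pair_grid()] results on
#' cohort x genotype x sex and Spearman-correlates their `delta_l`
#' (median DR - median AL) values; unmatched strata are dropped with a
#' warning.
#'
#' @param results_lab_a,results_lab_b [pair_grid()] rows for the two labs.
#' @return A [cross_lab_correlation()] result.
#' @export
delta_correlation <- function(results_lab_a, results_lab_b) {
  key <- function(d) paste(d$cohort, d$genotype, d$sex, sep = "\r")
  ka <- key(results_lab_a)
  kb <- key(results_lab_b)
  common <- intersect(ka, kb)
  if (length(common) < length(ka) || length(common) < length(kb)) {
    warning("dropping ", (length(ka) - length(common)) +
              (length(kb) - length(common)), " unmatched strata")
  }
  cross_lab_correlation(
    results_lab_a$delta_l[match(common, ka)],
    results_lab_b$delta_l[match(common, kb)]
  )
}
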