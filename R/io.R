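#' Read a fly-level event table
#'
#' CSV reader with header validation for the one-row-per-fly event table:
#' required columns `fly_id`, `lab`, `cohort`, `genotype`, `sex`, `diet`,
#' `vial`, `time_days`, `event`. Malformed rows are reported with their file
#' line numbers. `strict = TRUE` rejects unknown columns; the default warns
#' and keeps them.
#'
#' @param path CSV file path.
#' @param strict Reject unknown columns instead of warning.
#' @return Validated `data.frame` of survival records.
#' @export
read_event_table <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  required <- c("fly_id", "lab", "cohort", "genotype", "sex", "diet",
                "vial", "time_days", "event")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    if (strict) {
      stop("unknown column(s) in strict mode: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  line <- function(i) i + 1L  # header occupies line 1
  time <- suppressWarnings(as.numeric(df$time_days))
  bad <- which(!is.finite(time) | time < 0)
  if (length(bad)) {
    stop("non-numeric or negative time_days on line(s) ",
         paste(line(utils::head(bad, 5)), collapse = ", "), call. = FALSE)
  }
  if (!all(df$event %in% c("0", "1"))) {
    bad <- which(!df$event %in% c("0", "1"))
    stop("event must be 0 or 1; offending line(s) ",
         paste(line(utils::head(bad, 5)), collapse = ", "), call. = FALSE)
  }
  df$time_days <- time
  df$event <- as.integer(df$event)
  df[required]
}

#' Write a fly-level event table
#'
#' @param records Survival records (e.g. [simulate_lifespans()] output).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(records, path) {
  required <- c("fly_id", "lab", "cohort", "genotype", "sex", "diet",
                "vial", "time_days", "event")
  miss <- setdiff(required, names(records))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(records[required], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' The published 64-pair DR/AL log-rank grid
#'
#' The packaged transcription of the motivating two-lab study's printed
#' comparison grid: one row per (lab, cohort, genotype, sex) stratum with
#' the published log-rank p-value and, for comparisons passing the
#' Bonferroni cut, which arm was longer-lived (`"DR"`/`"AL"`; `"none"`
#' otherwise, including all non-significant cells, whose direction the
#' publication does not report). Feeding it to [summarize_pairs()]
#' reproduces the published significance tallies.
#'
#' @return `data.frame` with 64 rows: `lab`, `cohort`, `genotype`, `sex`,
#'   `p_value`, `direction`.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "dr_pair_grid_published.csv",
                      package = "drstoch", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cohort = "character"))
  stopifnot(nrow(df) == 64L, all(df$p_value > 0), all(df$p_value <= 1),
            all(df$direction %in% c("DR", "AL", "none")))
  df
}

#' Run the full analysis report on an event table
#'
#' Orchestrates the whole pipeline deterministically: the likelihood-based
#' variance partition on the declared cohort subsets, the per-stratum DR/AL
#' comparison grid with its Bonferroni summary, and the cross-laboratory
#' correlations of stratum lifespans and of DR effect sizes. Writes a
#' variance-partition TSV (rows = covariates, one column per subset), a
#' comparison-grid TSV (rows = genotype x sex, columns = lab x cohort, cells
#' p-value plus direction flag), JSON summaries with fixed key order, and a
#' run log recording every threshold and tolerance used.
#'
#' @param records Fly-level survival records.
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @param covariates Model terms for the variance partition.
#' @param subsets Named list of cohort subsets (values = cohort labels to
#'   keep; NULL = all). Default mirrors the motivating design: all cohorts,
#'   cohorts 1-3 (protocol 1) and cohorts 1 & 3 (same mating diet).
#' @param alpha Familywise level for the pair summary.
#' @param ties Tie handling for Cox fits.
#' @return List of class `"dr_report"`: `partition` (per subset),
#'   `pairs`, `pair_summary`, `lifespan_correlation`, `delta_correlation`,
#'   `settings`.
#' @export
run_report <- function(records, out_dir = NULL,
                       covariates = c("lab", "sex", "cohort", "genotype",
                                      "diet"),
                       subsets = list(all = NULL, c123 = c("1", "2", "3"),
                                      c13 = c("1", "3")),
                       alpha = 0.05, ties = "efron") {
  partition <- lapply(subsets, function(keep) {
    sub <- if (is.null(keep)) {
      records
    } else {
      records[records$cohort %in% keep, , drop = FALSE]
    }
    partition_pipeline(sub, covariates, ties = ties)
  })

  pairs <- pair_grid(records)
  psum <- summarize_pairs(pairs, alpha = alpha)

  labs <- sort(unique(records$lab))
  lifespan_cor <- delta_cor <- NULL
  if (length(labs) == 2L) {
    med <- stratum_medians(records)
    a <- med[med$lab == labs[1L], ]
    b <- med[med$lab == labs[2L], ]
    key <- function(d) paste(d$cohort, d$genotype, d$sex, d$diet, sep = "\r")
    common <- intersect(key(a), key(b))
    lifespan_cor <- cross_lab_correlation(
      a$lifespan[match(common, key(a))],
      b$lifespan[match(common, key(b))]
    )
    delta_cor <- delta_correlation(pairs[pairs$lab == labs[1L], ],
                                   pairs[pairs$lab == labs[2L], ])
  }

  settings <- list(
    covariates = covariates,
    subsets = lapply(subsets, function(s) if (is.null(s)) "all" else s),
    alpha_family = alpha, ties = ties,
    bonferroni_threshold = psum$bonferroni_threshold,
    cox_tol_grad = 1e-9, cox_tol_loglik = 1e-12, cox_max_iter = 50L,
    n_records = nrow(records)
  )
  rep <- list(
    partition = partition, pairs = pairs, pair_summary = psum,
    lifespan_correlation = lifespan_cor, delta_correlation = delta_cor,
    settings = settings
  )
  class(rep) <- "dr_report"
  if (!is.null(out_dir)) .write_report(rep, out_dir)
  rep
}

.write_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # variance partition: covariates x subsets, accounted variance (%)
  part_tab <- data.frame(
    factor = rep$partition[[1L]]$covariates,
    sapply(rep$partition, function(p) round(100 * p$contributions, 2)),
    check.names = FALSE
  )
  utils::write.table(part_tab, file.path(out_dir, "variance_partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # pair grid: rows genotype x sex, columns lab x cohort
  pg <- rep$pairs
  cell <- ifelse(is.na(pg$p_value), "NA",
                 paste0(signif(pg$p_value, 2),
                        ifelse(!is.na(pg$p_value) &
                                 pg$p_value <= rep$pair_summary$bonferroni_threshold &
                                 pg$direction != "none",
                               paste0(" (", pg$direction, ")"), "")))
  wide <- stats::reshape(
    data.frame(row = paste(pg$genotype, pg$sex, sep = "/"),
               col = paste(pg$lab, pg$cohort, sep = "_C"),
               cell = cell, stringsAsFactors = FALSE),
    idvar = "row", timevar = "col", direction = "wide"
  )
  names(wide) <- sub("^cell\\.", "", names(wide))
  utils::write.table(wide[order(wide$row), ],
                     file.path(out_dir, "pair_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  json <- list(
    loglik = lapply(rep$partition, function(p) list(
      full = p$loglik_full, null = p$loglik_null,
      reduced = as.list(p$loglik_reduced),
      r2_full = p$r2_full, r2_reduced = as.list(p$r2_reduced),
      contributions = as.list(p$contributions), n = p$n
    )),
    pair_summary = list(
      n_pairs = rep$pair_summary$n_pairs,
      bonferroni_threshold = rep$pair_summary$bonferroni_threshold,
      n_significant_dr = rep$pair_summary$n_significant_dr,
      n_significant_al = rep$pair_summary$n_significant_al,
      n_nominal = rep$pair_summary$nominal$n_significant
    ),
    lifespan_correlation = if (is.null(rep$lifespan_correlation)) NULL else
      rep$lifespan_correlation[c("rho", "p_value", "n")],
    delta_correlation = if (is.null(rep$delta_correlation)) NULL else
      rep$delta_correlation[c("rho", "p_value", "n")],
    settings = rep$settings
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  log_lines <- c(
    "drstoch run_report log",
    paste0("records: ", rep$settings$n_records),
    paste0("covariates: ", paste(rep$settings$covariates, collapse = ",")),
    paste0("subsets: ", paste(names(rep$partition), collapse = ",")),
    paste0("ties: ", rep$settings$ties),
    paste0("alpha_family: ", rep$settings$alpha_family),
    paste0("bonferroni_threshold: ",
           format(rep$settings$bonferroni_threshold, digits = 10)),
    paste0("cox_tol_grad: ", rep$settings$cox_tol_grad),
    paste0("cox_tol_loglik: ", rep$settings$cox_tol_loglik),
    paste0("cox_max_iter: ", rep$settings$cox_max_iter)
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.dr_report <- function(x, ...) {
  cat("DR lifespan analysis report\n")
  cat("-- variance partition (accounted variance %, subset 'all') --\n")
  print(round(100 * x$partition[[1L]]$contributions, 2))
  cat("-- DR/AL pairs --\n")
  print(x$pair_summary)
  if (!is.null(x$lifespan_correlation)) {
    cat("Cross-lab lifespan correlation: ")
    print(x$lifespan_correlation)
  }
  if (!is.null(x$delta_correlation)) {
    cat("Cross-lab DR-effect (delta-L) correlation: ")
    print(x$delta_correlation)
  }
  invisible(x)
}

#' Read simulation parameters from a JSON config file
#'
#' Keys mirror [sim_params()] argument names 1:1; absent keys keep their
#' defaults. `beta` must be a map of term name to (level -> log-hazard
#' effect) maps.
#'
#' @param path JSON file path.
#' @return A [sim_params()] object.
#' @export
read_sim_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$beta)) cfg$beta <- lapply(cfg$beta, unlist)
  do.call(sim_params, cfg)
}
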