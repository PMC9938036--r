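adjustment_covariates <- function() {
  c("age_group", "sex", "stage3", "mmr", "braf", "location", "grade")
}

#' Collapse AJCC stage to the I-II / III / IV coding used in Cox models
#'
#' @param stage Factor with levels I/II/III/IV.
#' @return Factor with levels `I-II`, `III`, `IV`.
#' @export
collapse_stage <- function(stage) {
  x <- as.character(stage)
  x[x %in% c("I", "II")] <- "I-II"
  factor(x, levels = c("I-II", "III", "IV"))
}

cox_fit_row <- function(fit, trend, model_label, endpoint, score_label) {
  tab <- fit$table
  data.frame(
    endpoint = endpoint, score = score_label, model = model_label,
    term = tab$term, level = tab$level, hr = tab$hr,
    ci_lower = tab$ci_lower, ci_upper = tab$ci_upper,
    p_value = tab$p_value, referent = tab$referent,
    p_trend = trend$p_value, n = fit$n, n_events = fit$n_events,
    converged = fit$converged,
    stringsAsFactors = FALSE)
}

score_cox_models <- function(analysis, endpoint_records, score_col,
                             other_score_col, endpoint, ties) {
  records <- merge(endpoint_records, analysis, by = "patient_id",
                   sort = FALSE)
  uni <- cox_fit(records, score_col, ties = ties)
  uni_trend <- p_trend(records, records[[score_col]], character(0),
                       ties = ties)
  multi_terms <- c(score_col, other_score_col, adjustment_covariates())
  multi <- cox_fit(records, multi_terms, ties = ties)
  multi_trend <- p_trend(records, records[[score_col]],
                         c(other_score_col, adjustment_covariates()),
                         ties = ties)
  label <- toupper(sub("_group$", "", score_col))
  rbind(
    cox_fit_row(uni, uni_trend, "univariable", endpoint, label),
    cox_fit_row(multi, multi_trend, "multivariable", endpoint, label))
}

component_cox_models <- function(analysis, endpoint_records, var,
                                 endpoint, ties) {
  grp_col <- paste0(var, "_tertile")
  records <- merge(endpoint_records, analysis, by = "patient_id",
                   sort = FALSE)
  uni <- cox_fit(records, grp_col, ties = ties)
  uni_trend <- p_trend(records, records[[grp_col]], character(0),
                       ties = ties)
  multi <- cox_fit(records, c(grp_col, adjustment_covariates()),
                   ties = ties)
  multi_trend <- p_trend(records, records[[grp_col]],
                         adjustment_covariates(), ties = ties)
  rbind(
    cox_fit_row(uni, uni_trend, "univariable", endpoint, var),
    cox_fit_row(multi, multi_trend, "multivariable", endpoint, var))
}

km_table <- function(analysis, endpoint_records, grp_col) {
  records <- merge(endpoint_records, analysis, by = "patient_id",
                   sort = FALSE)
  grp <- droplevels(records[[grp_col]])
  out <- lapply(levels(grp), function(g) {
    curve <- km_estimate(records[which(grp == g), , drop = FALSE])
    cbind(data.frame(group = g, stringsAsFactors = FALSE),
          as.data.frame(curve))
  })
  do.call(rbind, out)
}

association_report <- function(assoc) {
  lapply(assoc, function(a) {
    list(counts = a$table$counts,
         column_percent = round(a$column_percent, 1),
         n_used = a$table$n_used, n_missing = a$table$n_missing,
         statistic = a$test$statistic, df = a$test$df,
         p_value = a$test$p_value)
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full scoring and prognostic-analysis pipeline
#'
#' Orchestrates simulate (or load) -> score -> associate -> survival into
#' report artifacts: score-group characteristic tables with chi-square
#' p-values for every clinicopathological factor, the 8x8 Spearman
#' correlation matrix of the density panel, Kaplan-Meier step tables and
#' log-rank tests per score group, and univariable plus multivariable Cox
#' models (with ordinal trend tests) for both scores and all eight density
#' components, for cancer-specific and overall survival. Outputs are
#' deterministic given the cohort and configuration: rerunning with the
#' same inputs writes byte-identical files.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [cohort_config()]; also used for the follow-up cap.
#' @param cohort A cohort data frame, a path to a cohort CSV, or `NULL` to
#'   simulate one from `config`.
#' @param seed Seed for simulation (defaults to `config$seed`).
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @param endpoints Endpoints to analyse, subset of `c("css", "os")`.
#' @return A `study_report` list (invisibly): manifest, exclusion log,
#'   score group sizes, association tables, correlation matrix, Cox model
#'   table, log-rank results, and the paths written.
#' @export
run_study <- function(out_dir, config = cohort_config(), cohort = NULL,
                      seed = config$seed,
                      ties = c("efron", "breslow"),
                      endpoints = c("css", "os")) {
  ties <- match.arg(ties)
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  simulated <- is.null(cohort)
  if (simulated) {
    cohort <- simulate_cohort(config, seed = seed)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  paths <- character(0)
  if (simulated) {
    p <- file.path(out_dir, "cohort.csv")
    write_cohort(cohort, p)
    paths <- c(paths, p)
  }

  tsc <- compute_score(cohort, "t")
  bsc <- compute_score(cohort, "b")
  scores <- data.frame(
    patient_id = cohort$patient_id,
    t_percentile = tsc$mean_percentile, t_group = tsc$group,
    b_percentile = bsc$mean_percentile, b_group = bsc$group,
    stringsAsFactors = FALSE)
  p <- file.path(out_dir, "scores.tsv")
  write_tsv(scores, p)
  paths <- c(paths, p)

  assoc <- list(
    t = association_table(cohort, tsc$group),
    b = association_table(cohort, bsc$group))
  for (s in names(assoc)) {
    rows <- do.call(rbind, lapply(names(assoc[[s]]), function(nm) {
      a <- assoc[[s]][[nm]]
      data.frame(factor = nm, level = a$table$row_labels,
                 a$table$counts, check.names = FALSE,
                 p_value = a$test$p_value,
                 n_used = a$table$n_used, n_missing = a$table$n_missing,
                 stringsAsFactors = FALSE)
    }))
    p <- file.path(out_dir, sprintf("association_%s_score.tsv", s))
    write_tsv(rows, p)
    paths <- c(paths, p)
  }

  corr <- correlation_matrix(cohort[, density_variables()])
  p <- file.path(out_dir, "correlation_matrix.tsv")
  write_tsv(data.frame(variable = rownames(corr), round(corr, 4),
                       check.names = FALSE, stringsAsFactors = FALSE), p)
  paths <- c(paths, p)

  # analysis frame shared by all survival models
  analysis <- data.frame(
    patient_id = cohort$patient_id,
    tscore_group = tsc$group, bscore_group = bsc$group,
    cohort[, names(covariate_levels())],
    stringsAsFactors = FALSE)
  analysis$stage3 <- collapse_stage(cohort$stage)
  for (v in density_variables()) {
    analysis[[paste0(v, "_tertile")]] <- tertile_groups(cohort[[v]])
  }

  cox_rows <- list()
  logrank <- list()
  for (ep in endpoints) {
    records <- make_endpoint(cohort, ep,
                             admin_censor_months = config$admin_censor_months)
    n_excluded <- attr(records, "n_excluded")
    for (s in c("tscore_group", "bscore_group")) {
      merged <- merge(records, analysis, by = "patient_id", sort = FALSE)
      lr <- log_rank(merged, merged[[s]])
      logrank[[paste(ep, s, sep = "_")]] <- lr
      km <- km_table(analysis, records, s)
      p <- file.path(out_dir, sprintf("km_%s_%s.tsv", ep,
                                      sub("_group$", "", s)))
      write_tsv(km, p)
      paths <- c(paths, p)
      other <- setdiff(c("tscore_group", "bscore_group"), s)
      cox_rows[[paste(ep, s, sep = "_")]] <-
        score_cox_models(analysis, records, s, other, ep, ties)
    }
    for (v in density_variables()) {
      cox_rows[[paste(ep, v, sep = "_")]] <-
        component_cox_models(analysis, records, v, ep, ties)
    }
  }
  cox_table <- do.call(rbind, cox_rows)
  rownames(cox_table) <- NULL
  p <- file.path(out_dir, "cox_models.tsv")
  write_tsv(cox_table, p)
  paths <- c(paths, p)

  cfg_tmp <- tempfile(fileext = ".yaml")
  write_config(config, cfg_tmp)
  cfg_hash <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)

  non_conv <- cox_table[!cox_table$converged, c("endpoint", "score",
                                                "model")]
  report <- list(
    schema_version = "1.0",
    manifest = list(
      package = "lymphoscore",
      version = as.character(utils::packageVersion("lymphoscore")),
      seed = if (simulated) seed else NULL,
      simulated = simulated,
      config_md5 = cfg_hash,
      ties = ties,
      n_patients = nrow(cohort)),
    exclusions = list(
      surgical_30day_deaths = sum(cohort$surgical_30day_death == 1,
                                  na.rm = TRUE),
      t_score_missing = length(attr(tsc, "excluded")),
      b_score_missing = length(attr(bsc, "excluded"))),
    score_groups = list(
      t = as.list(attr(tsc, "sizes")),
      b = as.list(attr(bsc, "sizes"))),
    association = lapply(assoc, association_report),
    correlation_matrix = round(corr, 4),
    log_rank = logrank,
    cox_models = cox_table,
    non_converged_models = non_conv,
    files = basename(paths))
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  paths <- c(paths, p)
  report$files <- paths
  class(report) <- "study_report"
  message(sprintf(
    "run_study: %d patients, %d surgical exclusions, %d Cox models (%s)",
    nrow(cohort), report$exclusions$surgical_30day_deaths,
    nrow(unique(cox_table[, c("endpoint", "score", "model")])),
    paste(endpoints, collapse = "/")))
  invisible(report)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (lymphoscore", x$manifest$version, ")\n")
  cat(sprintf("  patients: %d, simulated: %s\n", x$manifest$n_patients,
              x$manifest$simulated))
  cat(sprintf("  T score groups: %s | B score groups: %s\n",
              paste(unlist(x$score_groups$t), collapse = "/"),
              paste(unlist(x$score_groups$b), collapse = "/")))
  cat(sprintf("  Cox model rows: %d; files: %d\n", nrow(x$cox_models),
              length(x$files)))
  invisible(x)
}
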