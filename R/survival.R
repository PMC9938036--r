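#' Build survival records for an endpoint
#'
#' Cancer-specific survival (CSS) counts death from the index cancer as the
#' event and censors other-cause deaths at their death time; overall
#' survival (OS) counts death from any cause. Patients flagged as 30-day
#' surgical deaths are excluded before analysis, and follow-up is capped at
#' `admin_censor_months` with censoring.
#'
#' @param cohort Cohort data frame with `time_months`, `cancer_death`,
#'   `any_death`, `surgical_30day_death`.
#' @param endpoint `"css"` or `"os"`.
#' @param admin_censor_months Follow-up cap in months (default 120).
#' @return Data frame with `patient_id` (if present), `time_months`,
#'   `event`; attribute `n_excluded` gives the surgical-death exclusions.
#' @export
make_endpoint <- function(cohort, endpoint = c("css", "os"),
                          admin_censor_months = 120) {
  endpoint <- match.arg(endpoint)
  if (any(cohort$cancer_death == 1 & cohort$any_death == 0, na.rm = TRUE)) {
    stop("cancer_death = 1 requires any_death = 1")
  }
  keep <- is.na(cohort$surgical_30day_death) |
    cohort$surgical_30day_death != 1
  x <- cohort[keep, , drop = FALSE]
  event <- if (endpoint == "css") x$cancer_death else x$any_death
  time <- x$time_months
  over <- time > admin_censor_months
  time[over] <- admin_censor_months
  event[over] <- 0L
  out <- data.frame(time_months = time, event = as.integer(event))
  if (!is.null(x$patient_id)) {
    out <- cbind(data.frame(patient_id = x$patient_id,
                            stringsAsFactors = FALSE), out)
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`.
#'
#' @param records Data frame with `time_months` and `event` (0/1), e.g.
#'   from [make_endpoint()].
#' @return Object of class `km_curve`: data frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` at each distinct observed time.
#' @export
km_estimate <- function(records) {
  if (any(records$time_months <= 0)) stop("times must be positive")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records, conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test across k groups
#'
#' Standard (unweighted) log-rank: observed minus expected events per group
#' accumulated over distinct event times with hypergeometric variance; the
#' statistic is referred to a chi-square distribution with k - 1 degrees of
#' freedom.
#'
#' @param records Data frame with `time_months` and `event`.
#' @param groups Factor with k >= 2 non-empty levels.
#' @return List with `statistic`, `df`, `p_value`, `n`, and the per-group
#'   observed/expected event counts.
#' @export
log_rank <- function(records, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  dat <- data.frame(time_months = records$time_months,
                    event = records$event, group = groups)
  fit <- survival::survdiff(
    survival::Surv(time_months, event) ~ group, data = dat)
  df <- length(fit$n) - 1L
  list(statistic = unname(fit$chisq), df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       n = sum(fit$n), observed = unname(fit$obs),
       expected = unname(fit$exp))
}

#' Cox proportional-hazards regression
#'
#' Fits a Cox model by partial-likelihood maximization (Efron or Breslow
#' handling of tied event times) and reports hazard ratios with Wald 95%
#' confidence intervals `exp(beta +/- 1.96 se)` and per-coefficient Wald
#' p-values. The first level of every factor term is the referent and is
#' reported with HR 1. Patients missing any model covariate are dropped
#' listwise; the count is recorded.
#'
#' @param records Data frame with `time_months`, `event` and the model
#'   covariates (factors with the reference level first, or numerics).
#' @param terms Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: list with `table` (term, level, coef,
#'   se, hr, ci_lower, ci_upper, p_value; referent rows have `hr` 1 and
#'   `NA` inference columns), `n`, `n_events`, `n_dropped`, `ties`,
#'   `converged`, `loglik`, and the underlying `survival::coxph` fit.
#' @export
cox_fit <- function(records, terms, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  missing_terms <- setdiff(terms, names(records))
  if (length(missing_terms)) {
    stop("records lack model columns: ",
         paste(missing_terms, collapse = ", "))
  }
  dat <- records[, c("time_months", "event", terms), drop = FALSE]
  for (nm in terms) {
    if (is.factor(dat[[nm]])) dat[[nm]] <- droplevels(dat[[nm]])
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         na.action = stats::na.omit, model = TRUE)
  n_dropped <- nrow(dat) - fit$n
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  converged <- all(is.finite(beta)) && all(abs(beta) < 15) &&
    all(is.finite(se))
  rows <- list()
  next_col <- 1L
  for (k in seq_along(terms)) {
    nm <- terms[k]
    n_coef <- if (is.factor(dat[[nm]])) nlevels(dat[[nm]]) - 1L else 1L
    cols <- seq.int(next_col, length.out = n_coef)
    next_col <- next_col + n_coef
    if (is.factor(dat[[nm]])) {
      levs <- levels(dat[[nm]])
      rows[[length(rows) + 1]] <- data.frame(
        term = nm, level = levs[1], coef = 0, se = NA_real_, hr = 1,
        ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
        referent = TRUE, stringsAsFactors = FALSE)
      for (i in seq_along(cols)) {
        b <- beta[cols[i]]
        s <- se[cols[i]]
        rows[[length(rows) + 1]] <- data.frame(
          term = nm, level = levs[i + 1], coef = unname(b), se = unname(s),
          hr = exp(unname(b)),
          ci_lower = exp(unname(b - 1.96 * s)),
          ci_upper = exp(unname(b + 1.96 * s)),
          p_value = 2 * stats::pnorm(-abs(unname(b) / unname(s))),
          referent = FALSE, stringsAsFactors = FALSE)
      }
    } else {
      b <- beta[cols]
      s <- se[cols]
      rows[[length(rows) + 1]] <- data.frame(
        term = nm, level = "", coef = unname(b), se = unname(s),
        hr = exp(unname(b)),
        ci_lower = exp(unname(b - 1.96 * s)),
        ci_upper = exp(unname(b + 1.96 * s)),
        p_value = 2 * stats::pnorm(-abs(unname(b) / unname(s))),
        referent = FALSE, stringsAsFactors = FALSE)
    }
  }
  structure(
    list(table = do.call(rbind, rows), n = fit$n,
         n_events = fit$nevent, n_dropped = n_dropped, ties = ties,
         converged = converged, loglik = fit$loglik, fit = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): n = %d, events = %d",
              x$ties, x$n, x$n_events))
  if (x$n_dropped > 0) cat(sprintf(", dropped = %d", x$n_dropped))
  if (!x$converged) cat("  [NOT CONVERGED]")
  cat("\n")
  tab <- x$table
  tab$hr_ci <- ifelse(tab$referent, "1 (referent)",
                      sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$ci_lower,
                              tab$ci_upper))
  print(tab[, c("term", "level", "hr_ci", "p_value")], row.names = FALSE)
  invisible(x)
}

#' Ordinal trend test for a score in a Cox model
#'
#' Wald p-value for the score entered as a single linear numeric term
#' (low/intermediate/high coded 0/1/2), adjusted for the same covariates as
#' the categorical model.
#'
#' @param records Data frame with `time_months`, `event`, and adjustment
#'   covariates.
#' @param ordinal_score Factor of score groups, or numeric 0/1/2 codes.
#' @param adjust Character vector of adjustment covariate names (possibly
#'   empty).
#' @param ties Tie handling, as in [cox_fit()].
#' @return List with `p_value`, `coef` (log-HR per score level), `se`.
#' @export
p_trend <- function(records, ordinal_score, adjust = character(0),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  score_num <- if (is.factor(ordinal_score)) {
    as.numeric(ordinal_score) - 1
  } else {
    as.numeric(ordinal_score)
  }
  dat <- records
  dat$.score_trend <- score_num
  fit <- cox_fit(dat, c(".score_trend", adjust), ties = ties)
  row <- fit$table[fit$table$term == ".score_trend", ]
  list(p_value = row$p_value, coef = row$coef, se = row$se)
}
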