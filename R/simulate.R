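#' Generate correlated regional immune-cell densities
#'
#' Draws an `n x 8` matrix of positive densities (cells/mm^2) through a
#' Gaussian copula: a latent multivariate normal with Pearson correlation
#' `r = 2 sin(pi * rho_s / 6)` for each target Spearman `rho_s`, pushed
#' through log-normal marginal quantile functions. Because the marginal
#' transforms are strictly increasing, the population Spearman correlation
#' of every pair equals its target; a pair with target 1 is drawn
#' comonotone. Uses the current RNG state; call `set.seed()` first for
#' reproducibility.
#'
#' @param config A [cohort_config()].
#' @param n Number of patients (defaults to `config$n_patients`).
#' @return Numeric matrix `n x 8`, columns [density_variables()].
#' @export
generate_densities <- function(config, n = config$n_patients) {
  validate_config(config)
  r <- latent_correlation(config$spearman_targets)
  e <- eigen(r, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  a <- e$vectors %*% diag(sqrt(vals))
  z <- matrix(stats::rnorm(n * 8L), nrow = n, ncol = 8L) %*% t(a)
  u <- stats::pnorm(z)
  marg <- config$density_marginals
  out <- matrix(NA_real_, n, 8L,
                dimnames = list(NULL, density_variables()))
  for (j in seq_len(8L)) {
    row <- marg[marg$variable == density_variables()[j], ]
    out[, j] <- stats::qlnorm(u[, j], meanlog = row$meanlog,
                              sdlog = row$sdlog)
  }
  out
}

#' Generate clinicopathological covariates
#'
#' Each covariate is drawn from its configured marginal distribution. If the
#' configuration carries a `stage_by_tscore` table and score groups are
#' supplied, AJCC stage is instead drawn per patient from the column of that
#' table matching the patient's T cell score group, which embeds the
#' stage-score association into the cohort. Missing values are then injected
#' at the configured per-covariate counts. Uses the current RNG state.
#'
#' @param config A [cohort_config()].
#' @param t_score_groups Optional factor of score groups
#'   (low/intermediate/high), one per patient.
#' @param n Number of patients.
#' @return Data frame of factors with the level sets of [covariate_levels()].
#' @export
generate_covariates <- function(config, t_score_groups = NULL,
                                n = config$n_patients) {
  levs <- covariate_levels()
  marg <- config$covariate_marginals
  out <- list()
  for (nm in names(levs)) {
    p <- marg[[nm]]
    if (is.null(p)) stop("no marginal configured for covariate ", nm)
    if (!setequal(names(p), levs[[nm]])) {
      stop(sprintf("marginal for %s has categories {%s}; expected {%s}",
                   nm, paste(names(p), collapse = ","),
                   paste(levs[[nm]], collapse = ",")))
    }
    p <- p[levs[[nm]]]
    if (nm == "stage" && !is.null(config$stage_by_tscore) &&
        !is.null(t_score_groups)) {
      tab <- config$stage_by_tscore
      if (!setequal(rownames(tab), levs$stage) ||
          !setequal(colnames(tab), score_group_levels())) {
        stop("stage_by_tscore rows/columns inconsistent with category sets")
      }
      grp <- as.character(t_score_groups)
      draw <- character(n)
      for (g in score_group_levels()) {
        idx <- which(grp == g)
        if (length(idx)) {
          draw[idx] <- sample(levs$stage, length(idx), replace = TRUE,
                              prob = tab[levs$stage, g])
        }
      }
      draw[is.na(grp) | !(grp %in% score_group_levels())] <- NA
      out[[nm]] <- factor(draw, levels = levs$stage)
    } else {
      out[[nm]] <- factor(sample(names(p), n, replace = TRUE, prob = p),
                          levels = levs[[nm]])
    }
  }
  miss <- config$covariate_missing
  for (nm in names(miss)) {
    k <- min(miss[[nm]], n)
    if (k > 0) out[[nm]][sample.int(n, k)] <- NA
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

linear_predictor <- function(loghr, score_groups, covariates, n) {
  lp <- numeric(n)
  for (term in names(loghr)) {
    vals <- if (term %in% c("tscore", "bscore")) {
      as.character(score_groups[[term]])
    } else if (!is.null(covariates) && term %in% names(covariates)) {
      as.character(covariates[[term]])
    } else {
      stop("hazard_spec term '", term, "' matches no score or covariate")
    }
    beta <- loghr[[term]]
    hit <- match(vals, names(beta))
    contrib <- ifelse(is.na(hit), 0, beta[hit])
    contrib[is.na(vals)] <- 0
    lp <- lp + contrib
  }
  lp
}

#' Generate cause-specific survival outcomes
#'
#' Two independent latent exponential event times (cancer death,
#' other-cause death), each with patient hazard
#' `base_rate * exp(linear predictor)` built from the configured
#' log-hazard-ratio terms over score groups and covariates. Administrative
#' censoring time is `min(admin_censor_months, accrual_span + lock_offset -
#' entry)` with entry uniform over the accrual span. The observed time is
#' the minimum of the three, with event indicators set accordingly. Uses
#' the current RNG state.
#'
#' @param config A [cohort_config()].
#' @param score_groups List (or data frame) with elements `tscore` and/or
#'   `bscore`: factors of score groups per patient.
#' @param covariates Optional covariate data frame.
#' @param n Number of patients.
#' @return Data frame with `time_months`, `cancer_death`, `any_death`.
#' @export
generate_survival <- function(config, score_groups, covariates = NULL,
                              n = config$n_patients) {
  hs <- config$hazard_spec
  lp_c <- linear_predictor(hs$cancer$loghr, score_groups, covariates, n)
  lp_o <- linear_predictor(hs$other$loghr, score_groups, covariates, n)
  draw_times <- function(rate, lp) {
    if (rate <= 0) return(rep(Inf, n))
    stats::rexp(n, rate = rate * exp(lp))
  }
  t_cancer <- draw_times(hs$cancer$base_rate, lp_c)
  t_other <- draw_times(hs$other$base_rate, lp_o)
  entry <- if (config$accrual_span_months > 0) {
    stats::runif(n, 0, config$accrual_span_months)
  } else {
    numeric(n)
  }
  censor <- pmin(config$admin_censor_months,
                 config$accrual_span_months + config$lock_offset_months -
                   entry)
  t_event <- pmin(t_cancer, t_other)
  time <- pmin(t_event, censor)
  any_death <- as.integer(t_event <= censor)
  cancer_death <- as.integer(t_cancer <= censor & t_cancer <= t_other)
  data.frame(time_months = time, cancer_death = cancer_death,
             any_death = any_death)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generator: correlated densities, T and B cell/plasma cell
#' scores (needed so stage and survival can depend on score group),
#' covariates, cause-specific survival, and post-hoc flagging of
#' `surgical_mortality_count` patients as 30-day surgical deaths (death
#' within the first month, not attributed to cancer). A single seed drives
#' the cohort; sub-seeds for each generation stage are derived
#' deterministically from it, so e.g. changing the hazard specification
#' does not perturb the density draws.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return Data frame, one row per patient, with columns `patient_id`, the
#'   eight density columns, the eight covariates, `time_months`,
#'   `cancer_death`, `any_death`, `surgical_30day_death`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_config(config)
  n <- config$n_patients
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  set.seed(stage_seeds[1])
  dens <- generate_densities(config)

  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(dens))

  tsc <- compute_score(cohort, "t")
  bsc <- compute_score(cohort, "b")

  set.seed(stage_seeds[2])
  covs <- generate_covariates(config, t_score_groups = tsc$group, n = n)
  cohort <- cbind(cohort, covs)

  set.seed(stage_seeds[3])
  surv <- generate_survival(config,
                            score_groups = list(tscore = tsc$group,
                                                bscore = bsc$group),
                            covariates = covs, n = n)
  cohort <- cbind(cohort, surv)

  cohort$surgical_30day_death <- 0L
  k <- config$surgical_mortality_count
  if (k > 0) {
    set.seed(stage_seeds[4])
    idx <- sample.int(n, k)
    cohort$surgical_30day_death[idx] <- 1L
    cohort$time_months[idx] <- stats::runif(k, 0.1, 1)
    cohort$any_death[idx] <- 1L
    cohort$cancer_death[idx] <- 0L
  }
  cohort
}
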