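#' Names of the eight regional density variables
#'
#' Marker (CD3, CD8, CD20, CD138) crossed with region: tumor center (`ct`)
#' and invasive margin (`im`).
#'
#' @return Character vector of length 8.
#' @export
density_variables <- function() {
  c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im",
    "cd20_ct", "cd20_im", "cd138_ct", "cd138_im")
}

#' Canonical category levels for the clinicopathological covariates
#'
#' @return Named list mapping covariate name to its ordered level set.
#' @export
covariate_levels <- function() {
  list(
    sex       = c("female", "male"),
    age_group = c("<65", "65-75", ">75"),
    location  = c("proximal", "distal", "rectum"),
    stage     = c("I", "II", "III", "IV"),
    grade     = c("low", "high"),
    lvi       = c("no", "yes"),
    mmr       = c("proficient", "deficient"),
    braf      = c("wildtype", "mutant")
  )
}

#' Default Spearman correlation targets for the density panel
#'
#' Symmetric 8x8 matrix of target Spearman correlations between the regional
#' densities. Five pairs are set to published estimates for colorectal
#' cancer immune infiltrates: CD3/CD8 at the invasive margin 0.606, CD20/CD8
#' at the invasive margin 0.459, CD20/CD3 at the invasive margin 0.442,
#' CD20/CD138 in the tumor center 0.421, and CD3/CD138 in the tumor center
#' 0.246. All remaining off-diagonal pairs default to a mild positive 0.2,
#' reflecting the broadly positive inter-correlation of immune infiltrates.
#'
#' @return 8x8 numeric matrix with unit diagonal.
#' @export
default_spearman_targets <- function() {
  v <- density_variables()
  s <- matrix(0.2, 8, 8, dimnames = list(v, v))
  diag(s) <- 1
  set2 <- function(a, b, val) {
    s[a, b] <<- val
    s[b, a] <<- val
  }
  set2("cd3_im", "cd8_im", 0.606)
  set2("cd20_im", "cd8_im", 0.459)
  set2("cd20_im", "cd3_im", 0.442)
  set2("cd20_ct", "cd138_ct", 0.421)
  set2("cd3_ct", "cd138_ct", 0.246)
  s
}

#' Default log-normal marginals for the density panel
#'
#' Per-variable log-mean and log-sd of cell densities in cells/mm^2. The
#' medians (exp(meanlog)) are plausible colorectal-cancer scales: T cell
#' densities in the hundreds, B cell densities in the tens, plasma cell
#' densities in between, with invasive-margin T cell densities above
#' tumor-center ones.
#'
#' @return Data frame with columns `variable`, `meanlog`, `sdlog`.
#' @export
default_density_marginals <- function() {
  data.frame(
    variable = density_variables(),
    meanlog  = c(log(300), log(500), log(100), log(200),
                 log(40), log(80), log(150), log(120)),
    sdlog    = rep(0.9, 8),
    stringsAsFactors = FALSE
  )
}

#' Default covariate marginal probabilities
#'
#' Category probabilities for each clinicopathological covariate, taken from
#' the cohort composition of a 221-patient colorectal-cancer series:
#' sex 110/111 female/male, age <65 / 65-75 / >75 = 68/71/82, location
#' proximal/distal/rectum = 93/60/68, stage I-IV = 45/74/67/34 (of 220),
#' grade low/high = 195/25 (of 220), lymphovascular invasion no/yes =
#' 110/109 (of 219), MMR proficient/deficient = 191/29 (of 220), BRAF
#' wild-type/mutant = 200/21.
#'
#' @return Named list of named probability vectors.
#' @export
default_covariate_marginals <- function() {
  list(
    sex       = c(female = 110, male = 111) / 221,
    age_group = c("<65" = 68, "65-75" = 71, ">75" = 82) / 221,
    location  = c(proximal = 93, distal = 60, rectum = 68) / 221,
    stage     = c(I = 45, II = 74, III = 67, IV = 34) / 220,
    grade     = c(low = 195, high = 25) / 220,
    lvi       = c(no = 110, yes = 109) / 219,
    mmr       = c(proficient = 191, deficient = 29) / 220,
    braf      = c(wildtype = 200, mutant = 21) / 221
  )
}

#' Default stage distribution conditional on T cell score group
#'
#' 4x3 probability table (stage I-IV by score group low/intermediate/high),
#' each column normalized, embedding the association between higher T cell
#' score and lower disease stage observed in the same 221-patient series
#' (stage counts 11/17/22/24, 14/31/24/5 and 20/26/21/5 in the low,
#' intermediate and high score columns).
#'
#' @return 4x3 column-stochastic matrix.
#' @export
default_stage_by_tscore <- function() {
  counts <- cbind(
    low          = c(11, 17, 22, 24),
    intermediate = c(14, 31, 24, 5),
    high         = c(20, 26, 21, 5)
  )
  rownames(counts) <- c("I", "II", "III", "IV")
  sweep(counts, 2, colSums(counts), "/")
}

#' Default cause-specific hazard specification
#'
#' Baseline exponential rates per month for cancer death and other-cause
#' death, with multiplicative group effects on the T cell score. The cancer
#' hazard ratios (1, 0.53, 0.22 for low/intermediate/high) match published
#' multivariable cancer-specific estimates; the other-cause hazard ratios
#' are derived so that the implied all-cause hazard ratios equal the
#' corresponding overall-survival estimates (1, 0.49, 0.44), using the
#' exponential identity HR_os = (l_c * HR_c + l_o * HR_o) / (l_c + l_o).
#' Baseline rates are calibrated so a 219-patient cohort followed under the
#' default censoring scheme accrues about 104 deaths of which about 59 are
#' cancer deaths.
#'
#' @param css_hr Cancer-specific hazard ratios for (intermediate, high) vs low.
#' @param os_hr All-cause hazard ratios for (intermediate, high) vs low.
#' @param cancer_rate,other_rate Baseline exponential rates per month.
#' @return List with elements `cancer` and `other`, each holding `base_rate`
#'   and a `loghr` list of named log-hazard-ratio vectors keyed by term.
#' @export
default_hazard_spec <- function(css_hr = c(intermediate = 0.53, high = 0.22),
                                os_hr = c(intermediate = 0.49, high = 0.44),
                                cancer_rate = 0.0061,
                                other_rate = 0.00355) {
  other_hr <- (os_hr * (cancer_rate + other_rate) - cancer_rate * css_hr) /
    other_rate
  if (any(other_hr <= 0)) {
    stop("implied other-cause hazard ratios are non-positive; ",
         "check css_hr/os_hr/base rates")
  }
  list(
    cancer = list(base_rate = cancer_rate,
                  loghr = list(tscore = log(css_hr))),
    other  = list(base_rate = other_rate,
                  loghr = list(tscore = log(other_hr)))
  )
}

#' Build a synthetic-cohort configuration
#'
#' Bundles every parameter of the synthetic cohort generator: cohort size,
#' seed, Spearman correlation targets and log-normal marginals for the eight
#' regional densities, covariate marginals (optionally with stage drawn
#' conditionally on the T cell score group), a cause-specific
#' proportional-hazards specification, and the administrative censoring
#' scheme (uniform accrual over `accrual_span_months`, database lock
#' `lock_offset_months` after accrual ends, follow-up capped at
#' `admin_censor_months`).
#'
#' @param n_patients Number of patients (default 221).
#' @param seed Integer seed for the cohort RNG stream.
#' @param spearman_targets Symmetric 8x8 target Spearman matrix.
#' @param density_marginals Data frame `variable`/`meanlog`/`sdlog`.
#' @param covariate_marginals Named list of category probability vectors.
#' @param covariate_missing Named integer vector: how many patients have a
#'   missing value for each covariate (defaults mirror 220/220/220/219
#'   non-missing out of 221 for stage, grade, MMR and LVI).
#' @param stage_by_tscore Optional 4x3 column-stochastic matrix giving the
#'   stage distribution within each T score group; `NULL` draws stage from
#'   its marginal independently of score.
#' @param hazard_spec Cause-specific hazard specification, see
#'   [default_hazard_spec()].
#' @param admin_censor_months Maximum follow-up in months (default 120).
#' @param accrual_span_months Uniform accrual window in months.
#' @param lock_offset_months Months between end of accrual and database lock.
#' @param surgical_mortality_count Number of patients flagged post hoc as
#'   30-day surgical deaths (default 2).
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 221,
                          seed = 1L,
                          spearman_targets = default_spearman_targets(),
                          density_marginals = default_density_marginals(),
                          covariate_marginals = default_covariate_marginals(),
                          covariate_missing = c(stage = 1L, grade = 1L,
                                                mmr = 1L, lvi = 2L),
                          stage_by_tscore = default_stage_by_tscore(),
                          hazard_spec = default_hazard_spec(),
                          admin_censor_months = 120,
                          accrual_span_months = 80,
                          lock_offset_months = 80,
                          surgical_mortality_count = 2L) {
  config <- structure(
    list(
      n_patients = as.integer(n_patients),
      seed = as.integer(seed),
      spearman_targets = spearman_targets,
      density_marginals = density_marginals,
      covariate_marginals = covariate_marginals,
      covariate_missing = covariate_missing,
      stage_by_tscore = stage_by_tscore,
      hazard_spec = hazard_spec,
      admin_censor_months = admin_censor_months,
      accrual_span_months = accrual_span_months,
      lock_offset_months = lock_offset_months,
      surgical_mortality_count = as.integer(surgical_mortality_count)
    ),
    class = "cohort_config"
  )
  validate_config(config)
  config
}

#' Map target Spearman correlations to latent Gaussian correlations
#'
#' Uses the exact Gaussian-copula relation r = 2 sin(pi * rho_s / 6): a
#' bivariate normal with Pearson correlation r has population Spearman
#' correlation rho_s, which survives any strictly increasing marginal
#' transform.
#'
#' @param spearman Numeric matrix (or scalar) of Spearman correlations.
#' @return Matrix (or scalar) of latent Pearson correlations.
#' @export
latent_correlation <- function(spearman) {
  r <- 2 * sin(pi * spearman / 6)
  if (is.matrix(r)) diag(r) <- 1
  r
}

#' Validate a cohort configuration
#'
#' Checks the generator invariants: the Spearman target matrix is symmetric
#' with unit diagonal and entries in \[-1, 1\], its latent-correlation
#' transform is positive semi-definite, all category probabilities sum to 1,
#' and rates/durations are strictly positive.
#'
#' @param config A `cohort_config` object.
#' @return The config, invisibly; errors describe the first violation found.
#' @export
validate_config <- function(config) {
  s <- config$spearman_targets
  v <- density_variables()
  if (!is.matrix(s) || !identical(dim(s), c(8L, 8L))) {
    stop("spearman_targets must be an 8x8 matrix")
  }
  if (is.null(dimnames(s))) dimnames(s) <- list(v, v)
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-12))) {
    stop("spearman_targets must be symmetric")
  }
  if (any(abs(diag(s) - 1) > 1e-12)) {
    stop("spearman_targets must have unit diagonal")
  }
  if (any(s < -1 - 1e-12) || any(s > 1 + 1e-12)) {
    stop("spearman_targets entries must lie in [-1, 1]")
  }
  r <- latent_correlation(s)
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    off <- abs(r)
    diag(off) <- 0
    idx <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0(
      "latent correlation matrix is not positive semi-definite ",
      "(min eigenvalue %.3g); largest off-diagonal target involves the ",
      "pair (%s, %s) - consider reducing it"),
      min(ev), v[idx[1]], v[idx[2]]))
  }
  for (nm in names(config$covariate_marginals)) {
    p <- config$covariate_marginals[[nm]]
    if (any(p < 0)) stop("negative probability in marginal for ", nm)
    if (abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("probabilities for %s sum to %.12f, not 1", nm, sum(p)))
    }
  }
  if (!is.null(config$stage_by_tscore)) {
    m <- config$stage_by_tscore
    if (!is.matrix(m) || nrow(m) != 4L || ncol(m) != 3L) {
      stop("stage_by_tscore must be a 4x3 matrix (stage I-IV x score group)")
    }
    if (any(m < 0) || any(abs(colSums(m) - 1) > 1e-9)) {
      stop("stage_by_tscore columns must be probability vectors summing to 1")
    }
  }
  hs <- config$hazard_spec
  if (hs$cancer$base_rate < 0 || hs$other$base_rate < 0) {
    stop("baseline hazard rates must be nonnegative")
  }
  if (config$admin_censor_months <= 0) {
    stop("admin_censor_months must be strictly positive")
  }
  if (config$accrual_span_months < 0 || config$lock_offset_months < 0) {
    stop("accrual_span_months and lock_offset_months must be nonnegative")
  }
  if (config$n_patients < 1) stop("n_patients must be a positive integer")
  if (config$surgical_mortality_count < 0 ||
      config$surgical_mortality_count > config$n_patients) {
    stop("surgical_mortality_count must be in [0, n_patients]")
  }
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n_patients: %d   seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  admin censoring: %g months (accrual %g, lock offset %g)\n",
              x$admin_censor_months, x$accrual_span_months,
              x$lock_offset_months))
  cat(sprintf("  baseline rates /month: cancer %g, other %g\n",
              x$hazard_spec$cancer$base_rate, x$hazard_spec$other$base_rate))
  cat(sprintf("  stage conditional on T score: %s\n",
              if (is.null(x$stage_by_tscore)) "no" else "yes"))
  cat(sprintf("  surgical 30-day deaths: %d\n", x$surgical_mortality_count))
  invisible(x)
}

#' Write a cohort configuration to YAML
#'
#' @param config A `cohort_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lst <- list(
    n_patients = config$n_patients,
    seed = config$seed,
    spearman_targets = apply(config$spearman_targets, 1, as.list,
                             simplify = FALSE),
    density_marginals = lapply(seq_len(nrow(config$density_marginals)),
      function(i) as.list(config$density_marginals[i, ])),
    covariate_marginals = lapply(config$covariate_marginals, as.list),
    covariate_missing = as.list(config$covariate_missing),
    stage_by_tscore = if (is.null(config$stage_by_tscore)) NULL else
      apply(config$stage_by_tscore, 2, as.list, simplify = FALSE),
    hazard_spec = list(
      cancer = list(base_rate = config$hazard_spec$cancer$base_rate,
                    loghr = lapply(config$hazard_spec$cancer$loghr, as.list)),
      other = list(base_rate = config$hazard_spec$other$base_rate,
                   loghr = lapply(config$hazard_spec$other$loghr, as.list))
    ),
    admin_censor_months = config$admin_censor_months,
    accrual_span_months = config$accrual_span_months,
    lock_offset_months = config$lock_offset_months,
    surgical_mortality_count = config$surgical_mortality_count
  )
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' Read a cohort configuration from YAML
#'
#' @param path Path to a YAML file written by [write_config()] (or matching
#'   its schema); the packaged default lives at
#'   `system.file("extdata", "default_config.yaml", package = "lymphoscore")`.
#' @return A validated `cohort_config`.
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  v <- density_variables()
  st <- t(vapply(lst$spearman_targets, function(row) unlist(row), numeric(8)))
  dimnames(st) <- list(v, v)
  dm <- do.call(rbind, lapply(lst$density_marginals, function(row) {
    data.frame(variable = row$variable, meanlog = row$meanlog,
               sdlog = row$sdlog, stringsAsFactors = FALSE)
  }))
  sbt <- NULL
  if (!is.null(lst$stage_by_tscore)) {
    sbt <- vapply(lst$stage_by_tscore, function(col) unlist(col), numeric(4))
    rownames(sbt) <- covariate_levels()$stage
    colnames(sbt) <- score_group_levels()
  }
  hs <- list(
    cancer = list(base_rate = lst$hazard_spec$cancer$base_rate,
                  loghr = lapply(lst$hazard_spec$cancer$loghr, unlist)),
    other = list(base_rate = lst$hazard_spec$other$base_rate,
                 loghr = lapply(lst$hazard_spec$other$loghr, unlist))
  )
  cohort_config(
    n_patients = lst$n_patients,
    seed = lst$seed,
    spearman_targets = st,
    density_marginals = dm,
    covariate_marginals = lapply(lst$covariate_marginals, unlist),
    covariate_missing = unlist(lst$covariate_missing),
    stage_by_tscore = sbt,
    hazard_spec = hs,
    admin_censor_months = lst$admin_censor_months,
    accrual_span_months = lst$accrual_span_months,
    lock_offset_months = lst$lock_offset_months,
    surgical_mortality_count = lst$surgical_mortality_count
  )
}

#' Score group labels
#'
#' @return `c("low", "intermediate", "high")`.
#' @export
score_group_levels <- function() c("low", "intermediate", "high")
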