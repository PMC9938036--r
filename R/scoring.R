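#' Average tissue-core densities into a regional density
#'
#' Each patient contributes 1-4 tissue-microarray cores per region; the
#' regional density is their arithmetic mean.
#'
#' @param core_densities Numeric vector of 1-4 finite nonnegative values.
#' @return The mean density.
#' @export
aggregate_cores <- function(core_densities) {
  if (length(core_densities) == 0) {
    stop("no core densities supplied for region (missing-region)")
  }
  if (length(core_densities) > 4) {
    stop("at most 4 cores per region expected, got ", length(core_densities))
  }
  if (any(!is.finite(core_densities)) || any(core_densities < 0)) {
    stop("core densities must be finite and nonnegative")
  }
  mean(core_densities)
}

#' Convert a cohort density vector to percentiles
#'
#' Hazen percentiles: `100 * (r - 0.5) / n`, where `r` is the ascending rank
#' (ties receive the average rank) and `n` the number of non-missing values.
#' Symmetric around 50, never exactly 0 or 100, and invariant under any
#' strictly increasing transform of the inputs. Missing inputs yield missing
#' percentiles and do not count towards `n`.
#'
#' @param values Numeric vector of cohort densities.
#' @return Numeric vector of percentiles in (0, 100), `NA` where input is.
#' @export
to_percentiles <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n == 0) stop("all values are missing; cannot compute percentiles")
  if (n < 2) stop("need at least 2 non-missing values for percentiles")
  r <- rank(values, na.last = "keep", ties.method = "average")
  100 * (r - 0.5) / n
}

#' Mean of the four component percentiles
#'
#' The per-patient score is the arithmetic mean of the four regional
#' percentile values (marker x region). A patient missing any component has
#' a missing score and is excluded from grouping.
#'
#' @param p1,p2,p3,p4 Numeric vectors of percentiles in \[0, 100\].
#' @return Numeric vector of mean percentiles; `NA` where any component is.
#' @export
mean_percentile <- function(p1, p2, p3, p4) {
  m <- cbind(p1, p2, p3, p4)
  out <- rowMeans(m)
  out[apply(m, 1, anyNA)] <- NA
  unname(out)
}

#' Split cohort scores into three ordinal groups
#'
#' Patients are sorted by ascending score, ties broken by stable input
#' order; groups get `floor(n/3)` patients each, with the remainder
#' allocated one extra patient first to the low, then to the intermediate
#' group. The lowest scores become "low". For n = 221 this yields sizes
#' (74, 74, 73).
#'
#' @param scores Numeric vector; `NA` scores receive `NA` group.
#' @return Factor with levels low/intermediate/high and an attribute
#'   `sizes` (named integer vector of group sizes).
#' @export
tertile_groups <- function(scores) {
  ok <- which(!is.na(scores))
  n <- length(ok)
  if (n < 3) stop("need at least 3 non-missing scores to form tertiles")
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(low = base + (rem >= 1L), intermediate = base + (rem >= 2L),
             high = base)
  ord <- ok[order(scores[ok], ok)]
  lab <- rep(score_group_levels(), times = sizes)
  groups <- factor(rep(NA_character_, length(scores)),
                   levels = score_group_levels())
  groups[ord] <- lab
  attr(groups, "sizes") <- sizes
  groups
}

#' Component density columns of a score
#'
#' @param score_type `"t"` (CD3/CD8) or `"b"` (CD20/CD138).
#' @return Character vector of the four density column names.
#' @export
score_components <- function(score_type) {
  switch(match.arg(score_type, c("t", "b")),
         t = c("cd3_ct", "cd3_im", "cd8_ct", "cd8_im"),
         b = c("cd20_ct", "cd20_im", "cd138_ct", "cd138_im"))
}

#' Compute a percentile-based immune-cell score for a cohort
#'
#' The T cell score combines CD3+ and CD8+ densities in the tumor center
#' and invasive margin; the B cell/plasma cell score combines CD20+ and
#' CD138+ densities in the same regions. Each of the four component
#' densities is converted to cohort-relative Hazen percentiles, the
#' per-patient score is the mean of the four percentiles, and the cohort is
#' split into ordinal low/intermediate/high groups by [tertile_groups()].
#' Percentiles are cohort-relative, so this is a cohort-level operation.
#'
#' @param cohort Cohort data frame with the density columns and
#'   `patient_id`.
#' @param score_type `"t"` or `"b"`.
#' @return Data frame `patient_id`, `score_type`, `mean_percentile`,
#'   `group`, with attributes `sizes` (group sizes) and `excluded`
#'   (patient ids missing a component density).
#' @export
compute_score <- function(cohort, score_type = c("t", "b")) {
  score_type <- match.arg(score_type)
  comp <- score_components(score_type)
  missing_cols <- setdiff(comp, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks density columns: ",
         paste(missing_cols, collapse = ", "))
  }
  pct <- lapply(comp, function(nm) to_percentiles(cohort[[nm]]))
  score <- mean_percentile(pct[[1]], pct[[2]], pct[[3]], pct[[4]])
  groups <- tertile_groups(score)
  out <- data.frame(
    patient_id = cohort$patient_id,
    score_type = toupper(score_type),
    mean_percentile = score,
    group = groups,
    stringsAsFactors = FALSE
  )
  attr(out, "sizes") <- attr(groups, "sizes")
  attr(out, "excluded") <- cohort$patient_id[is.na(score)]
  out
}
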