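#' Cross-tabulate a factor against score groups
#'
#' Counts each (factor level, group) pair among patients with both values
#' non-missing; missing rows are excluded pairwise and reported.
#'
#' @param groups Factor of score groups (columns).
#' @param factor_values Factor of a clinicopathological variable (rows).
#' @param row_name,col_name Labels used in printing.
#' @return Object of class `contingency_table`: list with `counts` (r x c
#'   integer matrix), `row_labels`, `col_labels`, `n_used`, `n_missing`.
#' @export
crosstab <- function(groups, factor_values, row_name = "factor",
                     col_name = "group") {
  if (length(groups) != length(factor_values)) {
    stop("groups and factor_values must have equal length")
  }
  groups <- as.factor(groups)
  factor_values <- as.factor(factor_values)
  ok <- !is.na(groups) & !is.na(factor_values)
  counts <- table(factor_values[ok], groups[ok])
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(
    list(counts = counts,
         row_labels = rownames(counts),
         col_labels = colnames(counts),
         row_name = row_name, col_name = col_name,
         n_used = sum(ok), n_missing = sum(!ok)),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("Contingency table: %s x %s (n = %d, missing = %d)\n",
              x$row_name, x$col_name, x$n_used, x$n_missing))
  print(x$counts)
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Statistic `sum((O - E)^2 / E)` with `E = row_sum * col_sum / n`, no
#' continuity correction; the p-value is the upper tail of the chi-square
#' distribution with `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param table A `contingency_table` from [crosstab()], or a count matrix.
#' @return Object of class `chi_square_result`: list with `statistic`,
#'   `df`, `p_value`.
#' @export
pearson_chi_square <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts else
    as.matrix(table)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least a 2x2 table for the chi-square test")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate table: a row or column sum is zero")
  }
  fit <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(
    list(statistic = unname(fit$statistic),
         df = as.integer(fit$parameter),
         p_value = unname(fit$p.value)),
    class = "chi_square_result"
  )
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Tie-corrected Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks over pairwise-complete
#' observations.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho` and `n` (number of complete pairs).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 pairwise-complete observations")
  xo <- x[ok]
  yo <- y[ok]
  if (length(unique(xo)) < 2 || length(unique(yo)) < 2) {
    stop("constant vector: Spearman correlation undefined")
  }
  rho <- stats::cor(rank(xo, ties.method = "average"),
                    rank(yo, ties.method = "average"))
  list(rho = rho, n = n)
}

#' Pairwise Spearman correlation matrix of the density panel
#'
#' Symmetric matrix with unit diagonal; each off-diagonal entry uses the
#' pairwise-complete observations for that pair of columns.
#'
#' @param densities Numeric matrix or data frame of density columns.
#' @return Symmetric numeric correlation matrix.
#' @export
correlation_matrix <- function(densities) {
  m <- as.matrix(densities)
  p <- ncol(m)
  out <- diag(1, p)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(p - 1)) {
    for (j in seq(i + 1, p)) {
      out[i, j] <- out[j, i] <- spearman_cor(m[, i], m[, j])$rho
    }
  }
  out
}

#' Association table of score groups against every covariate
#'
#' Runs [crosstab()] and [pearson_chi_square()] for each clinicopathological
#' covariate against the score groups, handling missing data pairwise per
#' factor.
#'
#' @param cohort Cohort data frame.
#' @param groups Factor of score groups.
#' @param covariates Covariate column names (default: all eight).
#' @return Named list, one element per covariate, each with the
#'   `contingency_table`, column percentages and the `chi_square_result`.
#' @export
association_table <- function(cohort, groups,
                              covariates = names(covariate_levels())) {
  out <- lapply(covariates, function(nm) {
    tab <- crosstab(groups, cohort[[nm]], row_name = nm)
    test <- pearson_chi_square(tab)
    pct <- sweep(tab$counts, 2, colSums(tab$counts), "/") * 100
    list(table = tab, column_percent = pct, test = test)
  })
  names(out) <- covariates
  out
}
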