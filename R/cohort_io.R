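cohort_columns <- function() {
  c("patient_id", density_variables(), names(covariate_levels()),
    "time_months", "cancer_death", "any_death", "surgical_30day_death")
}

# shortest decimal representation that round-trips the double exactly
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    for (d in c(1, 6, 10, 15)) {
      s <- sprintf(paste0("%.", d, "g"), v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Write a cohort table to a CSV file
#'
#' Comma-separated UTF-8, one row per patient, empty string for missing
#' values. Numeric fields are written with just enough significant digits to
#' round-trip exactly, so `read_cohort(write_cohort(x))` reproduces `x`
#' field-for-field and repeated writes of the same cohort are
#' byte-identical.
#'
#' @param cohort Cohort data frame (see [simulate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(cohort)
  fields <- lapply(cols, function(nm) {
    v <- cohort[[nm]]
    if (nm == "patient_id") {
      x <- as.character(v)
      x[is.na(x)] <- ""
      x
    } else if (nm %in% names(covariate_levels())) {
      x <- as.character(v)
      x[is.na(x)] <- ""
      x
    } else if (nm %in% c("cancer_death", "any_death",
                         "surgical_30day_death")) {
      ifelse(is.na(v), "", as.character(as.integer(v)))
    } else {
      fmt_num(as.numeric(v))
    }
  })
  lines <- c(paste(cols, collapse = ","),
             if (n > 0) do.call(paste, c(fields, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read and validate a cohort CSV file
#'
#' Reads a file written by [write_cohort()] (or matching its schema),
#' checking that all mandatory columns are present, density/time fields are
#' numeric, and categorical fields use the canonical labels of
#' [covariate_levels()]. Violations are reported with row numbers and
#' column names.
#'
#' @param path Path to a cohort CSV.
#' @return Cohort data frame with numeric densities, factor covariates and
#'   integer event indicators.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, check.names = FALSE)
  cols <- cohort_columns()
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  out <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  parse_num <- function(nm) {
    x <- raw[[nm]]
    x[x == ""] <- NA
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(val))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column %s, row %d",
                   x[bad[1]], nm, bad[1]))
    }
    val
  }
  for (nm in density_variables()) {
    val <- parse_num(nm)
    if (any(val < 0, na.rm = TRUE)) {
      stop(sprintf("negative density in column %s, row %d",
                   nm, which(val < 0)[1]))
    }
    out[[nm]] <- val
  }
  levs <- covariate_levels()
  for (nm in names(levs)) {
    x <- raw[[nm]]
    x[x == ""] <- NA
    bad <- which(!is.na(x) & !(x %in% levs[[nm]]))
    if (length(bad)) {
      stop(sprintf(
        "unknown label '%s' in column %s, row %d (expected one of: %s)",
        x[bad[1]], nm, bad[1], paste(levs[[nm]], collapse = ", ")))
    }
    out[[nm]] <- factor(x, levels = levs[[nm]])
  }
  out$time_months <- parse_num("time_months")
  if (any(out$time_months < 0, na.rm = TRUE)) {
    stop(sprintf("negative time_months in row %d",
                 which(out$time_months < 0)[1]))
  }
  for (nm in c("cancer_death", "any_death", "surgical_30day_death")) {
    val <- parse_num(nm)
    bad <- which(!is.na(val) & !(val %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("column %s must be 0/1; bad value in row %d", nm, bad[1]))
    }
    out[[nm]] <- as.integer(val)
  }
  bad <- which(out$cancer_death == 1 & out$any_death == 0)
  if (length(bad)) {
    stop(sprintf("cancer_death = 1 but any_death = 0 in row %d", bad[1]))
  }
  out
}
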