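# Small deterministic cohort for IO / endpoint tests: n patients with
# simple density values, complete covariates, and hand-set survival fields.
tiny_cohort <- function(n = 6) {
  levs <- covariate_levels()
  co <- data.frame(patient_id = sprintf("P%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (v in density_variables()) {
    co[[v]] <- seq_len(n) * 10 + match(v, density_variables())
  }
  for (nm in names(levs)) {
    co[[nm]] <- factor(rep(levs[[nm]], length.out = n),
                       levels = levs[[nm]])
  }
  co$time_months <- seq(10, by = 10, length.out = n)
  co$cancer_death <- rep(c(1L, 0L), length.out = n)
  co$any_death <- co$cancer_death
  co$surgical_30day_death <- 0L
  co
}

# expand a count matrix (rows = factor levels, cols = group levels) into
# paired label vectors, in a scrambled but deterministic order
expand_counts <- function(counts, seed = 42) {
  rows <- rep(rownames(counts), times = rowSums(counts))
  cols <- unlist(lapply(seq_len(nrow(counts)), function(i) {
    rep(colnames(counts), times = counts[i, ])
  }))
  set.seed(seed)
  idx <- sample(length(rows))
  list(factor_values = rows[idx], groups = cols[idx])
}
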