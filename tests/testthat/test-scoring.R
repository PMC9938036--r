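test_that("core aggregation is the arithmetic mean with strict input checks", {
  expect_identical(aggregate_cores(100), 100)
  expect_identical(aggregate_cores(c(0, 0, 0, 0)), 0)
  expect_identical(aggregate_cores(c(10, 20, 30)), 20)
  expect_error(aggregate_cores(numeric(0)), "missing-region")
  expect_error(aggregate_cores(1:5), "at most 4")
  expect_error(aggregate_cores(c(1, NA)), "finite")
  expect_error(aggregate_cores(c(1, -2)), "nonnegative")
})

# independent oracle: percentile from exhaustive pair counting,
# rank_i = #smaller + (#equal + 1) / 2
brute_percentiles <- function(x) {
  n <- sum(!is.na(x))
  sapply(x, function(v) {
    if (is.na(v)) return(NA_real_)
    r <- sum(x < v, na.rm = TRUE) + (sum(x == v, na.rm = TRUE) + 1) / 2
    100 * (r - 0.5) / n
  })
}

test_that("Hazen percentiles match their defining formula", {
  expect_equal(to_percentiles(c(5, 10, 20, 40)),
               c(12.5, 37.5, 62.5, 87.5))
  expect_equal(to_percentiles(rep(7, 5)), rep(50, 5))
  expect_equal(to_percentiles(c(3, 1, 1, 7)), c(62.5, 25, 25, 87.5))
  set.seed(61)
  for (i in 1:20) {
    x <- sample(round(rlnorm(30, 4, 1)))  # rounding forces ties
    x[sample(30, 3)] <- NA
    expect_equal(to_percentiles(x), brute_percentiles(x))
  }
  expect_error(to_percentiles(c(NA, NA)), "missing")
  expect_error(to_percentiles(c(1, NA)), "at least 2")
})

test_that("mean percentile averages four components, NA-propagating", {
  expect_identical(mean_percentile(50, 50, 50, 50), 50)
  expect_identical(mean_percentile(0, 100, 0, 100), 50)
  expect_identical(mean_percentile(12.5, 37.5, 62.5, 87.5), 50)
  expect_equal(mean_percentile(c(10, 20), c(30, NA), c(50, 60), c(70, 80)),
               c(40, NA))
})

# independent oracle for the remainder rule: sizes by direct allocation
brute_sizes <- function(n) {
  sizes <- rep(n %/% 3, 3)
  for (i in seq_len(n %% 3)) sizes[i] <- sizes[i] + 1
  sizes
}

test_that("tertile grouping follows the stable remainder rule", {
  set.seed(62)
  g221 <- tertile_groups(runif(221))
  expect_identical(unname(attr(g221, "sizes")), c(74L, 74L, 73L))

  s9 <- c(5, 1, 9, 3, 7, 2, 8, 4, 6)
  g9 <- tertile_groups(s9)
  expect_identical(unname(attr(g9, "sizes")), c(3L, 3L, 3L))
  expect_identical(as.character(g9[s9 <= 3]), rep("low", 3))
  expect_identical(as.character(g9[s9 >= 7]), rep("high", 3))

  g7 <- tertile_groups(1:7)
  expect_identical(unname(attr(g7, "sizes")), c(3L, 2L, 2L))
  for (n in c(3, 5, 10, 220, 221, 222)) {
    expect_identical(unname(attr(tertile_groups(seq_len(n)), "sizes")),
                     as.integer(brute_sizes(n)))
  }

  # stable tie-break: equal scores are split in input order
  g <- tertile_groups(c(1, 1, 1, 1, 1, 1))
  expect_identical(as.character(g),
                   c("low", "low", "intermediate", "intermediate",
                     "high", "high"))
  expect_error(tertile_groups(c(1, 2)), "at least 3")

  # NA scores get NA group and do not count towards sizes
  gna <- tertile_groups(c(4, NA, 1, 2, 3, NA, 5, 6))
  expect_identical(sum(is.na(gna)), 2L)
  expect_identical(unname(attr(gna, "sizes")), c(2L, 2L, 2L))
})

test_that("cohort scores are rank-invariant and sum to the right structure", {
  co <- simulate_cohort(cohort_config(n_patients = 101), seed = 63)
  ts <- compute_score(co, "t")
  expect_identical(unname(attr(ts, "sizes")), c(34L, 34L, 33L))
  expect_equal(mean(ts$mean_percentile), 50)

  # strictly increasing per-marker transform leaves scores and groups alone
  co2 <- co
  for (v in score_components("t")) co2[[v]] <- co2[[v]]^2
  ts2 <- compute_score(co2, "t")
  expect_identical(ts2$group, ts$group)
  expect_equal(ts2$mean_percentile, ts$mean_percentile)

  # permuting patients permutes outputs identically (distinct scores)
  set.seed(64)
  perm <- sample(nrow(co))
  ts3 <- compute_score(co[perm, ], "t")
  expect_identical(ts3$patient_id, ts$patient_id[perm])
  expect_equal(ts3$mean_percentile, ts$mean_percentile[perm])
  expect_identical(as.character(ts3$group), as.character(ts$group[perm]))
})

test_that("a patient dominating all four markers scores highest", {
  co <- tiny_cohort(9)
  for (v in score_components("b")) co[[v]] <- seq_len(9)
  co[9, score_components("b")] <- 1000
  bs <- compute_score(co, "b")
  expect_identical(which.max(bs$mean_percentile), 9L)
  expect_identical(as.character(bs$group[9]), "high")
})

test_that("patients missing a component are excluded and reported", {
  co <- tiny_cohort(10)
  co$cd3_im[4] <- NA
  ts <- compute_score(co, "t")
  expect_true(is.na(ts$mean_percentile[4]))
  expect_true(is.na(ts$group[4]))
  expect_identical(attr(ts, "excluded"), "P04")
  expect_identical(sum(attr(ts, "sizes")), 9L)
})
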