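test_that("epoch generation is bit-reproducible for a fixed seed", {
  e1 <- generate_epoch("PMCI", 2, duration = 4, seed = 99)
  e2 <- generate_epoch("PMCI", 2, duration = 4, seed = 99)
  expect_identical(e1$data, e2$data)
  e3 <- generate_epoch("PMCI", 2, duration = 4, seed = 100)
  expect_false(identical(e1$data, e3$data))
})

test_that("generated epochs honour the montage and config contracts", {
  ep <- generate_epoch("SMCI", 1, duration = 4, fs = 100, seed = 5)
  expect_identical(ep$channels, eeg_channels())
  expect_equal(dim(ep$data), c(16L, 400L))
  expect_true(all(is.finite(ep$data)))

  expect_error(generate_epoch("SMCI", 1, duration = 2, seed = 1),
               class = "eegtraj_invalid_config")
  expect_error(generate_epoch("SMCI", 1, fs = 50, seed = 1),
               class = "eegtraj_invalid_config")
  expect_error(generate_cohort(n_smci = 0, n_pmci = 3, seed = 1),
               class = "eegtraj_invalid_config")
  expect_error(effect_schedule(array(-1, c(2, 4, 5)), matrix(0.5, 2, 4),
                               matrix(0.5, 2, 4)),
               class = "eegtraj_invalid_config")
})

test_that("the default cohort has 38 stable and 27 progressive subjects", {
  co <- generate_cohort(timepoints = 1, duration = 4, fs = 100, seed = 2)
  expect_length(co, 65)
  groups <- vapply(co$subjects, function(s) s$group, character(1))
  expect_equal(sum(groups == "SMCI"), 38)
  expect_equal(sum(groups == "PMCI"), 27)
  ids <- vapply(co$subjects, function(s) s$subject_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("cohort generation is deterministic and epochs carry identity", {
  co1 <- generate_cohort(n_smci = 2, n_pmci = 2, timepoints = 1:2,
                         duration = 4, seed = 8)
  co2 <- generate_cohort(n_smci = 2, n_pmci = 2, timepoints = 1:2,
                         duration = 4, seed = 8)
  expect_identical(co1$subjects[[3]]$epochs[["2"]]$data,
                   co2$subjects[[3]]$epochs[["2"]]$data)
  expect_equal(co1$subjects[[3]]$epochs[["2"]]$timepoint, 2L)
  expect_equal(co1$subjects[[3]]$epochs[["1"]]$subject_id,
               co1$subjects[[3]]$subject_id)
})

mean_ratio2 <- function(epoch) {
  pw <- band_powers(welch_psd(epoch))
  mean(pw[, "theta"] / pw[, "alpha"])
}

test_that("a null schedule produces no group difference in theta/alpha", {
  diffs <- vapply(1:6, function(s) {
    co <- generate_cohort(n_smci = 6, n_pmci = 6, timepoints = 3,
                          schedule = null_effect_schedule(),
                          duration = 6, seed = 500 + s)
    r2 <- vapply(co$subjects, function(su) mean_ratio2(su$epochs[["3"]]),
                 numeric(1))
    g <- cohort_groups(co)
    mean(r2[g == "PMCI"]) - mean(r2[g == "SMCI"])
  }, numeric(1))
  # replicate-level t test: mean difference indistinguishable from zero
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("PMCI theta/alpha rises from timepoint 1 to 3 (paired sign test)", {
  co <- generate_cohort(n_smci = 1, n_pmci = 27, timepoints = c(1, 3),
                        duration = 8, seed = 77)
  pmci <- Filter(function(s) s$group == "PMCI", co$subjects)
  r2_t1 <- vapply(pmci, function(s) mean_ratio2(s$epochs[["1"]]), numeric(1))
  r2_t3 <- vapply(pmci, function(s) mean_ratio2(s$epochs[["3"]]), numeric(1))
  bt <- binom.test(sum(r2_t3 > r2_t1), length(pmci), alternative = "greater")
  expect_lt(bt$p.value, 0.05)
})

test_that("raising the PMCI theta multiplier raises expected Ratio2", {
  s_lo <- default_effect_schedule()
  s_hi <- default_effect_schedule()
  s_hi$band_mult["PMCI", 3, "theta"] <- s_hi$band_mult["PMCI", 3, "theta"] * 1.5
  r2 <- function(sch, seed) {
    mean_ratio2(generate_epoch("PMCI", 3, sch, duration = 8, seed = seed))
  }
  vals <- vapply(1:4, function(s) r2(s_hi, 900 + s) - r2(s_lo, 900 + s),
                 numeric(1))
  expect_true(all(vals > 0))
})

test_that("kappa drives the alpha-band synchrony extremes", {
  lo <- generate_epoch("SMCI", 1, null_effect_schedule(kappa = 0),
                       duration = 30, seed = 61)
  expect_lt(mean(connectivity_features(lo)), 0.2)

  hi <- generate_epoch("SMCI", 1, null_effect_schedule(kappa = 1, rho = 1),
                       duration = 30, seed = 62)
  expect_gt(mean(connectivity_features(hi)), 0.8)
})

test_that("cohorts round-trip through the plain-text array format", {
  co <- generate_cohort(n_smci = 2, n_pmci = 1, timepoints = 1:2,
                        duration = 4, seed = 12)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_equal(nrow(manifest), 6)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "cohort.json")))

  back <- read_cohort(dir)
  expect_length(back, 3)
  orig <- co$subjects[[1]]$epochs[["1"]]
  got <- back$subjects[[which(vapply(back$subjects, function(s) s$subject_id,
                                     character(1)) ==
                                co$subjects[[1]]$subject_id)]]$epochs[["1"]]
  expect_equal(got$data, orig$data, tolerance = 1e-12)
  expect_equal(got$fs, orig$fs)
})
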