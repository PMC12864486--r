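test_that("trend descriptors match direct evaluation", {
  s <- longitudinal_stats(c(1, 2, 4), times = c(0, 4, 8))
  expect_equal(unname(s["MF"]), 7 / 3, tolerance = 1e-4)
  expect_equal(unname(s["SDF"]), sd(c(1, 2, 4)), tolerance = 1e-4)
  expect_equal(unname(s["RF"]), 3)
  expect_equal(unname(s["AF"]), 18)  # (1+2)/2*4 + (2+4)/2*4
  expect_equal(unname(s["MVF"]), 0.375)
  expect_equal(unname(s["SDVF"]), sd(c(0.25, 0.5)), tolerance = 1e-4)
})

test_that("flat trajectories have zero dispersion and velocity", {
  for (c_ in c(-2, 0.5, 7)) {
    s <- longitudinal_stats(rep(c_, 3))
    expect_equal(unname(s), c(c_, 0, 0, 8 * c_, 0, 0))
  }
})

test_that("time reversal preserves level/dispersion and flips velocity", {
  s_fwd <- longitudinal_stats(c(1, 2, 4))
  s_rev <- longitudinal_stats(c(4, 2, 1))
  expect_equal(s_fwd[c("MF", "SDF", "RF", "AF")],
               s_rev[c("MF", "SDF", "RF", "AF")])
  expect_equal(unname(s_fwd["MVF"]), -unname(s_rev["MVF"]))
  expect_equal(unname(s_fwd["SDVF"]), unname(s_rev["SDVF"]))
})

test_that("descriptors transform linearly under a*x + b", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(3)
    a <- rnorm(1); b <- rnorm(1)
    s0 <- longitudinal_stats(x)
    s1 <- longitudinal_stats(a * x + b)
    expect_equal(unname(s1["MF"]), a * unname(s0["MF"]) + b, tolerance = 1e-10)
    expect_equal(unname(s1["SDF"]), abs(a) * unname(s0["SDF"]), tolerance = 1e-10)
    expect_equal(unname(s1["RF"]), abs(a) * unname(s0["RF"]), tolerance = 1e-10)
    expect_equal(unname(s1["AF"]), a * unname(s0["AF"]) + b * 8, tolerance = 1e-9)
    expect_equal(unname(s1["MVF"]), a * unname(s0["MVF"]), tolerance = 1e-10)
    expect_equal(unname(s1["SDVF"]), abs(a) * unname(s0["SDVF"]), tolerance = 1e-10)
  }
})

test_that("the span-slope option adds the first-to-last velocity", {
  s <- longitudinal_stats(c(1, 2, 4), include_span_slope = TRUE)
  expect_equal(unname(s["MVF"]), mean(c(0.25, 0.5, 3 / 8)))
})

test_that("invalid trajectories are rejected", {
  expect_error(longitudinal_stats(c(1, 2)), class = "eegtraj_invalid_input")
  expect_error(longitudinal_stats(c(1, 2, NA)), class = "eegtraj_invalid_input")
  expect_error(longitudinal_stats(c(1, 2, 3), times = c(0, 8, 4)),
               class = "eegtraj_invalid_input")
})

fake_features <- function(ids, groups, tps = 1:3, p = 4, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject_id = ids, timepoint = tps,
                      stringsAsFactors = FALSE)
  rows$group <- groups[match(rows$subject_id, ids)]
  X <- matrix(rnorm(nrow(rows) * p), ncol = p,
              dimnames = list(NULL, paste0("feat", seq_len(p))))
  cbind(rows[, c("subject_id", "group", "timepoint")], X)
}

test_that("the longitudinal table has 6 x P columns in canonical order", {
  fe <- fake_features(c("a", "b", "c", "d"), c("SMCI", "SMCI", "PMCI", "PMCI"))
  tab <- build_feature_table(fe)
  cols <- table_feature_cols(tab)
  expect_length(cols, 6 * 4)
  expect_identical(cols[1:6], paste0("feat1__", c("MF", "SDF", "RF", "AF",
                                                  "MVF", "SDVF")))
  expect_identical(tab$label, c(0L, 0L, 1L, 1L))

  # values in the table equal per-subject descriptor computation
  a_vals <- fe[fe$subject_id == "a", ][order(fe$timepoint[fe$subject_id == "a"]), "feat2"]
  expect_equal(unname(unlist(tab[1, paste0("feat2__", c("MF", "SDF", "RF",
                                                        "AF", "MVF", "SDVF"))])),
               unname(longitudinal_stats(a_vals)))
})

test_that("subjects missing a required timepoint are excluded with a warning", {
  fe <- fake_features(c("a", "b", "c"), c("SMCI", "SMCI", "PMCI"))
  fe <- fe[!(fe$subject_id == "b" & fe$timepoint == 2), ]
  expect_warning(tab <- build_feature_table(fe), "excluding 1 subject")
  expect_equal(nrow(tab), 2)
  expect_false("b" %in% tab$subject_id)
})
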