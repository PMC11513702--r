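test_that("identical groups yield null pairwise contrasts with adjusted p = 1", {
  base <- simulate_study_table(n_patients = 10, seed = 30)
  # duplicate every patient's teeth into both factor levels: exact mirror
  dup <- base
  dup$recession_type <- ifelse(base$recession_type == "RT1", "RT2", "RT1")
  dup$tooth_id <- paste0(base$tooth_id, "_m")
  tab <- rbind(base, dup)
  gc <- group_compare(tab, "recession_reduction", "recession_type")
  expect_equal(gc$pairwise$estimate, 0, tolerance = 1e-9)
  expect_equal(gc$pairwise$p_scheffe, 1, tolerance = 1e-6)
})

test_that("Scheffe adjustment never falls below the unadjusted p-value", {
  for (seed in 1:5) {
    tab <- simulate_study_table(seed = seed, factor = "tooth_type",
                                levels = c("incisor", "canine", "premolar",
                                           "molar"),
                                effects = c(0, 0.1, -0.1, 0.25))
    gc <- group_compare(tab, "recession_reduction", "tooth_type")
    expect_equal(nrow(gc$pairwise), 6L)
    expect_true(all(gc$pairwise$p_scheffe >= gc$pairwise$p_unadjusted - 1e-12))
    # ordering of contrasts does not affect the adjusted values
    expect_identical(gc$pairwise$p_scheffe,
                     group_compare(tab, "recession_reduction",
                                   "tooth_type")$pairwise$p_scheffe)
  }
})

test_that("the clustered factor test keeps its nominal type-I error", {
  pv <- vapply(1:300, function(s)
    group_compare(simulate_study_table(seed = s),
                  "recession_reduction", "recession_type")$overall_p, 0)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.03)
})

test_that("a true group difference is recovered with near-nominal CI coverage", {
  hits <- vapply(1:150, function(s) {
    tab <- simulate_study_table(seed = 5000 + s, effects = c(0, 0.5),
                                sd_resid = 0.3)
    pw <- group_compare(tab, "recession_reduction", "recession_type")$pairwise
    pw$lower <= -0.5 && -0.5 <= pw$upper
  }, TRUE)
  expect_gte(mean(hits), 0.93)
})

test_that("fixed-patient models are supported as the literal reading", {
  tab <- simulate_study_table(seed = 77, effects = c(0, 0.4))
  gc <- group_compare(tab, "recession_reduction", "recession_type",
                      patient_effect = "fixed")
  expect_true(is.finite(gc$overall_p))
  expect_equal(nrow(gc$levels), 2L)
  expect_error(group_compare(tab[tab$recession_type == "RT1", ],
                             "recession_reduction", "recession_type"),
               "single level")
})

test_that("ICC is exact on degenerate fixtures and matches the variance-ratio oracle", {
  x <- matrix(rnorm(40, 5, 2), 20, 2)
  same <- cbind(x[, 1], x[, 1], x[, 1])
  expect_equal(icc(same)$estimate, 1)
  expect_equal(icc(same, form = "ICC3_1")$estimate, 1)
  # invariance under adding a constant
  y <- x + matrix(rnorm(40, 0, 0.1), 20, 2)
  expect_equal(icc(y)$estimate, icc(y + 100)$estimate, tolerance = 1e-9)
  expect_true(abs(icc(y)$estimate) <= 1)
  # pure noise: no row effect
  set.seed(9)
  noise <- matrix(rnorm(2000), 500, 4)
  expect_lt(abs(icc(noise)$estimate), 0.1)
  # closed-form oracle: ICC = s2_row / (s2_row + s2_col + s2_e)
  set.seed(10)
  est <- replicate(30, {
    m <- outer(rnorm(200, 0, 3), rep(1, 3)) +
      matrix(rnorm(600), 200, 3)
    icc(m)$estimate
  })
  expect_equal(mean(est), 9 / (9 + 1), tolerance = 0.02)
  ci <- icc(outer(rnorm(100, 0, 3), rep(1, 3)) + matrix(rnorm(300), 100, 3))
  expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
})

test_that("ICC input validation and degenerate cases behave as documented", {
  expect_error(icc(matrix(1:4, 2, 2)), "at least 5")
  expect_error(icc(matrix(1:10, 10, 1)), "at least 2")
  expect_warning(out <- icc(matrix(5, 10, 2) +
                              cbind(rep(0, 10), rnorm(10, 0, 1e-9))),
                 "zero between-tooth variance")
  expect_equal(out$estimate, 0)
  withmiss <- matrix(rnorm(40), 20, 2)
  withmiss[3, 1] <- NA
  expect_warning(res <- icc(withmiss), "dropped")
  expect_equal(res$n, 19L)
})

test_that("the non-inferiority sample size reproduces the planned 66 teeth", {
  ss <- noninferiority_sample_size(reference_mean = 87, margin = 10, sd = 25,
                                   power = 0.90, alpha = 0.05, vif = 3)
  expect_identical(ss$n_required, 66L)
  expect_identical(ss$n_vif_adjusted, 198L)
  expect_identical(noninferiority_sample_size(margin = 20)$n_required, 17L)
  expect_identical(noninferiority_sample_size(sd = 0)$n_required, 1L)
})

test_that("sample size is monotone in sd, power and margin", {
  n_of <- function(...) noninferiority_sample_size(...)$n_required
  sds <- vapply(c(10, 20, 30, 40), function(s) n_of(sd = s), 0L)
  expect_true(all(diff(sds) >= 0))
  pows <- vapply(c(0.7, 0.8, 0.9, 0.95), function(p) n_of(power = p), 0L)
  expect_true(all(diff(pows) >= 0))
  margins <- vapply(c(5, 10, 15, 20), function(m) n_of(margin = m), 0L)
  expect_true(all(diff(margins) <= 0))
  expect_error(n_of(power = 0.04), "power")
  expect_error(n_of(margin = 300), "margin")
})

test_that("the outcome summary reproduces study-style counts", {
  tab <- simulate_study_table(n_patients = 19, seed = 12)  # 82 teeth
  tab$recession_depth_pre <- abs(tab$recession_reduction) + 0.5
  tab$recession_depth_post <- tab$recession_depth_pre - tab$recession_reduction
  tab$mrc_percent <- 100 * tab$recession_reduction / tab$recession_depth_pre
  tab$thickness_gain <- 0.33
  tab$jaw <- rep(c("maxilla", "mandible"), c(38, 44))
  s <- summarize_outcomes(tab)
  expect_identical(s$counts$teeth, 82L)
  expect_identical(s$counts$patients, 19L)
  expect_equal(unname(unlist(s$counts$jaw[c("maxilla", "mandible")])),
               c(38L, 44L))
  expect_equal(s$outcomes$mean[s$outcomes$parameter == "thickness_gain"], 0.33)
  expect_equal(s$crc_percent,
               round(100 * mean(tab$recession_depth_post <= 0), 2))
})
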