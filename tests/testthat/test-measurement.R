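test_that("the deepest recession point is the axial argmin with index ties", {
  m <- rbind(c(0, 0, 2), c(0, 0, 1), c(0, 0, 3))
  expect_equal(deepest_recession_point(m, c(0, 0, 1)), c(0, 0, 1))
  same <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(deepest_recession_point(same, c(0, 0, 1)), c(1, 2, 3))
  # tie between distinct points resolves to the first
  tie <- rbind(c(5, 0, 1), c(-5, 0, 1), c(0, 0, 2))
  expect_equal(deepest_recession_point(tie, c(0, 0, 1)), c(5, 0, 1))
  expect_error(deepest_recession_point(matrix(0, 0, 3), c(0, 0, 1)), "point")
})

test_that("recession depth is the axial gap to the in-plane-nearest CEJ point", {
  ax <- c(0, 0, 1)
  cej <- rbind(c(0, 0, 3), c(4, 0, 7))  # second point is a distant CEJ arm
  expect_equal(recession_depth(c(0, 0, 1.5), cej, ax), 1.5)
  expect_equal(recession_depth(c(0, 0, 3), cej, ax), 0)
  expect_equal(recession_depth(c(0, 0, 3.4), cej, ax), -0.4)  # beyond the CEJ
  expect_error(recession_depth(c(0, 0, 1), NULL, ax), class = "cej_unavailable")
})

test_that("recession reduction is signed, CEJ-free, and mode-consistent", {
  ax <- c(0, 0, 1)
  p <- c(1, 2, 3)
  expect_equal(recession_reduction(p, p, ax), 0)
  expect_equal(recession_reduction(p, p + ax, ax), 1)           # axial case
  expect_equal(recession_reduction(p, p - 2 * ax, ax), -2)      # worsening
  q <- p + c(3, 4, 5)
  expect_equal(recession_reduction(p, q, ax), sqrt(50))
  expect_equal(recession_reduction(p, q, ax, mode = "axial"), 5)
  # pure-axial displacement limit: both modes give d
  d <- 0.87
  expect_equal(recession_reduction(p, p + d * ax, ax), d, tolerance = 1e-12)
  expect_equal(recession_reduction(p, p + d * ax, ax, mode = "axial"), d,
               tolerance = 1e-12)
})

test_that("mRC and cRC implement the percentage definitions", {
  rec <- data.frame(tooth_id = c("a", "b", "c"),
                    recession_depth_pre = c(2, 2, 2),
                    recession_depth_post = c(0, 1, -0.2))
  m <- mean_root_coverage(rec)
  expect_equal(m$per_tooth$mrc_percent, c(100, 50, 110))
  expect_equal(m$n, 3L)
  expect_warning(
    mean_root_coverage(rbind(rec, data.frame(tooth_id = "d",
                                             recession_depth_pre = 0,
                                             recession_depth_post = 0))),
    "excluded")
  expect_equal(complete_root_coverage(rec), round(100 * 2 / 3, 2))
  none <- data.frame(recession_depth_post = c(1, 2))
  expect_equal(complete_root_coverage(none), 0)
  all_cov <- data.frame(recession_depth_post = c(0, -1))
  expect_equal(complete_root_coverage(all_cov), 100)
})

test_that("identical meshes give a flat full-profile thickness record", {
  pair <- fixture("pair10_clean")
  ann <- pair$annotations[[3]]
  apex <- deepest_recession_point(ann$margin_pre, ann$coronal_axis)
  thk <- thickness_profile(pair$pre, pair$pre, apex, ann$coronal_axis,
                           ann$buccal_normal)
  expect_equal(thk$measurement_mode, "full_profile")
  expect_equal(nrow(thk$samples), 7L)
  expect_true(all(thk$samples$valid))
  expect_equal(thk$thickness_gain, 0, tolerance = 1e-9)
  expect_equal(max(abs(thk$samples$deviation)), 0, tolerance = 1e-9)
})

test_that("a uniform buccal inflation is recovered at each profile sample", {
  pair <- fixture("pair10_clean")
  reg <- truth_registration(pair)
  post_reg <- apply_transform(pair$post, reg)
  tr <- pair$truth$teeth
  clean_teeth <- which(!tr$artifact)
  for (i in clean_teeth[c(1, ceiling(length(clean_teeth) / 2),
                          length(clean_teeth))]) {
    ann <- pair$annotations[[i]]
    apex <- deepest_recession_point(ann$margin_pre, ann$coronal_axis)
    thk <- thickness_profile(pair$pre, post_reg, apex, ann$coronal_axis,
                             ann$buccal_normal)
    expect_equal(thk$thickness_gain, tr$true_thickness_gain[i],
                 tolerance = 0.02)
    expect_equal(thk$measurement_mode, "full_profile")
  }
  # the apex-excluded grid variant remains a 6-sample mean
  i <- clean_teeth[2]
  ann <- pair$annotations[[i]]
  apex <- deepest_recession_point(ann$margin_pre, ann$coronal_axis)
  thk6 <- thickness_profile(pair$pre, post_reg, apex, ann$coronal_axis,
                            ann$buccal_normal, include_apex = FALSE)
  expect_equal(thk6$thickness_gain, tr$true_thickness_gain[i], tolerance = 0.02)
})

test_that("impression artifacts trigger the single-point fallback", {
  pair <- fixture("pair8_artifact")
  tr <- pair$truth$teeth
  expect_gt(sum(tr$artifact), 0)
  rec <- assess_case(pair$pre, pair$post, pair$annotations,
                     truth_registration(pair))
  expect_identical(rec$measurement_mode == "apex_only", tr$artifact)
  samp <- attr(rec, "thickness_samples")
  for (i in which(tr$artifact)) {
    s <- samp[[sprintf("%s.1.1", tr$tooth_id[i])]]
    expect_gte(sum(!s$valid), 1L)                  # >= 1 invalid sample
    expect_true(s$valid[s$offset == 0])            # mid-axis band intact
    expect_equal(rec$thickness_gain[i], s$deviation[s$offset == 0])
    expect_equal(rec$thickness_gain[i], tr$true_thickness_gain[i],
                 tolerance = 0.02)
  }
})

test_that("noise-free assessment reproduces the ground truth end to end", {
  pair <- fixture("pair10_clean")
  rec <- assess_case(pair$pre, pair$post, pair$annotations,
                     truth_registration(pair))
  tr <- pair$truth$teeth
  expect_equal(rec$recession_depth_pre, tr$true_recession_depth_pre,
               tolerance = 1e-6)
  expect_equal(rec$recession_depth_post, tr$true_recession_depth_post,
               tolerance = 1e-6)
  expect_equal(rec$recession_reduction, tr$true_reduction, tolerance = 1e-6)
  expect_identical(rec$complete_coverage, tr$complete_coverage)
  expect_equal(rec$thickness_gain, tr$true_thickness_gain, tolerance = 1e-3)
})

test_that("per-tooth record invariants hold on measured data", {
  pair <- fixture("pair10_noisy")
  rec <- assess_case(pair$pre, pair$post, pair$annotations,
                     register_case(pair$pre, pair$post, pair$annotations))
  at100 <- abs(rec$mrc_percent - 100) < 1e-9
  expect_identical(at100, abs(rec$recession_depth_post) < 1e-9 *
                     pmax(1, rec$recession_depth_pre))
  expect_true(all(rec$mrc_percent[rec$complete_coverage] >= 100 - 1e-9))
})

test_that("reduction is invariant under a common rigid motion and needs no CEJ", {
  pair <- fixture("pair10_clean")
  reg <- truth_registration(pair)
  rec0 <- assess_case(pair$pre, pair$post, pair$annotations, reg)
  extra <- compose_transform(rotation_about(c(1, 1, 0), 31),
                             rigid_transform(diag(3), c(5, -3, 2)))
  pre2 <- apply_transform(pair$pre, extra)
  post2 <- pair$post
  ann2 <- lapply(pair$annotations, function(a) {
    a$margin_pre <- apply_transform(a$margin_pre, extra)
    a$cej <- NULL                                  # CEJ never consulted
    a$coronal_axis <- apply_transform(a$coronal_axis, rigid_transform(extra$rotation))
    a$buccal_normal <- apply_transform(a$buccal_normal, rigid_transform(extra$rotation))
    a
  })
  reg2 <- compose_transform(extra, reg)
  rec2 <- assess_case(pre2, post2, ann2, reg2)
  expect_equal(rec2$recession_reduction, rec0$recession_reduction,
               tolerance = 1e-9)
  expect_true(all(is.na(rec2$recession_depth_pre)))  # CEJ metrics unavailable
  expect_true(all(is.na(rec2$mrc_percent)))
})

test_that("replicated measurements with landmark jitter stay near truth", {
  pair <- fixture("pair10_clean")
  rec <- assess_case(pair$pre, pair$post, pair$annotations,
                     truth_registration(pair), raters = 2, replicates = 2,
                     landmark_sd = 0.03, seed = 4)
  expect_equal(nrow(rec), 40L)
  expect_identical(anyDuplicated(paste(rec$tooth_id, rec$rater_id,
                                       rec$replicate_index)), 0L)
  err <- abs(rec$recession_reduction -
               rep(pair$truth$teeth$true_reduction, each = 4))
  expect_lt(mean(err), 0.1)
  # deterministic given the seed
  rec2 <- assess_case(pair$pre, pair$post, pair$annotations,
                      truth_registration(pair), raters = 2, replicates = 2,
                      landmark_sd = 0.03, seed = 4)
  expect_identical(rec, rec2)
})

test_that("heat-map deviations reflect the thickness-gain band sign", {
  pair <- fixture("pair10_clean")
  post_reg <- apply_transform(pair$post, truth_registration(pair))
  dev <- deviation_heatmap(pair$pre, post_reg)
  expect_length(dev, nrow(pair$pre$vertices))
  expect_lt(stats::median(abs(dev)), 0.05)  # most of the arch is unchanged
  path <- withr::local_tempfile(fileext = ".ply")
  write_ply(pair$pre, dev, path)
  head <- readLines(path, n = 9)
  expect_true(any(grepl("property float quality", head)))
})
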