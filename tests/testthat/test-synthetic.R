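test_that("generation is fully reproducible from the seed", {
  p <- arch_params(n_teeth = 4, seed = 21, mesh_edge_length = 0.5)
  g1 <- generate_arch_pair(p)
  g2 <- generate_arch_pair(p)
  expect_identical(g1$pre$vertices, g2$pre$vertices)
  expect_identical(g1$post$vertices, g2$post$vertices)
  expect_identical(g1$truth$teeth, g2$truth$teeth)
  expect_identical(g1$truth$applied_transform, g2$truth$applied_transform)
})

test_that("per-tooth draws do not depend on tooth count or ordering", {
  g4 <- generate_arch_pair(arch_params(n_teeth = 4, seed = 21,
                                       mesh_edge_length = 0.5))
  g6 <- generate_arch_pair(arch_params(n_teeth = 6, seed = 21,
                                       mesh_edge_length = 0.5))
  expect_equal(g4$truth$teeth$true_recession_depth_pre,
               g6$truth$teeth$true_recession_depth_pre[1:4])
})

test_that("ground truth satisfies its own invariants", {
  tr <- fixture("pair10_noisy")$truth$teeth
  expect_true(all(tr$true_recession_depth_pre >= 0))
  expect_equal(tr$true_reduction,
               tr$true_recession_depth_pre - tr$true_recession_depth_post,
               tolerance = 1e-9)
  expect_identical(tr$complete_coverage, tr$true_recession_depth_post <= 0)
})

test_that("drawn depths are calibrated to the requested distribution", {
  # pool per-tooth draws across patient-sized arches to study scale (82 teeth)
  counts <- c(rep(4, 13), rep(5, 6))
  d <- unlist(lapply(seq_along(counts), function(i)
    generate_arch_pair(arch_params(n_teeth = counts[i], seed = 100 + i,
                                   mesh_edge_length = 0.8)
    )$truth$teeth$true_recession_depth_pre))
  expect_length(d, 82L)
  expect_lt(abs(mean(d) - 1.34), 3 * 0.92 / sqrt(82))
  expect_true(all(d >= 0 & d <= 5))
})

test_that("degenerate full coverage puts every post margin at the CEJ", {
  p <- arch_params(n_teeth = 4, seed = 8, noise_sd = 0,
                   coverage_fraction_distribution = c(mean = 1, sd = 0),
                   thickness_gain_distribution = c(mean = 0, sd = 0),
                   mesh_edge_length = 0.5)
  g <- generate_arch_pair(p)
  rec <- assess_case(g$pre, g$post, g$annotations, truth_registration(g))
  expect_equal(rec$recession_depth_post, rep(0, 4), tolerance = 1e-9)
  expect_true(all(rec$complete_coverage))
  expect_true(all(g$truth$teeth$complete_coverage))
})

test_that("the no-change limit produces identical meshes and zero reduction", {
  p <- arch_params(n_teeth = 4, seed = 8, noise_sd = 0,
                   max_rotation_deg = 0, max_translation_mm = 0,
                   coverage_fraction_distribution = c(mean = 0, sd = 0),
                   thickness_gain_distribution = c(mean = 0, sd = 0),
                   artifact_probability = 0, mesh_edge_length = 0.5)
  g <- generate_arch_pair(p)
  expect_equal(g$pre$vertices, g$post$vertices, tolerance = 1e-12)
  expect_equal(g$truth$teeth$true_reduction, rep(0, 4))
  rec <- assess_case(g$pre, g$post, g$annotations, rigid_transform())
  expect_equal(rec$recession_reduction, rep(0, 4), tolerance = 1e-9)
  expect_equal(rec$thickness_gain, rep(0, 4), tolerance = 1e-9)
})

test_that("artifact injection is seed-deterministic and probability-gated", {
  g0 <- generate_arch_pair(arch_params(n_teeth = 6, seed = 3,
                                       artifact_probability = 0,
                                       mesh_edge_length = 0.5))
  expect_false(any(g0$truth$teeth$artifact))
  expect_false(any(vapply(g0$annotations, `[[`, FALSE, "artifact_flag")))
  # inject into an artifact-free follow-up mesh (landmarks share its frame)
  i <- 2L
  m1 <- inject_artifact(g0$post, g0$annotations[[i]], seed = 42)
  m2 <- inject_artifact(g0$post, g0$annotations[[i]], seed = 42)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$faces, m2$faces)
  expect_lt(nrow(m1$faces), nrow(g0$post$faces))  # crater removes geometry
})

test_that("maxillary arches mirror the frame consistently", {
  p <- arch_params(n_teeth = 4, jaw = "maxilla", seed = 13, noise_sd = 0,
                   mesh_edge_length = 0.5)
  g <- generate_arch_pair(p)
  expect_equal(g$annotations[[1]]$coronal_axis, c(0, 0, -1))
  rec <- assess_case(g$pre, g$post, g$annotations, truth_registration(g))
  expect_equal(rec$recession_depth_pre,
               g$truth$teeth$true_recession_depth_pre, tolerance = 1e-6)
  expect_equal(rec$recession_reduction, g$truth$teeth$true_reduction,
               tolerance = 1e-6)
})

test_that("invalid generator parameters are rejected", {
  expect_error(arch_params(n_teeth = 0), "n_teeth")
  expect_error(arch_params(arch_radius = -1), "> 0")
  expect_error(arch_params(artifact_probability = 1.5), "\\[0, 1\\]")
})

test_that("ground truth survives a file round trip", {
  pair <- fixture("pair8_artifact")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth(pair$truth, path)
  back <- read_truth(path)
  expect_equal(back$teeth$true_reduction, pair$truth$teeth$true_reduction)
  expect_equal(back$applied_transform$rotation,
               pair$truth$applied_transform$rotation, tolerance = 1e-12)
  expect_identical(back$n_vertices_pre, pair$truth$n_vertices_pre)
})
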