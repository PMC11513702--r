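# Shared fixtures, built once per session. All synthetic; nothing on disk.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!is.null(.fx_cache[[name]])) return(.fx_cache[[name]])
  val <- switch(name,
    # 10-tooth arch, known rigid perturbation, no noise
    pair10_clean = generate_arch_pair(
      arch_params(n_teeth = 10, noise_sd = 0, seed = 5)),
    # same arch with 0.01 mm vertex noise
    pair10_noisy = generate_arch_pair(
      arch_params(n_teeth = 10, noise_sd = 0.01, seed = 5)),
    # small arch with impression artifacts present (seed chosen so that the
    # 10% artifact draw hits at least one of the 8 teeth)
    pair8_artifact = generate_arch_pair(
      arch_params(n_teeth = 8, noise_sd = 0, seed = 11)),
    stop("unknown fixture ", name))
  .fx_cache[[name]] <- val
  val
}

# largest per-coordinate discrepancy between two vertex sets (order-free):
# each vertex is matched to its nearest counterpart, both directions
point_set_distance <- function(a, b) {
  ia <- recess3d:::cpp_nearest(a, b)$index
  ib <- recess3d:::cpp_nearest(b, a)$index
  max(abs(a - b[ia, , drop = FALSE]), abs(b - a[ib, , drop = FALSE]))
}

# a single unit right triangle in the xy-plane
triangle_mesh <- function(shift = c(0, 0, 0)) {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)) +
                 rep(shift, each = 3),
               rbind(c(1L, 2L, 3L)))
}

# exact post->pre transform from generator truth
truth_registration <- function(pair) invert_transform(pair$truth$applied_transform)

expect_transform_close <- function(tf, truth, trans_tol, rot_tol_deg) {
  err <- compose_transform(tf, truth)
  expect_lt(sqrt(sum(err$translation^2)), trans_tol)
  expect_lt(rotation_angle_deg(err$rotation), rot_tol_deg)
}
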