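#' Parameters for the synthetic dental-arch generator
#'
#' Defines the study conditions emulated by [generate_arch_pair()]: a segment
#' of a dental arch with `n_teeth` teeth placed along a circular arc, each
#' tooth carrying a buccal gingival recession of known depth, a known partial
#' (or over-) coverage at follow-up, a known buccal thickness gain, plus a
#' rigid misalignment between the two scans, scanner noise, and occasional
#' impression artifacts.
#'
#' Distribution defaults are calibrated to published root-coverage outcomes at
#' six months: recession depth normal(1.34, 0.92) mm truncated to `[0, 5]`,
#' coverage fraction normal(0.65, 0.48) clipped to `[0, 1.2]` (so complete
#' coverage, margin at or beyond the CEJ, occurs stochastically in roughly a
#' quarter of teeth), thickness gain normal(0.33, 0.30) mm, and artifacts on
#' 10\% of teeth.
#'
#' @param n_teeth number of teeth in the arch segment (>= 1).
#' @param jaw `"mandible"` (occlusal = +z) or `"maxilla"` (occlusal = -z).
#' @param arch_radius arch radius in mm.
#' @param tooth_spacing arc length per tooth in mm.
#' @param crown_height clinical crown height in mm.
#' @param recession_depth_distribution `c(mean, sd)` in mm, truncated to `[0, 5]`.
#' @param coverage_fraction_distribution `c(mean, sd)`, clipped to `[0, 1.2]`.
#' @param thickness_gain_distribution `c(mean, sd)` in mm.
#' @param artifact_probability per-tooth probability of an impression artifact.
#' @param mesh_edge_length target mesh edge length in mm.
#' @param max_rotation_deg,max_translation_mm bounds of the random rigid
#'   perturbation applied to the follow-up scan.
#' @param noise_sd Gaussian vertex noise SD in mm applied to the follow-up scan.
#' @param seed integer seed; per-tooth random streams are derived from
#'   `(seed, tooth_id)` by a stable hash so draws do not depend on tooth order.
#' @return An object of class `arch_params`.
#' @export
arch_params <- function(n_teeth = 10L, jaw = c("mandible", "maxilla"),
                        arch_radius = 24, tooth_spacing = 7, crown_height = 8,
                        recession_depth_distribution = c(mean = 1.34, sd = 0.92),
                        coverage_fraction_distribution = c(mean = 0.65, sd = 0.48),
                        thickness_gain_distribution = c(mean = 0.33, sd = 0.30),
                        artifact_probability = 0.1,
                        mesh_edge_length = 0.25,
                        max_rotation_deg = 10, max_translation_mm = 5,
                        noise_sd = 0.01, seed = 1L) {
  jaw <- match.arg(jaw)
  n_teeth <- as.integer(n_teeth)
  if (is.na(n_teeth) || n_teeth < 1L) stop("n_teeth must be >= 1")
  for (v in list(arch_radius, tooth_spacing, crown_height, mesh_edge_length))
    if (!is.finite(v) || v <= 0) stop("scale parameters must be > 0")
  if (artifact_probability < 0 || artifact_probability > 1)
    stop("artifact_probability must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    n_teeth = n_teeth, jaw = jaw, arch_radius = arch_radius,
    tooth_spacing = tooth_spacing, crown_height = crown_height,
    recession_depth_distribution = recession_depth_distribution,
    coverage_fraction_distribution = coverage_fraction_distribution,
    thickness_gain_distribution = thickness_gain_distribution,
    artifact_probability = artifact_probability,
    mesh_edge_length = mesh_edge_length,
    max_rotation_deg = max_rotation_deg,
    max_translation_mm = max_translation_mm,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "arch_params")
}

# template constants (mm), shared by the generator and its tests
.arch_const <- list(
  z_cej = 10,        # CEJ level above the apical mesh border
  collar = 1.2,      # cervical collar: crown bulge starts this far above CEJ
  gum_roll = 1.8,    # attached-gingiva bulge amplitude
  gum_drop = 6,      # bulge begins this far apical of the CEJ
  band_plateau = 3.4,  # thickness-gain band: full displacement within +/- this
  band_end = 5.4,      # ... tapering to zero here (axial, from recession apex)
  margin_sweep = 0.35, # margin/CEJ polylines span +/- this fraction of a tooth
  papilla = 2.5,       # interdental papilla tips sit this far coronal of the CEJ
  n_polyline = 21L,
  artifact_radius = 2.2,    # impression-artifact crater radius
  artifact_dz = 3.0,        # crater centre: this far coronal of the apex
  artifact_lateral = 0.18)  # ... and this fraction of a tooth width sideways

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# stable per-tooth stream seed from (seed, id); independent of tooth order
tooth_seed <- function(seed, id) {
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(as.character(id))) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# plateau/taper window: 1 within |x| <= a, cos^2 taper to 0 at |x| = b
taper_window <- function(x, a, b) {
  ax <- abs(x)
  w <- numeric(length(x))
  w[ax <= a] <- 1
  mid <- ax > a & ax < b
  w[mid] <- cos(pi / 2 * (ax[mid] - a) / (b - a))^2
  dim(w) <- dim(x)
  w
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a paired pre-/post-operative synthetic arch with ground truth
#'
#' Builds two triangle meshes of the buccal aspect of a dental arch segment:
#' a baseline ("pre") scan and a follow-up ("post") scan. Teeth are smooth
#' crown bulges on a gingival base placed along a circular arc. Per tooth, a
#' recession depth, a coverage fraction and a buccal thickness gain are drawn
#' from the configured distributions; the gingival-margin landmark polyline is
#' displaced apically by the drawn depth relative to the marked CEJ curve in
#' the pre scan, and coronally by `coverage x depth` in the post scan. The
#' post surface is additionally inflated outward along the buccal normal by
#' the drawn thickness gain over a smoothly tapered band around the recession
#' apex, deformed by impression artifacts on flagged teeth, perturbed by
#' Gaussian vertex noise, and moved by a random rigid transform.
#'
#' Margin and CEJ polylines are exact landmarks on the cervical reference
#' surface of each tooth (a cylindrical collar band of constant radius), in
#' each mesh's own frame; the gingival margin is a marked curve, not a
#' geometric step (see the methods vignette). In the noise-free,
#' identity-transform limit, measuring these landmarks reproduces the drawn
#' depths and reductions exactly.
#'
#' @param params an [arch_params()] object.
#' @return A list with elements `pre` and `post` (`surface_mesh`),
#'   `annotations` (list of [tooth_annotation()]), and `truth` (class
#'   `synthetic_ground_truth`): per-tooth data frame `teeth` with columns
#'   `tooth_id`, `true_recession_depth_pre`, `true_recession_depth_post`,
#'   `true_reduction`, `true_thickness_gain`, `complete_coverage`,
#'   `artifact`, plus `applied_transform`, `noise_sd`, `seed`,
#'   `n_vertices_pre`, `n_vertices_post`.
#' @export
generate_arch_pair <- function(params) {
  stopifnot(inherits(params, "arch_params"))
  k <- .arch_const
  R <- params$arch_radius
  dth <- params$tooth_spacing / R
  n <- params$n_teeth
  th0 <- pi / 2 - n * dth / 2
  th_centers <- th0 + (seq_len(n) - 0.5) * dth
  ids <- sprintf("tooth_%02d", seq_len(n))

  # ---- per-tooth draws from stable streams ------------------------------
  rd <- params$recession_depth_distribution
  cv <- params$coverage_fraction_distribution
  tg <- params$thickness_gain_distribution
  draw <- lapply(seq_len(n), function(i) {
    with_local_seed(tooth_seed(params$seed, ids[i]), {
      d <- rtrunc_norm(1, rd[["mean"]], rd[["sd"]], 0, 5)
      cov <- if (cv[["sd"]] <= 0) cv[["mean"]] else
        stats::rnorm(1, cv[["mean"]], cv[["sd"]])
      cov <- pmin(1.2, pmax(0, cov))
      tau <- stats::rnorm(1, tg[["mean"]], tg[["sd"]])
      bulge <- 2.5 + 0.25 * i / n + stats::rnorm(1, 0, 0.2)
      ch <- params$crown_height + stats::runif(1, -0.5, 0.5)
      skew <- stats::runif(1, -1, 1)
      art <- stats::runif(1) < params$artifact_probability
      side <- if (stats::runif(1) < 0.5) -1 else 1
      list(d = d, cov = cov, tau = tau, bulge = bulge, ch = ch, skew = skew,
           art = art, side = side)
    })
  })
  d <- vapply(draw, `[[`, 0, "d")
  cov <- vapply(draw, `[[`, 0, "cov")
  tau <- vapply(draw, `[[`, 0, "tau")
  z_apex <- k$z_cej - d

  # ---- surface grids ----------------------------------------------------
  h <- params$mesh_edge_length
  z_max <- k$z_cej + params$crown_height + 0.6
  th_grid <- seq(th0, th0 + n * dth, by = h / R)
  z_grid <- seq(0, z_max, by = h)
  rho_ref <- arch_radius_field(th_grid, z_grid, th_centers, draw, k, params)
  rho_post <- rho_ref
  for (i in seq_len(n)) {  # thickness-gain band (post only)
    wt <- taper_window((th_grid - th_centers[i]) / (dth / 2), 0.55, 0.95)
    wz <- taper_window(z_grid - z_apex[i], k$band_plateau, k$band_end)
    rho_post <- rho_post + tau[i] * outer(wt, wz)
  }
  pre <- grid_to_mesh(th_grid, z_grid, R + rho_ref)
  post_ref <- grid_to_mesh(th_grid, z_grid, R + rho_post)

  # ---- landmark polylines (cervical reference surface, radius R) --------
  tt <- seq(-1, 1, length.out = k$n_polyline)
  bump <- cos(pi * tt / 2)^2   # 1 at the mid-facial zenith, 0 at papilla tips
  annotations <- vector("list", n)
  ax_cor <- c(0, 0, 1)
  margin_curve <- function(i, th, depth) {
    # scalloped margin: papilla tips coronal of the CEJ, zenith at depth below
    z <- (k$z_cej + k$papilla) - (k$papilla + depth) * bump
    r <- R + ref_radius_at(th, z, th_centers, draw, k, params)
    cbind(r * cos(th), r * sin(th), z)
  }
  for (i in seq_len(n)) {
    th <- th_centers[i] + tt * k$margin_sweep * dth
    m_pre <- margin_curve(i, th, d[i])
    m_post <- margin_curve(i, th, d[i] * (1 - cov[i]))
    cej <- cbind(R * cos(th), R * sin(th), k$z_cej)
    annotations[[i]] <- tooth_annotation(
      tooth_id = ids[i], jaw = params$jaw,
      tooth_type = c("incisor", "canine", "premolar", "molar")[(i - 1L) %% 4L + 1L],
      recession_type = if (tooth_seed(params$seed, ids[i]) %% 2L == 0L) "RT1" else "RT2",
      coronal_axis = ax_cor,
      buccal_normal = c(cos(th_centers[i]), sin(th_centers[i]), 0),
      margin_pre = m_pre, margin_post = m_post, cej = cej,
      artifact_flag = draw[[i]]$art)
  }

  # ---- artifacts, noise, rigid perturbation (post) ----------------------
  for (i in seq_len(n)) {
    if (draw[[i]]$art)
      post_ref <- inject_artifact(post_ref, annotations[[i]],
                                  seed = tooth_seed(params$seed + 7L, ids[i]))
  }
  transform <- with_local_seed(params$seed, {
    if (params$noise_sd > 0)
      post_ref$vertices <- post_ref$vertices +
        matrix(stats::rnorm(length(post_ref$vertices), 0, params$noise_sd),
               ncol = 3L)
    random_rigid(params$max_rotation_deg, params$max_translation_mm)
  })
  post_ref$normals <- NULL
  post_ref <- validate_mesh(post_ref)
  post_ref$normals <- vertex_normals(post_ref)
  post <- apply_transform(post_ref, transform)
  for (i in seq_len(n))
    annotations[[i]]$margin_post <-
      apply_transform(annotations[[i]]$margin_post, transform)

  # ---- maxilla: mirror the canonical frame (occlusal -> -z) -------------
  if (params$jaw == "maxilla") {
    flip <- function(m) { m[, 3] <- -m[, 3]; m }
    flip_mesh <- function(mesh) {
      mesh$vertices <- flip(mesh$vertices)
      mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
      mesh$normals <- NULL
      mesh <- validate_mesh(mesh)
      mesh$normals <- vertex_normals(mesh)
      mesh
    }
    pre <- flip_mesh(pre); post <- flip_mesh(post)
    for (i in seq_len(n)) {
      a <- annotations[[i]]
      a$margin_pre <- flip(a$margin_pre); a$margin_post <- flip(a$margin_post)
      a$cej <- flip(a$cej)
      a$coronal_axis <- c(0, 0, -1)
      annotations[[i]] <- a
    }
    Rm <- diag(c(1, 1, -1))  # transform conjugated into the mirrored frame
    transform <- rigid_transform(Rm %*% transform$rotation %*% Rm,
                                 as.numeric(Rm %*% transform$translation))
  }

  truth <- structure(list(
    teeth = data.frame(
      tooth_id = ids,
      true_recession_depth_pre = d,
      true_recession_depth_post = d * (1 - cov),
      true_reduction = d - d * (1 - cov),
      true_thickness_gain = tau,
      complete_coverage = d * (1 - cov) <= 0,
      artifact = vapply(draw, `[[`, FALSE, "art"),
      stringsAsFactors = FALSE),
    applied_transform = transform,
    noise_sd = params$noise_sd, seed = params$seed,
    n_vertices_pre = nrow(pre$vertices),
    n_vertices_post = nrow(post$vertices),
    params = params), class = "synthetic_ground_truth")

  list(pre = pre, post = post, annotations = annotations, truth = truth)
}

# pointwise reference radius offset (same field as arch_radius_field)
ref_radius_at <- function(th, z, th_centers, draw, k, params) {
  dth <- params$tooth_spacing / params$arch_radius
  rho <- k$gum_roll * smoothstep((k$z_cej - k$gum_drop - z) / 2.5)
  for (i in seq_along(th_centers)) {
    tt <- (th - th_centers[i]) / (dth / 2)
    wt <- cos(pi * tt / 2)^2 * (abs(tt) < 1) * (1 + 0.15 * draw[[i]]$skew * tt)
    u <- (z - k$z_cej - k$collar) / (draw[[i]]$ch - k$collar)
    wz <- sin(pi * pmin(1, pmax(0, u))) * (u > 0 & u < 1)
    rho <- rho + draw[[i]]$bulge * wt * wz
  }
  rho
}

# radius offset field rho(theta, z): gingival roll + crown bulges
arch_radius_field <- function(th_grid, z_grid, th_centers, draw, k, params) {
  dth <- params$tooth_spacing / params$arch_radius
  rho <- outer(rep(1, length(th_grid)),
               k$gum_roll * smoothstep((k$z_cej - k$gum_drop - z_grid) / 2.5))
  for (i in seq_along(th_centers)) {
    tt <- (th_grid - th_centers[i]) / (dth / 2)
    wt <- cos(pi * tt / 2)^2 * (abs(tt) < 1) * (1 + 0.15 * draw[[i]]$skew * tt)
    u <- (z_grid - k$z_cej - k$collar) / (draw[[i]]$ch - k$collar)
    wz <- sin(pi * pmin(1, pmax(0, u))) * (u > 0 & u < 1)
    rho <- rho + draw[[i]]$bulge * outer(wt, wz)
  }
  rho
}

# cylindrical height-field grid -> triangle mesh with outward normals
grid_to_mesh <- function(th_grid, z_grid, radius) {
  nt <- length(th_grid); nz <- length(z_grid)
  x <- radius * cos(th_grid)           # radius is nt x nz
  y <- radius * sin(th_grid)
  z <- matrix(z_grid, nt, nz, byrow = TRUE)
  verts <- cbind(as.vector(x), as.vector(y), as.vector(z))
  vid <- function(it, iz) (iz - 1L) * nt + it
  it <- rep(seq_len(nt - 1L), nz - 1L)
  iz <- rep(seq_len(nz - 1L), each = nt - 1L)
  a <- vid(it, iz); b <- vid(it + 1L, iz)
  cc <- vid(it, iz + 1L); dd <- vid(it + 1L, iz + 1L)
  faces <- rbind(cbind(a, b, dd), cbind(a, dd, cc))
  m <- surface_mesh(verts, faces, validate = FALSE)
  # orient faces outward (away from the arch axis)
  fn <- face_normals(m$vertices, m$faces)
  ctr <- (m$vertices[m$faces[, 1], , drop = FALSE] +
          m$vertices[m$faces[, 2], , drop = FALSE] +
          m$vertices[m$faces[, 3], , drop = FALSE]) / 3
  outward <- rowSums(fn[, 1:2, drop = FALSE] * ctr[, 1:2, drop = FALSE])
  if (mean(outward > 0) < 0.5) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m <- validate_mesh(m)
  m$normals <- vertex_normals(m)
  m
}

random_rigid <- function(max_rotation_deg, max_translation_mm) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, max_rotation_deg)
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  tr <- dir * stats::runif(1, 0, max_translation_mm)
  tf <- rotation_about(ax, ang)
  rigid_transform(tf$rotation, tr)
}

#' Inject an impression artifact near a tooth
#'
#' Emulates a localised impression/casting void in the interdental-papilla
#' region adjacent to the tooth: all faces within a crater of ~2 mm radius,
#' centred ~3 mm coronal of the recession apex and offset sideways toward the
#' papilla, are removed. The mid-tooth axial band (the recession apex and the
#' apical profile) is left intact, so the single-point fallback of the
#' thickness measurement remains exercisable while at least one coronal
#' profile sample becomes invalid.
#'
#' @param mesh the follow-up `surface_mesh` (in its own frame).
#' @param annotation the [tooth_annotation()] of the affected tooth (landmarks
#'   in the same frame as `mesh`).
#' @param seed integer seed (chooses the mesial/distal side deterministically).
#' @return The deformed `surface_mesh`.
#' @export
inject_artifact <- function(mesh, annotation, seed = 1L) {
  k <- .arch_const
  side <- with_local_seed(seed, if (stats::runif(1) < 0.5) -1 else 1)
  apex <- deepest_recession_point(annotation$margin_post, annotation$coronal_axis)
  lateral <- pracma_cross(annotation$coronal_axis, annotation$buccal_normal)
  centre <- apex + k$artifact_dz * annotation$coronal_axis +
    side * k$artifact_lateral * 7 * lateral
  d2 <- rowSums((mesh$vertices - rep(centre, each = nrow(mesh$vertices)))^2)
  hit <- which(d2 < k$artifact_radius^2)
  if (length(hit) == 0L) return(mesh)
  drop <- rowSums(matrix(mesh$faces %in% hit, nrow = nrow(mesh$faces))) > 0L
  mesh$faces <- mesh$faces[!drop, , drop = FALSE]
  mesh$normals <- NULL
  mesh <- validate_mesh(mesh)
  mesh$normals <- vertex_normals(mesh)
  mesh
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Write / read synthetic ground truth (YAML)
#' @param truth a `synthetic_ground_truth` object.
#' @param path file path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the truth object.
#' @export
write_truth <- function(truth, path) {
  tf <- truth$applied_transform
  yaml::write_yaml(list(
    teeth = lapply(seq_len(nrow(truth$teeth)), function(i)
      as.list(truth$teeth[i, , drop = FALSE])),
    applied_transform = as.numeric(c(t(tf$rotation), tf$translation)),
    noise_sd = truth$noise_sd, seed = truth$seed,
    n_vertices_pre = truth$n_vertices_pre,
    n_vertices_post = truth$n_vertices_post), path, precision = 17L)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  doc <- yaml::read_yaml(path)
  teeth <- do.call(rbind, lapply(doc$teeth, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  vals <- as.numeric(doc$applied_transform)
  structure(list(
    teeth = teeth,
    applied_transform = rigid_transform(matrix(vals[1:9], 3, 3, byrow = TRUE),
                                        vals[10:12]),
    noise_sd = doc$noise_sd, seed = doc$seed,
    n_vertices_pre = doc$n_vertices_pre,
    n_vertices_post = doc$n_vertices_post), class = "synthetic_ground_truth")
}
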