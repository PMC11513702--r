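#' Most apical point of a gingival-margin polyline
#'
#' Returns the margin point with the minimal coordinate along the coronal
#' axis (the deepest point of recession). Ties break to the lowest point
#' index, so the landmark is deterministic.
#'
#' @param margin `n x 3` polyline matrix.
#' @param coronal_axis unit 3-vector pointing coronally.
#' @return A length-3 point.
#' @export
deepest_recession_point <- function(margin, coronal_axis) {
  margin <- as_polyline(margin, "margin", min_points = 1L)
  ax <- unitize(coronal_axis, "coronal_axis")
  s <- as.vector(margin %*% ax)
  as.numeric(margin[which.min(s), ])
}

#' Recession depth relative to the CEJ
#'
#' The classical CEJ-dependent depth: the distance, along the tooth axis,
#' between the deepest point of recession and the CEJ. The CEJ reference
#' point is the polyline point nearest to the margin point in the plane
#' orthogonal to the axis (avoiding pairing with a distant CEJ arm); both
#' points are then projected onto the axis and the difference
#' `CEJ - margin` returned. Positive when the margin is apical to the CEJ;
#' negative post-operatively when coverage extends beyond the CEJ.
#'
#' @param margin_point deepest recession point (length-3).
#' @param cej CEJ polyline (`n x 3`), or `NULL` if not annotated.
#' @param coronal_axis unit 3-vector pointing coronally.
#' @return Depth in mm, or an error of class `cej_unavailable` when `cej` is
#'   `NULL` (the tooth is then excluded from CEJ-dependent summaries).
#' @export
recession_depth <- function(margin_point, cej, coronal_axis) {
  if (is.null(cej))
    stop(structure(class = c("cej_unavailable", "error", "condition"),
                   list(message = "CEJ-dependent metric unavailable: no CEJ polyline",
                        call = sys.call())))
  cej <- as_polyline(cej, "cej", min_points = 1L)
  ax <- unitize(coronal_axis, "coronal_axis")
  p <- as.numeric(margin_point)
  perp <- function(x) x - outer(as.vector(x %*% ax), ax)
  d2 <- rowSums((perp(cej) - rep(perp(matrix(p, 1)), each = nrow(cej)))^2)
  ref <- as.numeric(cej[which.min(d2), ])
  sum(ref * ax) - sum(p * ax)
}

#' CEJ-independent recession reduction
#'
#' The direct two-point measurement between the deepest points of the pre-
#' and post-operative gingival margins, both expressed in the common
#' (baseline) frame after registration. The CEJ is never consulted. The
#' default mode returns the full 3D Euclidean distance with a sign attached
#' from the displacement component along the coronal axis (positive = margin
#' moved coronally = recession reduced); mode `"axial"` returns the signed
#' axial component itself.
#'
#' @param pre_point,post_point deepest margin points (length-3, common frame).
#' @param coronal_axis unit 3-vector pointing coronally.
#' @param mode `"euclidean"` (default) or `"axial"`.
#' @return Signed reduction in mm.
#' @export
recession_reduction <- function(pre_point, post_point, coronal_axis,
                                mode = c("euclidean", "axial")) {
  mode <- match.arg(mode)
  ax <- unitize(coronal_axis, "coronal_axis")
  d <- as.numeric(post_point) - as.numeric(pre_point)
  axial <- sum(d * ax)
  if (mode == "axial") return(axial)
  len <- sqrt(sum(d^2))
  if (len == 0) 0 else sign(axial) * len
}

#' Mean root coverage over a set of tooth records
#'
#' Per-tooth mRC = 100 x (pre-depth - post-depth) / pre-depth, summarised as
#' arithmetic mean +/- SD over teeth. Values above 100 (margin beyond the
#' CEJ) and below 0 (worsening) are legitimate. Records without CEJ-dependent
#' depths, or with pre-depth = 0 (mRC undefined), are excluded with a warning
#' reporting the count.
#'
#' @param records data frame of tooth measurement records ([assess_case()]).
#' @return A list with `mean`, `sd`, `n`, `n_excluded`, and `per_tooth`
#'   (data frame `tooth_id`, `mrc_percent`).
#' @export
mean_root_coverage <- function(records) {
  ok <- !is.na(records$recession_depth_pre) & !is.na(records$recession_depth_post)
  pos <- ok & records$recession_depth_pre > 0
  n_excluded <- sum(!pos)
  if (n_excluded > 0)
    warning(sprintf("%d record(s) excluded from mRC (missing CEJ or zero pre-operative depth)",
                    n_excluded))
  if (!any(pos)) stop("no records eligible for mean root coverage")
  r <- records[pos, , drop = FALSE]
  mrc <- 100 * (r$recession_depth_pre - r$recession_depth_post) /
    r$recession_depth_pre
  list(mean = mean(mrc), sd = stats::sd(mrc), n = sum(pos),
       n_excluded = n_excluded,
       per_tooth = data.frame(tooth_id = r$tooth_id, mrc_percent = mrc,
                              stringsAsFactors = FALSE))
}

#' Complete root coverage percentage
#'
#' 100 x (number of teeth whose post-operative margin reaches or passes the
#' CEJ, i.e. post-operative depth <= 0) / (number of eligible teeth),
#' reported to two decimals.
#'
#' @param records data frame of tooth measurement records with CEJ-dependent
#'   depths (rows without them are dropped).
#' @return Percentage, rounded to 2 decimals.
#' @export
complete_root_coverage <- function(records) {
  ok <- !is.na(records$recession_depth_post)
  if (!any(ok)) stop("no records with CEJ-dependent depths")
  round(100 * sum(records$recession_depth_post[ok] <= 0) / sum(ok), 2)
}

#' Gingival thickness-change profile on the mid-tooth sagittal plane
#'
#' Reproduces the surface-comparison thickness measurement: on the sagittal
#' plane through the deepest recession point (spanned by the coronal axis and
#' the buccal normal), the baseline surface is sampled at axial offsets of
#' -3 ... +3 mm in 1 mm steps from the apex; at each sample the deviation is
#' the signed distance from the baseline surface to the follow-up surface
#' along the buccal normal (positive = outward gain). Samples whose ray does
#' not meet the follow-up surface within `max_deviation` mm (e.g. impression
#' artifacts) are invalid. When all profile samples are valid the thickness
#' gain is their mean (`full_profile`); otherwise the measurement falls back
#' to the single mid-axis sample at the apex (`apex_only`). An invalid apex
#' sample is a measurement failure for the tooth.
#'
#' @param pre baseline `surface_mesh`.
#' @param post_registered follow-up `surface_mesh`, already in the baseline
#'   frame.
#' @param apex_point deepest pre-operative recession point (baseline frame).
#' @param coronal_axis,buccal_normal unit 3-vectors of the tooth.
#' @param offsets axial sample offsets in mm.
#' @param include_apex include the offset-0 sample in the full-profile mean?
#' @param max_deviation samples beyond this |deviation| (mm) are invalid.
#' @return A list with `samples` (data frame `offset`, `deviation`, `valid`),
#'   `thickness_gain` (mm) and `measurement_mode` (`"full_profile"` or
#'   `"apex_only"`).
#' @export
thickness_profile <- function(pre, post_registered, apex_point, coronal_axis,
                              buccal_normal, offsets = -3:3,
                              include_apex = TRUE, max_deviation = 3) {
  ax <- unitize(coronal_axis, "coronal_axis")
  bn <- unitize(buccal_normal, "buccal_normal")
  apex <- as.numeric(apex_point)
  offs <- sort(unique(c(0, offsets)))
  fpre <- pre$faces - 1L
  fpost <- post_registered$faces - 1L
  res <- lapply(offs, function(k) {
    if (k == 0) {
      p <- apex
    } else {
      origin <- apex + k * ax + 6 * bn
      s <- cpp_ray_mesh(origin, -bn, pre$vertices, fpre, 1e-9, 12, 0L)
      if (is.na(s)) return(c(NA_real_, FALSE))
      p <- origin - s * bn
    }
    t <- cpp_ray_mesh(p, bn, post_registered$vertices, fpost,
                      -max_deviation, max_deviation, 1L)
    if (is.na(t)) c(NA_real_, FALSE) else c(t, TRUE)
  })
  res <- do.call(rbind, res)
  samples <- data.frame(offset = offs, deviation = res[, 1],
                        valid = as.logical(res[, 2]))
  grid <- if (include_apex) samples else samples[samples$offset != 0, , drop = FALSE]
  apex_row <- samples[samples$offset == 0, , drop = FALSE]
  if (all(grid$valid)) {
    list(samples = samples, thickness_gain = mean(grid$deviation),
         measurement_mode = "full_profile")
  } else if (apex_row$valid) {
    list(samples = samples, thickness_gain = apex_row$deviation,
         measurement_mode = "apex_only")
  } else {
    stop(structure(class = c("measurement_failure", "error", "condition"),
                   list(message = "thickness measurement failure: apex ray misses the follow-up surface",
                        call = sys.call())))
  }
}

#' Measure all per-tooth outcomes for a registered case
#'
#' Orchestrates the per-tooth workflow: transforms the post-operative margin
#' landmarks into the baseline frame, locates the deepest recession points,
#' and computes recession depths (when a CEJ is annotated), the
#' CEJ-independent recession reduction, the complete-coverage flag, and the
#' thickness-change profile. Optionally repeats the measurements for several
#' raters and replicates, re-drawing the landmark picks with Gaussian
#' perturbation (`landmark_sd`) each time to emulate manual landmark
#' selection variability; `landmark_sd = 0` reproduces a single deterministic
#' measurement.
#'
#' @param pre baseline `surface_mesh`.
#' @param post follow-up `surface_mesh` (its own frame).
#' @param annotations list of [tooth_annotation()].
#' @param registration `registration_result` from [register_case()], or a
#'   `rigid_transform` mapping post-frame into pre-frame.
#' @param reduction_mode `"euclidean"` or `"axial"` (see
#'   [recession_reduction()]).
#' @param include_apex include the apex sample in full thickness profiles?
#' @param raters,replicates number of raters / replicate measurements.
#' @param landmark_sd SD (mm) of the landmark-pick perturbation.
#' @param seed seed for the landmark perturbation streams.
#' @return A data frame with one row per tooth x rater x replicate: tooth
#'   metadata, `recession_depth_pre`, `recession_depth_post` (NA without
#'   CEJ), `recession_reduction`, `mrc_percent`, `complete_coverage`,
#'   `thickness_gain`, `measurement_mode`, `status`, `rater_id`,
#'   `replicate_index`. Thickness sample tables are attached as attribute
#'   `thickness_samples` (named `tooth_id.rater.replicate`).
#' @export
assess_case <- function(pre, post, annotations, registration,
                        reduction_mode = c("euclidean", "axial"),
                        include_apex = TRUE, raters = 1L, replicates = 1L,
                        landmark_sd = 0, seed = 1L) {
  reduction_mode <- match.arg(reduction_mode)
  tf <- if (inherits(registration, "registration_result"))
    registration$transform else registration
  stopifnot(inherits(tf, "rigid_transform"))
  post_reg <- apply_transform(post, tf)
  rows <- list(); samp <- list()
  for (ann in annotations) {
    margin_post_reg <- apply_transform(ann$margin_post, tf)
    for (r in seq_len(raters)) for (j in seq_len(replicates)) {
      mp <- ann$margin_pre
      mq <- margin_post_reg
      cj <- ann$cej
      if (landmark_sd > 0) {
        pseed <- tooth_seed(seed + 131L * r + j, ann$tooth_id)
        with_local_seed(pseed, {
          jitter <- function(m) m + matrix(stats::rnorm(length(m), 0, landmark_sd),
                                           ncol = 3L)
          mp <- jitter(mp); mq <- jitter(mq)
          if (!is.null(cj)) cj <- jitter(cj)
        })
      }
      apex_pre <- deepest_recession_point(mp, ann$coronal_axis)
      apex_post <- deepest_recession_point(mq, ann$coronal_axis)
      depth_pre <- depth_post <- NA_real_
      if (!is.null(cj)) {
        depth_pre <- recession_depth(apex_pre, cj, ann$coronal_axis)
        depth_post <- recession_depth(apex_post, cj, ann$coronal_axis)
      }
      red <- recession_reduction(apex_pre, apex_post, ann$coronal_axis,
                                 mode = reduction_mode)
      thk <- tryCatch(
        thickness_profile(pre, post_reg, apex_pre, ann$coronal_axis,
                          ann$buccal_normal, include_apex = include_apex),
        measurement_failure = function(e) NULL)
      status <- if (is.null(thk)) "thickness_failure" else "ok"
      key <- sprintf("%s.%d.%d", ann$tooth_id, r, j)
      if (!is.null(thk)) samp[[key]] <- thk$samples
      rows[[key]] <- data.frame(
        tooth_id = ann$tooth_id, jaw = ann$jaw, tooth_type = ann$tooth_type,
        recession_type = ann$recession_type, artifact = ann$artifact_flag,
        cej_available = !is.null(cj),
        recession_depth_pre = depth_pre, recession_depth_post = depth_post,
        recession_reduction = red,
        mrc_percent = if (!is.na(depth_pre) && depth_pre > 0)
          100 * (depth_pre - depth_post) / depth_pre else NA_real_,
        complete_coverage = if (is.na(depth_post)) NA else depth_post <= 0,
        thickness_gain = if (is.null(thk)) NA_real_ else thk$thickness_gain,
        measurement_mode = if (is.null(thk)) NA_character_ else thk$measurement_mode,
        status = status, rater_id = sprintf("rater_%d", r), replicate_index = j,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thickness_samples") <- samp
  out
}

#' Per-vertex surface-deviation heat map
#'
#' Signed distance from each baseline vertex to the registered follow-up
#' surface (nearest-vertex approximation, signed along the baseline vertex
#' normal; positive = tissue gain), the quantity visualised as a
#' surface-comparison heat map.
#'
#' @param pre baseline `surface_mesh`.
#' @param post_registered follow-up `surface_mesh` in the baseline frame.
#' @return Numeric vector of signed deviations (mm), one per `pre` vertex.
#' @export
deviation_heatmap <- function(pre, post_registered) {
  if (is.null(pre$normals)) pre$normals <- vertex_normals(pre)
  nn <- cpp_nearest(pre$vertices, post_registered$vertices)
  q <- post_registered$vertices[nn$index, , drop = FALSE]
  s <- rowSums((q - pre$vertices) * pre$normals)
  sign(s) * nn$distance
}

#' Write a mesh with a per-vertex scalar as ASCII PLY
#'
#' @param mesh a `surface_mesh`.
#' @param scalar numeric vector, one value per vertex (stored as `quality`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, scalar, path) {
  stopifnot(length(scalar) == nrow(mesh$vertices))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               "property float quality",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  v <- cbind(mesh$vertices, scalar)
  writeLines(apply(v, 1, function(r)
    paste(formatC(r, format = "g", digits = 9), collapse = " ")), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}
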