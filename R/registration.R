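#' Coarse alignment by principal axes
#'
#' Initial superimposition of the follow-up scan on the baseline scan:
#' centroids are matched and the principal axes of the two vertex clouds are
#' aligned. The four-fold axis-sign ambiguity (proper rotations only) is
#' resolved by picking the candidate with the smallest symmetric
#' nearest-neighbour RMS distance on a vertex subsample.
#'
#' @param moving,fixed `surface_mesh` objects.
#' @param n_subsample vertices per mesh used to score the four candidates.
#' @return A `rigid_transform` mapping `moving` into the `fixed` frame.
#' @export
coarse_align <- function(moving, fixed, n_subsample = 500L) {
  pm <- principal_frame(moving$vertices)
  pf <- principal_frame(fixed$vertices)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  sub <- function(v) v[unique(round(seq(1, nrow(v), length.out = n_subsample))), ,
                       drop = FALSE]
  mv <- sub(moving$vertices)
  fv <- sub(fixed$vertices)
  best <- NULL; best_score <- Inf
  for (s in signs) {
    Rc <- pf$axes %*% diag(s) %*% t(pm$axes)
    tc <- pf$centre - as.numeric(Rc %*% pm$centre)
    tf <- rigid_transform(Rc, tc)
    fwd <- cpp_nearest(apply_transform(mv, tf), fixed$vertices)$distance
    bwd <- cpp_nearest(apply_transform(fv, invert_transform(tf)),
                       moving$vertices)$distance
    score <- sqrt(mean(c(fwd^2, bwd^2)))
    if (score < best_score) { best_score <- score; best <- tf }
  }
  best
}

principal_frame <- function(v) {
  if (nrow(v) < 3L) stop("degenerate geometry: fewer than 3 vertices")
  ctr <- colMeans(v)
  cv <- stats::cov(v)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[3] <= 1e-12 * max(e$values[1], 1e-300))
    stop("degenerate geometry: vertex covariance has rank < 3")
  ax <- e$vectors
  if (det(ax) < 0) ax[, 3] <- -ax[, 3]
  list(centre = ctr, axes = ax)
}

#' Refine a superimposition by masked point-to-plane ICP
#'
#' Iterative closest point with point-to-plane error and staged
#' correspondence rejection (1.0 mm shrinking by 0.7 per stage to 0.2 mm).
#' The intended use restricts refinement to tooth (crown) surfaces via
#' `mask`, excluding the gingiva that changed between timepoints — the
#' computational equivalent of manually selecting tooth surfaces in
#' inspection software. Nearest-neighbour ties break to the lowest vertex
#' index, and an iteration is only accepted if the correspondence RMS does
#' not increase, so runs are deterministic and the residual trace monotone.
#'
#' @param moving,fixed `surface_mesh` objects; `fixed` must carry per-vertex
#'   normals (recomputed if absent).
#' @param init initial `rigid_transform` (e.g. from [coarse_align()]);
#'   identity if `NULL`.
#' @param mask optional restriction to a subset of moving vertices: a logical
#'   or integer index vector over vertices, or a predicate
#'   `function(points) -> logical` evaluated on the init-transformed moving
#'   vertices (see [crown_mask()]). Must retain at least 3 non-collinear
#'   vertices.
#' @param thresholds correspondence-rejection distances per stage (mm).
#' @param tol relative RMS-change convergence tolerance.
#' @param max_iter maximum total iterations.
#' @return An object of class `registration_result`: `transform` (moving ->
#'   fixed), `rms_residual` (mm, point-to-plane over the final correspondence
#'   set), `n_correspondences`, `converged`, `iterations`; the accepted RMS
#'   trace is attached as attribute `rms_trace`.
#' @export
icp_refine <- function(moving, fixed, init = NULL, mask = NULL,
                       thresholds = c(1, 0.7, 0.49, 0.343, 0.2401, 0.2),
                       tol = 1e-6, max_iter = 200L) {
  if (is.null(init)) init <- rigid_transform()
  stopifnot(inherits(init, "rigid_transform"))
  if (is.null(fixed$normals)) fixed$normals <- vertex_normals(fixed)
  mv <- moving$vertices
  if (!is.null(mask)) {
    keep <- if (is.function(mask)) mask(apply_transform(mv, init)) else mask
    if (is.logical(keep)) keep <- which(keep)
    mv <- mv[keep, , drop = FALSE]
  }
  if (nrow(mv) < 3L) stop("registration failure: mask retains fewer than 3 vertices")
  ev <- eigen(stats::cov(mv), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12 * max(ev[1], 1e-300))
    stop("registration failure: masked vertices are collinear")
  res <- cpp_icp_point_to_plane(mv, fixed$vertices, fixed$normals,
                                init$rotation, init$translation,
                                thresholds, tol, as.integer(max_iter))
  if (isTRUE(res$failed) || res$n_correspondences < 3L)
    stop("registration failure: fewer than 3 surviving correspondences")
  out <- structure(list(
    transform = rigid_transform(matrix(res$rotation, 3, 3),
                                as.numeric(res$translation)),
    rms_residual = res$rms_residual,
    n_correspondences = res$n_correspondences,
    converged = isTRUE(res$converged),
    iterations = res$iterations), class = "registration_result")
  attr(out, "rms_trace") <- res$rms_trace
  out
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("registration_result: rms %.5f mm over %d correspondences",
                     " (%d iterations, %sconverged)\n"),
              x$rms_residual, x$n_correspondences, x$iterations,
              if (x$converged) "" else "not "))
  print(x$transform)
  invisible(x)
}

#' Default crown mask for ICP refinement
#'
#' Builds a predicate selecting vertices on the occlusal band of the crowns:
#' points whose coordinate along the coronal axis is at least `offset` mm
#' coronal of the CEJ level (taken from the annotations' CEJ polylines, or
#' the most coronal gingival-margin points when no CEJ is annotated). This
#' band excludes the gingiva, the recession region and the cervical crown
#' area that soft-tissue change or impression artifacts may touch.
#'
#' @param annotations list of [tooth_annotation()].
#' @param offset mm coronal of the CEJ level at which the band starts.
#' @return `function(points) -> logical` usable as the `mask` argument of
#'   [icp_refine()].
#' @export
crown_mask <- function(annotations, offset = 5.5) {
  ax <- annotations[[1]]$coronal_axis
  lev <- vapply(annotations, function(a) {
    p <- if (!is.null(a$cej)) a$cej else a$margin_pre
    max(p %*% ax)
  }, 0)
  cut <- stats::median(lev) + offset
  function(points) as.vector(points %*% ax) >= cut
}

#' Register a follow-up scan onto a baseline scan
#'
#' Convenience wrapper running [coarse_align()] followed by crown-masked
#' [icp_refine()], the standard superimposition path of the pipeline.
#'
#' @param pre baseline `surface_mesh` (fixed).
#' @param post follow-up `surface_mesh` (moving).
#' @param annotations list of [tooth_annotation()] (for the crown mask).
#' @param use_mask restrict refinement to the crown band? Default `TRUE`.
#' @param ... passed on to [icp_refine()].
#' @return A `registration_result` mapping post-frame into pre-frame.
#' @export
register_case <- function(pre, post, annotations, use_mask = TRUE, ...) {
  init <- coarse_align(post, pre)
  mask <- if (use_mask) crown_mask(annotations) else NULL
  icp_refine(post, pre, init = init, mask = mask, ...)
}
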