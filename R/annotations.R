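#' Per-tooth annotation: landmarks and metadata
#'
#' Houses everything the measurement layer needs to know about one tooth:
#' identity and classification, the tooth's coronal axis (apical is its
#' negation) and outward buccal normal, the gingival-margin polylines at both
#' timepoints (each in its own mesh's frame), and an optional CEJ polyline.
#' When the CEJ polyline is absent, CEJ-dependent metrics (recession depth,
#' mRC, cRC) are flagged unavailable for the tooth, mirroring clinical
#' exclusion of teeth with an indistinct CEJ; the CEJ-independent metrics
#' remain computable.
#'
#' @param tooth_id tooth label (non-empty string).
#' @param jaw `"maxilla"` or `"mandible"`.
#' @param tooth_type `"incisor"`, `"canine"`, `"premolar"` or `"molar"`.
#' @param recession_type `"RT1"` or `"RT2"` (Cairo classification).
#' @param coronal_axis unit 3-vector pointing coronally (re-normalised).
#' @param buccal_normal unit 3-vector pointing out of the buccal surface.
#' @param margin_pre,margin_post gingival-margin polylines (`>= 2` points,
#'   `n x 3` matrices), pre-op in the pre-op frame, post-op in the post-op
#'   frame before registration.
#' @param cej optional CEJ polyline (`n x 3` matrix, pre-op frame).
#' @param artifact_flag impression artifact present near this tooth?
#' @return An object of class `tooth_annotation`.
#' @export
tooth_annotation <- function(tooth_id, jaw, tooth_type, recession_type,
                             coronal_axis, buccal_normal,
                             margin_pre, margin_post, cej = NULL,
                             artifact_flag = FALSE) {
  if (!is.character(tooth_id) || !nzchar(tooth_id))
    stop("tooth_id must be a non-empty string")
  jaw <- match.arg(jaw, c("maxilla", "mandible"))
  tooth_type <- match.arg(tooth_type, c("incisor", "canine", "premolar", "molar"))
  recession_type <- match.arg(recession_type, c("RT1", "RT2"))
  coronal_axis <- unitize(coronal_axis, "coronal_axis")
  buccal_normal <- unitize(buccal_normal, "buccal_normal")
  if (abs(sum(coronal_axis * buccal_normal)) >= 0.9)
    stop("coronal_axis and buccal_normal must be roughly orthogonal (|dot| < 0.9)")
  margin_pre <- as_polyline(margin_pre, "margin_pre", min_points = 2L)
  margin_post <- as_polyline(margin_post, "margin_post", min_points = 2L)
  if (!is.null(cej)) cej <- as_polyline(cej, "cej", min_points = 1L)
  structure(list(tooth_id = tooth_id, jaw = jaw, tooth_type = tooth_type,
                 recession_type = recession_type, coronal_axis = coronal_axis,
                 buccal_normal = buccal_normal, margin_pre = margin_pre,
                 margin_post = margin_post, cej = cej,
                 artifact_flag = isTRUE(artifact_flag)),
            class = "tooth_annotation")
}

unitize <- function(v, what) {
  v <- as.numeric(v)
  if (length(v) != 3L || !all(is.finite(v))) stop(what, " must be a finite 3-vector")
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop(what, " has zero norm")
  v / n
}

as_polyline <- function(p, what, min_points) {
  if (is.list(p)) p <- do.call(rbind, lapply(p, as.numeric))
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  dimnames(p) <- NULL
  if (ncol(p) != 3L) stop(what, " must be an n x 3 polyline")
  if (nrow(p) < min_points) stop(what, " needs at least ", min_points, " point(s)")
  if (!all(is.finite(p))) stop(what, " contains non-finite coordinates")
  p
}

#' @export
print.tooth_annotation <- function(x, ...) {
  cat(sprintf("tooth_annotation %s: %s %s %s%s%s\n", x$tooth_id, x$jaw,
              x$tooth_type, x$recession_type,
              if (is.null(x$cej)) ", no CEJ" else "",
              if (x$artifact_flag) ", artifact" else ""))
  invisible(x)
}

#' Read / write per-tooth annotations (YAML)
#'
#' The annotation file is a YAML document with a top-level `teeth` list; each
#' entry carries the fields of [tooth_annotation()], polylines as lists of
#' `[x, y, z]` points in mm. A missing required field is a schema error naming
#' the field and the offending tooth. Axis vectors are re-normalised on read.
#'
#' @param path annotation file path.
#' @param annotations list of `tooth_annotation` objects.
#' @param meshes optional named list with elements `pre` and `post`
#'   (`surface_mesh`); when given, polyline points are checked to lie within
#'   the corresponding mesh bounding box expanded by 1 mm.
#' @return `read_annotations`: a list of `tooth_annotation`;
#'   `write_annotations`: `path`, invisibly.
#' @export
read_annotations <- function(path, meshes = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$teeth) || length(doc$teeth) == 0L)
    stop("annotation schema error: no 'teeth' entries in ", path)
  out <- lapply(doc$teeth, function(rec) {
    id <- if (is.null(rec$tooth_id)) "<unnamed>" else as.character(rec$tooth_id)
    required <- c("tooth_id", "jaw", "tooth_type", "recession_type",
                  "coronal_axis", "buccal_normal", "margin_pre", "margin_post")
    for (fld in required)
      if (is.null(rec[[fld]]))
        stop(sprintf("annotation schema error: missing field '%s' for tooth %s",
                     fld, id))
    tooth_annotation(
      tooth_id = as.character(rec$tooth_id), jaw = rec$jaw,
      tooth_type = rec$tooth_type, recession_type = rec$recession_type,
      coronal_axis = rec$coronal_axis, buccal_normal = rec$buccal_normal,
      margin_pre = rec$margin_pre, margin_post = rec$margin_post,
      cej = rec$cej, artifact_flag = isTRUE(rec$artifact_flag))
  })
  ids <- vapply(out, `[[`, "", "tooth_id")
  if (anyDuplicated(ids)) stop("annotation schema error: duplicate tooth_id")
  if (!is.null(meshes)) {
    for (ann in out) check_annotation_bounds(ann, meshes$pre, meshes$post)
  }
  out
}

check_annotation_bounds <- function(ann, pre, post, slack = 1) {
  inside <- function(p, mesh) {
    bb <- mesh_bbox(mesh)
    all(p >= rep(bb[1, ] - slack, each = nrow(p)) &
        p <= rep(bb[2, ] + slack, each = nrow(p)))
  }
  if (!is.null(pre)) {
    if (!inside(ann$margin_pre, pre))
      stop("margin_pre outside pre-op mesh bounds for tooth ", ann$tooth_id)
    if (!is.null(ann$cej) && !inside(ann$cej, pre))
      stop("cej outside pre-op mesh bounds for tooth ", ann$tooth_id)
  }
  if (!is.null(post) && !inside(ann$margin_post, post))
    stop("margin_post outside post-op mesh bounds for tooth ", ann$tooth_id)
  invisible(TRUE)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  poly <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  teeth <- lapply(annotations, function(a) {
    rec <- list(tooth_id = a$tooth_id, jaw = a$jaw, tooth_type = a$tooth_type,
                recession_type = a$recession_type,
                coronal_axis = as.numeric(a$coronal_axis),
                buccal_normal = as.numeric(a$buccal_normal),
                margin_pre = poly(a$margin_pre),
                margin_post = poly(a$margin_post),
                artifact_flag = a$artifact_flag)
    if (!is.null(a$cej)) rec$cej <- poly(a$cej)
    rec
  })
  yaml::write_yaml(list(teeth = teeth), path, precision = 17L)
  invisible(path)
}
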