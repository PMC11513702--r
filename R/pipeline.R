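#' Pipeline configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()]: input
#' paths, registration, measurement and statistics settings, and the seed.
#' Any subset of settings may be given; the rest take the documented
#' defaults. A configuration can also be read from a YAML file with the same
#' nesting.
#'
#' @param pre,post,annotations input file paths (STL, STL, YAML).
#' @param out_dir output directory (created if missing).
#' @param patient_id patient label used in the study table.
#' @param registration list: `use_mask` (default TRUE), `mask_offset` (mm,
#'   5.5), `tol` (1e-6), `max_iter` (200).
#' @param measurement list: `reduction` (`"euclidean"`/`"axial"`),
#'   `include_apex` (TRUE), `raters` (1), `replicates` (1), `landmark_sd`
#'   (0 mm).
#' @param stats list: `patient_effect` (`"random"`/`"fixed"`), `icc_form`
#'   (`"ICC2_1"`/`"ICC3_1"`).
#' @param seed integer seed (landmark perturbation streams).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pre, post, annotations, out_dir,
                            patient_id = "case",
                            registration = list(), measurement = list(),
                            stats = list(), seed = 1L) {
  defaults <- list(
    registration = list(use_mask = TRUE, mask_offset = 5.5, tol = 1e-6,
                        max_iter = 200L),
    measurement = list(reduction = "euclidean", include_apex = TRUE,
                       raters = 1L, replicates = 1L, landmark_sd = 0),
    stats = list(patient_effect = "random", icc_form = "ICC2_1"))
  merge <- function(d, u) { d[names(u)] <- u; d }
  cfg <- list(pre = pre, post = post, annotations = annotations,
              out_dir = out_dir, patient_id = patient_id,
              registration = merge(defaults$registration, registration),
              measurement = merge(defaults$measurement, measurement),
              stats = merge(defaults$stats, stats), seed = as.integer(seed))
  stopifnot(cfg$measurement$reduction %in% c("euclidean", "axial"),
            cfg$stats$patient_effect %in% c("random", "fixed"),
            cfg$stats$icc_form %in% c("ICC2_1", "ICC3_1"))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  do.call(pipeline_config, c(doc$paths, doc[setdiff(names(doc), "paths")]))
}

#' Run the full digital recession-assessment workflow
#'
#' Executes the three pipeline stages on one pre/post scan pair:
#' registration (coarse alignment + crown-masked ICP), per-tooth measurement,
#' and the statistical report. Writes, into `out_dir`: `transform.txt` (12
#' numbers, row-major rotation then translation), `records.csv` (one row per
#' tooth x rater x replicate), `heatmap.ply` (baseline mesh with per-vertex
#' signed deviation), `report.json`, and `run.log` (package version, seed and
#' settings — enough to reconstruct every reported number). Runs are
#' deterministic given identical inputs and seed. Input-validation failures
#' abort before any output is written.
#'
#' @param config a [pipeline_config()], or a path to a YAML config file.
#' @return Invisibly, a list with `records`, `registration`, `report`, and
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$pre, config$post, config$annotations))
    if (!file.exists(p)) stop("input not found: ", p)
  pre <- read_stl(config$pre)
  post <- read_stl(config$post)
  anns <- read_annotations(config$annotations,
                           meshes = list(pre = pre, post = post))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  reg <- register_case(pre, post, anns,
                       use_mask = isTRUE(config$registration$use_mask),
                       tol = config$registration$tol,
                       max_iter = config$registration$max_iter)
  records <- assess_case(pre, post, anns, reg,
                         reduction_mode = config$measurement$reduction,
                         include_apex = isTRUE(config$measurement$include_apex),
                         raters = config$measurement$raters,
                         replicates = config$measurement$replicates,
                         landmark_sd = config$measurement$landmark_sd,
                         seed = config$seed)
  table <- build_study_table(stats::setNames(list(records), config$patient_id))
  report <- stats_report(table,
                         patient_effect = config$stats$patient_effect,
                         icc_form = config$stats$icc_form)
  report$registration <- list(
    rms_residual = reg$rms_residual,
    n_correspondences = reg$n_correspondences,
    iterations = reg$iterations, converged = reg$converged)

  paths <- list(transform = file.path(config$out_dir, "transform.txt"),
                records = file.path(config$out_dir, "records.csv"),
                heatmap = file.path(config$out_dir, "heatmap.ply"),
                report = file.path(config$out_dir, "report.json"),
                log = file.path(config$out_dir, "run.log"))
  write_transform(reg$transform, paths$transform)
  utils::write.csv(records, paths$records, row.names = FALSE)
  dev <- deviation_heatmap(pre, apply_transform(post, reg$transform))
  write_ply(pre, dev, paths$heatmap)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  writeLines(c(
    sprintf("recess3d %s", as.character(utils::packageVersion("recess3d"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", config$seed),
    sprintf("inputs: %s | %s | %s", config$pre, config$post, config$annotations),
    "settings:", yaml::as.yaml(config[c("registration", "measurement", "stats")])),
    paths$log)
  invisible(list(records = records, registration = reg, report = report,
                 paths = paths))
}

#' Statistical report for a study table
#'
#' The stats stage of the pipeline: descriptive summary, group comparisons
#' for each factor that is estimable on the table (>= 2 levels and >= 2
#' patients), intra-/inter-rater ICC blocks when replicate measurements are
#' present, and the non-inferiority sample-size block.
#'
#' @param table study table ([build_study_table()]).
#' @param patient_effect,icc_form see [group_compare()] and [icc()].
#' @param outcome outcome used for group comparisons and ICC.
#' @return A nested list (serialisable as JSON).
#' @export
stats_report <- function(table, patient_effect = "random",
                         icc_form = "ICC2_1",
                         outcome = "recession_reduction") {
  summary <- summarize_outcomes(table)
  report <- list(summary = list(counts = summary$counts,
                                outcomes = summary$outcomes,
                                crc_percent = summary$crc_percent))
  report$group_comparisons <- list()
  for (f in c("recession_type", "jaw", "tooth_type")) {
    ok <- length(unique(table[[f]])) >= 2L &&
      length(unique(table$patient_id)) >= 2L
    if (!ok) { report$group_comparisons[[f]] <- "not estimable"; next }
    gc <- tryCatch(group_compare(table, outcome, f,
                                 patient_effect = patient_effect),
                   error = function(e) NULL)
    report$group_comparisons[[f]] <- if (is.null(gc)) "not estimable" else
      list(levels = gc$levels, overall_p = round(gc$overall_p, 3),
           pairwise = transform(gc$pairwise,
                                p_unadjusted = round(p_unadjusted, 3),
                                p_scheffe = round(p_scheffe, 3)))
  }
  if (length(unique(table$replicate_index)) >= 2L) {
    m <- stats::reshape(
      table[c("tooth_id", "rater_id", "replicate_index", outcome)],
      direction = "wide", idvar = c("tooth_id", "rater_id"),
      timevar = "replicate_index")
    intra <- icc(as.matrix(m[, -(1:2), drop = FALSE]), form = icc_form)
    report$icc <- list(intrarater = intra[c("estimate", "lower", "upper")])
    if (length(unique(table$rater_id)) >= 2L) {
      agg <- stats::aggregate(table[[outcome]],
                              by = table[c("tooth_id", "rater_id")], FUN = mean)
      w <- stats::reshape(agg, direction = "wide", idvar = "tooth_id",
                          timevar = "rater_id")
      inter <- icc(as.matrix(w[, -1, drop = FALSE]), form = icc_form)
      report$icc$interrater <- inter[c("estimate", "lower", "upper")]
    }
  }
  report$sample_size <- noninferiority_sample_size()
  report
}
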