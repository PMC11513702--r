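#' Assemble a study table from per-case measurement records
#'
#' Binds the per-tooth records of several cases (patients) into the long
#' study table used by the statistical layer, checking uniqueness of
#' `(tooth_id, rater_id, replicate_index)` within patient.
#'
#' @param cases named list of record data frames from [assess_case()]; names
#'   are patient ids.
#' @return A data frame with a `patient_id` column prepended; tooth ids are
#'   prefixed with the patient id to stay unique across patients.
#' @export
build_study_table <- function(cases) {
  if (is.null(names(cases)) || any(!nzchar(names(cases))))
    stop("cases must be a named list (patient ids)")
  tabs <- lapply(names(cases), function(pid) {
    x <- cases[[pid]]
    x$tooth_id <- paste(pid, x$tooth_id, sep = ":")
    cbind(patient_id = pid, x, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  key <- paste(out$tooth_id, out$rater_id, out$replicate_index)
  if (anyDuplicated(key)) stop("duplicate (tooth_id, rater_id, replicate_index)")
  out
}

# per-tooth means over raters/replicates for modelling (the study analysed
# the mean of the repeated measurements)
collapse_replicates <- function(table, outcome) {
  agg <- stats::aggregate(table[[outcome]],
                          by = table[c("patient_id", "tooth_id", "jaw",
                                       "tooth_type", "recession_type")],
                          FUN = mean)
  names(agg)[ncol(agg)] <- outcome
  agg
}

#' Clustered comparison of an outcome across a factor
#'
#' Fits a linear model for one outcome with a single factor of interest and
#' patient-level clustering of teeth, and reports per-level summaries, an
#' overall factor test, and all pairwise contrasts with Scheffe correction
#' (each contrast compared against `F[k-1, df]` after dividing its F
#' statistic by `k - 1`, so adjusted p-values are never smaller than
#' unadjusted ones). By default the patient enters as a random intercept —
#' the standard treatment for teeth clustered within patients; the literal
#' fixed-effect reading is available via `patient_effect = "fixed"`.
#'
#' @param table study table ([build_study_table()]); replicate rows are
#'   collapsed to per-tooth means first.
#' @param outcome outcome column name (e.g. `"recession_reduction"`).
#' @param factor one of `"recession_type"`, `"jaw"`, `"tooth_type"`.
#' @param patient_effect `"random"` (default) or `"fixed"`.
#' @return A list with `levels` (per-level n, mean, sd), `overall_p`,
#'   `pairwise` (data frame: contrast, estimate, se, df, p_unadjusted,
#'   p_scheffe, lower, upper), `model`.
#' @export
group_compare <- function(table, outcome,
                          factor = c("recession_type", "jaw", "tooth_type"),
                          patient_effect = c("random", "fixed")) {
  factor <- match.arg(factor)
  patient_effect <- match.arg(patient_effect)
  dat <- collapse_replicates(table, outcome)
  dat <- dat[!is.na(dat[[outcome]]), , drop = FALSE]
  dat$.y <- dat[[outcome]]
  dat$.f <- droplevels(as.factor(dat[[factor]]))
  dat$patient_id <- as.factor(dat$patient_id)
  k <- nlevels(dat$.f)
  if (k < 2L) stop("factor '", factor, "' has a single level")
  if (nlevels(dat$patient_id) < 2L) stop("need at least 2 patients")

  if (patient_effect == "random") {
    fit <- nlme::lme(.y ~ .f, random = ~ 1 | patient_id, data = dat,
                     method = "REML")
    an <- stats::anova(fit)
    overall_p <- an[".f", "p-value"]
  } else {
    fit <- stats::lm(.y ~ patient_id + .f, data = dat)
    an <- car::Anova(fit, type = 2)
    overall_p <- an[".f", "Pr(>F)"]
  }
  emm <- emmeans::emmeans(fit, ".f")
  prs_sch <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                                   adjust = "scheffe", infer = c(TRUE, TRUE)))
  prs_raw <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                                   adjust = "none"))
  pairwise <- data.frame(
    contrast = as.character(prs_sch$contrast),
    estimate = prs_sch$estimate, se = prs_sch$SE, df = prs_sch$df,
    p_unadjusted = prs_raw$p.value, p_scheffe = prs_sch$p.value,
    lower = prs_sch$lower.CL, upper = prs_sch$upper.CL,
    stringsAsFactors = FALSE)
  lv <- split(dat$.y, dat$.f)
  levels <- data.frame(level = names(lv),
                       n = vapply(lv, length, 0L),
                       mean = vapply(lv, mean, 0),
                       sd = vapply(lv, stats::sd, 0),
                       stringsAsFactors = FALSE)
  rownames(levels) <- NULL
  list(levels = levels, overall_p = overall_p, pairwise = pairwise,
       factor = factor, outcome = outcome, patient_effect = patient_effect,
       model = fit)
}

#' Intraclass correlation coefficient for repeated measurements
#'
#' Single-measurement ICC from the two-way mean-squares decomposition of a
#' complete teeth x raters (or replicates) matrix. The default form is the
#' two-way random-effects, absolute-agreement ICC(2,1); the consistency form
#' ICC(3,1) is available via `form`. Confidence limits follow the standard
#' F-based construction. Rows with missing cells are dropped (count
#' reported); zero between-tooth variance yields ICC 0 with a warning.
#'
#' @param ratings numeric matrix, teeth in rows, raters/replicates in columns
#'   (>= 5 rows, >= 2 columns).
#' @param form `"ICC2_1"` (absolute agreement, default) or `"ICC3_1"`
#'   (consistency).
#' @param conf_level confidence level for the interval.
#' @return A list with `estimate`, `lower`, `upper`, `form`, `n`, `k`,
#'   `n_dropped`.
#' @export
icc <- function(ratings, form = c("ICC2_1", "ICC3_1"), conf_level = 0.95) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  keep <- stats::complete.cases(ratings)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(n_dropped, " row(s) with missing cells dropped")
    ratings <- ratings[keep, , drop = FALSE]
  }
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2L) stop("need at least 2 raters/replicates (columns)")
  if (n < 5L) stop("need at least 5 teeth (rows)")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  if (stats::var(rowm) < 1e-12 * max(1, grand^2) + 1e-24) {
    warning("zero between-tooth variance: ICC degenerate, returning 0")
    return(list(estimate = 0, lower = NA_real_, upper = NA_real_, form = form,
                n = n, k = k, n_dropped = n_dropped))
  }
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- sum((ratings - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2) / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (form == "ICC3_1") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse <= 0) return(list(estimate = 1, lower = 1, upper = 1, form = form,
                              n = n, k = k, n_dropped = n_dropped))
    f <- msr / mse
    fl <- f / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    if (mse <= 0 && msc <= 0)
      return(list(estimate = 1, lower = 1, upper = 1, form = form,
                  n = n, k = k, n_dropped = n_dropped))
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * est * fj + n * (1 + (k - 1) * est) - k * est)^2
    vd <- (n - 1) * k^2 * est^2 * fj^2 +
      (n * (1 + (k - 1) * est) - k * est)^2
    v <- vn / vd
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  list(estimate = est, lower = lower, upper = upper, form = form,
       n = n, k = k, n_dropped = n_dropped)
}

#' Non-inferiority sample size for mean root coverage
#'
#' Normal-approximation sample size for a single-arm non-inferiority design:
#' `n0 = ceiling(((z[1 - alpha/2] + z[power]) * sd / margin)^2)`, with alpha
#' interpreted as the two-sided 5\% quantile. Because several teeth per
#' patient are clustered, a variance-inflation-factor-adjusted count
#' `ceiling(vif * n0_raw)` is reported alongside; the unadjusted `n_required`
#' is the headline figure (with reference mean 87\%, margin 10, SD 25, power
#' 0.90, alpha 0.05 it equals 66 teeth).
#'
#' @param reference_mean reference mean root coverage (\%), annotation only.
#' @param margin non-inferiority margin (percentage points, > 0).
#' @param sd assumed standard deviation (percentage points).
#' @param power target power (0 < power < 1).
#' @param alpha significance level (two-sided quantile).
#' @param vif variance inflation factor (>= 1) for clustered teeth.
#' @return A list with `n_required` (teeth), `n_raw` (unrounded), and
#'   `n_vif_adjusted`.
#' @export
noninferiority_sample_size <- function(reference_mean = 87, margin = 10,
                                       sd = 25, power = 0.90, alpha = 0.05,
                                       vif = 3) {
  if (margin <= 0) stop("margin must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("power and alpha must be in (0, 1)")
  if (power <= alpha) stop("parameter error: power must exceed alpha")
  if (vif < 1) stop("vif must be >= 1")
  if (sd == 0)  # degenerate no-variance limit: one tooth suffices
    return(list(n_required = 1L, n_raw = 0, n_vif_adjusted = 1L))
  if (margin >= sd * 10) stop("parameter error: margin implausibly large relative to sd")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_raw <- (z * sd / margin)^2
  list(n_required = max(1L, as.integer(ceiling(n_raw))),
       n_raw = n_raw,
       n_vif_adjusted = max(1L, as.integer(ceiling(vif * n_raw))))
}

#' Study-style outcome summary
#'
#' Emits the descriptive layout of a root-coverage results section: counts by
#' jaw, tooth type and recession type, mean +/- SD (to two decimals) for
#' recession depth, mRC, recession reduction and thickness gain, and the
#' complete-root-coverage percentage. Empty strata are omitted with a notice.
#'
#' @param table study table ([build_study_table()]).
#' @return A list with `counts`, `outcomes` (data frame parameter/mean/sd/n)
#'   and `crc_percent`; printable via its own `print` method.
#' @export
summarize_outcomes <- function(table) {
  if (nrow(table) == 0L) stop("empty study table")
  one <- collapse_replicates(table, "recession_reduction")
  cnt <- function(f) {
    t <- table(one[[f]])
    t <- t[t > 0]
    if (length(t) < length(unique(one[[f]])))
      message("empty ", f, " strata omitted")
    as.list(t)
  }
  counts <- list(patients = length(unique(one$patient_id)),
                 teeth = nrow(one), jaw = cnt("jaw"),
                 tooth_type = cnt("tooth_type"),
                 recession_type = cnt("recession_type"))
  per_tooth <- lapply(c("recession_depth_pre", "mrc_percent",
                        "recession_reduction", "thickness_gain"),
                      function(o) {
                        v <- collapse_replicates(table, o)[[o]]
                        v <- v[!is.na(v)]
                        data.frame(parameter = o,
                                   mean = round(mean(v), 2),
                                   sd = round(stats::sd(v), 2),
                                   n = length(v), stringsAsFactors = FALSE)
                      })
  depth_post <- collapse_replicates(table, "recession_depth_post")
  crc <- complete_root_coverage(
    data.frame(recession_depth_post = depth_post$recession_depth_post))
  structure(list(counts = counts, outcomes = do.call(rbind, per_tooth),
                 crc_percent = crc), class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Study summary: %d patients, %d teeth\n",
              x$counts$patients, x$counts$teeth))
  cat("  jaw:", paste(names(x$counts$jaw), unlist(x$counts$jaw),
                      sep = "=", collapse = ", "), "\n")
  cat("  tooth type:", paste(names(x$counts$tooth_type),
                             unlist(x$counts$tooth_type),
                             sep = "=", collapse = ", "), "\n")
  cat("  recession type:", paste(names(x$counts$recession_type),
                                 unlist(x$counts$recession_type),
                                 sep = "=", collapse = ", "), "\n")
  for (i in seq_len(nrow(x$outcomes)))
    cat(sprintf("  %-22s %.2f +/- %.2f (n = %d)\n", x$outcomes$parameter[i],
                x$outcomes$mean[i], x$outcomes$sd[i], x$outcomes$n[i]))
  cat(sprintf("  complete root coverage %.2f%%\n", x$crc_percent))
  invisible(x)
}

#' Simulate a study table directly (no meshes)
#'
#' Draws a clustered per-tooth outcome table for statistical calibration:
#' `outcome = grand_mean + factor effect + patient random intercept + noise`.
#' Used for type-I-error and coverage checks of [group_compare()].
#'
#' @param n_patients number of patients.
#' @param teeth_per_patient teeth per patient (recycled); the default
#'   allocation gives 82 teeth over 19 patients.
#' @param factor factor column to simulate (`"recession_type"` by default);
#'   levels assigned at random per tooth.
#' @param levels factor level labels.
#' @param effects per-level additive effects (0 = null).
#' @param grand_mean outcome grand mean.
#' @param sd_patient SD of the patient random intercept.
#' @param sd_resid residual SD.
#' @param seed integer seed.
#' @return A study table with columns `patient_id`, `tooth_id`, `jaw`,
#'   `tooth_type`, `recession_type`, `recession_reduction`, `rater_id`,
#'   `replicate_index`.
#' @export
simulate_study_table <- function(n_patients = 19,
                                 teeth_per_patient = c(rep(4L, 13), rep(5L, 6)),
                                 factor = "recession_type",
                                 levels = c("RT1", "RT2"),
                                 effects = c(0, 0), grand_mean = 0.87,
                                 sd_patient = 0.3, sd_resid = 0.5, seed = 1L) {
  with_local_seed(seed, {
    counts <- rep_len(teeth_per_patient, n_patients)
    pid <- rep(sprintf("P%02d", seq_len(n_patients)), counts)
    n <- length(pid)
    f <- sample(levels, n, replace = TRUE)
    b <- stats::rnorm(n_patients, 0, sd_patient)[match(pid, unique(pid))]
    y <- grand_mean + effects[match(f, levels)] + b + stats::rnorm(n, 0, sd_resid)
    out <- data.frame(patient_id = pid,
                      tooth_id = sprintf("%s:t%03d", pid, seq_len(n)),
                      jaw = sample(c("maxilla", "mandible"), n, replace = TRUE),
                      tooth_type = sample(c("incisor", "canine", "premolar",
                                            "molar"), n, replace = TRUE),
                      recession_type = sample(c("RT1", "RT2"), n, replace = TRUE),
                      recession_reduction = y,
                      rater_id = "rater_1", replicate_index = 1L,
                      stringsAsFactors = FALSE)
    out[[factor]] <- f
    out
  })
}
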