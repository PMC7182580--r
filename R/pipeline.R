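#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with the study's defaults.
#'
#' @param scale_mm_per_px OCTA pixel size (mm), default 6 mm / 512 px.
#' @param min_length_px Minimum centerline length (px).
#' @param fractal_window LFD moving-window size (odd).
#' @param fdr_low,fdr_high FDR band thresholds.
#' @param quality_min Minimum scan-quality score; scans must score strictly
#'   above it.
#' @param meta Doppler [scan_meta].
#' @param covariates Model adjustment covariates.
#' @param seed Global seed for the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(scale_mm_per_px = 6 / 512, min_length_px = 10L,
                            fractal_window = 3L, fdr_low = 0.3,
                            fdr_high = 0.7, quality_min = 3,
                            meta = scan_meta(),
                            covariates = c("map", "laterality"),
                            seed = 1L) {
  if (!(fdr_low > 0 && fdr_low < fdr_high && fdr_high < 1))
    stop("FDR thresholds must satisfy 0 < low < high < 1")
  if (quality_min < 0) stop("quality_min must be >= 0")
  structure(list(scale_mm_per_px = scale_mm_per_px,
                 min_length_px = as.integer(min_length_px),
                 fractal_window = as.integer(fractal_window),
                 fdr_low = fdr_low, fdr_high = fdr_high,
                 quality_min = quality_min, meta = meta,
                 covariates = covariates, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Filter scans by instrument quality score
#'
#' Retains images whose quality score is strictly greater than `min_score`
#' (one scan per eye passed this gate in the study protocol); exclusions are
#' reported via `message()`.
#'
#' @param images List of [en_face_image] objects with `quality` set.
#' @param min_score Strict lower bound on the quality score.
#' @return The retained sublist.
#' @export
filter_by_quality <- function(images, min_score = 3) {
  if (!length(images)) return(images)
  q <- vapply(images, function(im) {
    if (is.null(im$quality)) NA_real_ else as.numeric(im$quality)
  }, numeric(1))
  keep <- !is.na(q) & q > min_score
  if (any(!keep))
    message(sum(!keep), " image(s) excluded for quality <= ", min_score,
            " (or missing score)")
  images[keep]
}

# morphology metrics of one eye's OCTA image
eye_morphology <- function(image, config) {
  map <- binarize_vessels(image)
  vti <- tryCatch(
    eye_vti_from_mask(map, min_length_px = config$min_length_px)$mean_vti,
    error = function(e) NA_real_)
  lm <- lfd_metrics_from_mask(map, window = config$fractal_window,
                              low = config$fdr_low, high = config$fdr_high)
  list(vti = vti, vd = lm$vd, ssv = lm$ssv, slv = lm$slv,
       vessel_fraction = map$vessel_fraction)
}

#' Run the full analysis pipeline
#'
#' Composes the stages — vessel segmentation and tortuosity, fractal density,
#' Doppler flow, and cohort models — over whatever inputs are supplied:
#'
#' * `inputs$cohort`: output of [make_cohort()] (or a compatible list with
#'   `eyes`); its eye-level metrics feed the statistics layer directly.
#' * `inputs$images`: named list of [en_face_image] per eye, each entry a
#'   list `list(subject_id, laterality, group, image, map?)`; segmented and
#'   measured per eye.
#' * `inputs$flows`: named list per eye:
#'   `list(subject_id, laterality, volumes, veins)`; converted to TRBF.
#'
#' Eyes missing a metric keep their row with `NA` markers and drop out of
#' each model listwise. Association models (one per morphology outcome
#' against TRBF per 100 uL/min) and group models (each outcome vs disease
#' group) are fitted whenever the needed columns are sufficiently complete.
#'
#' @param config A [pipeline_config].
#' @param inputs List as described above.
#' @param out_dir Optional directory; when given, `metrics_table.csv`,
#'   `association_models.csv` and `group_models.csv` are written there.
#' @return List with `metrics` (one row per eye), `associations`,
#'   `group_comparisons` (data frames, possibly empty) and `log`.
#' @export
run_pipeline <- function(config, inputs, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  log <- c(sprintf("octaflow %s", as.character(utils::packageVersion("octaflow"))),
           sprintf("seed %d", config$seed),
           sprintf("config %s", paste(deparse(unclass(config)[
             c("scale_mm_per_px", "min_length_px", "fractal_window",
               "fdr_low", "fdr_high", "quality_min")]), collapse = "")))

  rows <- list()
  if (!is.null(inputs$cohort)) {
    eyes <- as.data.frame(inputs$cohort$eyes)
    for (i in seq_len(nrow(eyes))) rows[[length(rows) + 1L]] <- eyes[i, ]
  }
  if (!is.null(inputs$images)) {
    for (entry in inputs$images) {
      m <- eye_morphology(entry$image, config)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = entry$subject_id,
        group = if (is.null(entry$group)) NA_character_ else entry$group,
        laterality = entry$laterality,
        vti = m$vti, vd = m$vd, ssv = m$ssv, slv = m$slv,
        trbf_ul_min = NA_real_,
        map = if (is.null(entry$map)) NA_real_ else entry$map,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no inputs: supply a cohort and/or images")
  metrics <- do.call(rbind, lapply(rows, function(r) {
    for (col in c("subject_id", "group", "laterality", "vti", "vd", "ssv",
                  "slv", "trbf_ul_min", "map"))
      if (is.null(r[[col]])) r[[col]] <- NA
    r[, c("subject_id", "group", "laterality", "vti", "vd", "ssv", "slv",
          "trbf_ul_min", "map")]
  }))
  rownames(metrics) <- NULL

  if (!is.null(inputs$flows)) {
    for (entry in inputs$flows) {
      ef <- suppressWarnings(
        total_retinal_blood_flow(entry$volumes, entry$veins))
      hit <- metrics$subject_id == entry$subject_id &
        metrics$laterality == entry$laterality
      if (any(hit)) metrics$trbf_ul_min[hit] <- ef$trbf
      else metrics <- rbind(metrics, data.frame(
        subject_id = entry$subject_id, group = NA_character_,
        laterality = entry$laterality, vti = NA_real_, vd = NA_real_,
        ssv = NA_real_, slv = NA_real_, trbf_ul_min = ef$trbf,
        map = NA_real_, stringsAsFactors = FALSE))
    }
  }

  fit_safely <- function(expr) tryCatch(expr, error = function(e) NULL)
  assoc <- list(); grp <- list()
  model_ready <- function(cols) {
    ok <- stats::complete.cases(metrics[, cols, drop = FALSE])
    sum(ok) >= 6L && length(unique(metrics$subject_id[ok])) >= 3L
  }
  for (outcome in c("vti", "vd", "ssv", "slv")) {
    if (model_ready(c(outcome, "trbf_ul_min", config$covariates))) {
      f <- fit_safely(fit_association_model(metrics, outcome,
                                            covariates = config$covariates))
      if (!is.null(f)) assoc[[outcome]] <- data.frame(
        outcome = outcome, beta = f$beta, ci_low = f$ci_low,
        ci_high = f$ci_high, p = f$p_value)
    }
  }
  if (!all(is.na(metrics$group))) {
    for (outcome in c("vti", "vd", "ssv", "slv", "trbf_ul_min")) {
      if (model_ready(c(outcome, "group", config$covariates))) {
        f <- fit_safely(fit_group_model(metrics, outcome,
                                        covariates = config$covariates))
        if (!is.null(f)) grp[[outcome]] <- data.frame(
          outcome = outcome, mean_scr = f$mean_scr, sd_scr = f$sd_scr,
          mean_nc = f$mean_nc, sd_nc = f$sd_nc, beta = f$beta,
          ci_low = f$ci_low, ci_high = f$ci_high, p = f$p_value)
      }
    }
  }
  associations <- if (length(assoc)) do.call(rbind, assoc) else
    data.frame(outcome = character(), beta = numeric(), ci_low = numeric(),
               ci_high = numeric(), p = numeric())
  group_comparisons <- if (length(grp)) do.call(rbind, grp) else
    data.frame(outcome = character(), mean_scr = numeric(),
               sd_scr = numeric(), mean_nc = numeric(), sd_nc = numeric(),
               beta = numeric(), ci_low = numeric(), ci_high = numeric(),
               p = numeric())
  rownames(associations) <- rownames(group_comparisons) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics_table.csv"),
                     row.names = FALSE)
    utils::write.csv(associations,
                     file.path(out_dir, "association_models.csv"),
                     row.names = FALSE)
    utils::write.csv(group_comparisons,
                     file.path(out_dir, "group_models.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(metrics = metrics, associations = associations,
       group_comparisons = group_comparisons, log = log)
}
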