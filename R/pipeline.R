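# End-to-end orchestration: per ant, select the pirouette pair around the
# coil event, extract the longest-stop gaze relative to the real and the
# fictive nest, then assemble the experiment-level circular statistics.

#' Analysis configuration
#'
#' @param criteria a [stop_criteria()].
#' @param min_dist_cm pirouette selection distance threshold, cm (default 5).
#' @param mww_method method for the before-vs-after comparison:
#'   `"auto"`, `"chi2"` or `"permutation"`.
#' @param n_perm permutation count for the Monte-Carlo p-value.
#' @param alpha significance level echoed into reports (default 0.05; no
#'   multiple-testing correction is applied).
#' @param seed integer seed for any randomized p-value, or `NULL`.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(criteria = stop_criteria(), min_dist_cm = 5,
                            mww_method = "auto", n_perm = 1999, alpha = 0.05,
                            seed = NULL) {
  stopifnot(inherits(criteria, "stop_criteria"))
  structure(list(criteria = criteria, min_dist_cm = min_dist_cm,
                 mww_method = mww_method, n_perm = n_perm, alpha = alpha,
                 seed = seed),
            class = "analysis_config")
}

analyze_one_ant <- function(ant, config) {
  track <- ant$track; event <- ant$event
  res <- list(ant_id = track$ant_id,
              before_gaze_nest_deg = NA_real_, before_gaze_fictive_deg = NA_real_,
              after_gaze_nest_deg = NA_real_, after_gaze_fictive_deg = NA_real_,
              fictive_nest = c(NA_real_, NA_real_),
              before_phase = NULL, after_phase = NULL,
              exclusion = NULL)
  sel <- select_pirouettes(track, ant$annotations, event, config$min_dist_cm)
  f <- track$frames
  # fictive nest from the mandible position at the first frame at or after
  # switch-on
  sw <- which(f$t_s >= event$switch_on_t)[1]
  if (!is.na(sw)) {
    mand_sw <- as.numeric(mand_xy(track)[sw, ])
    res$fictive_nest <- tryCatch(fictive_nest(mand_sw, track$nest, event$alteration_deg),
                                 error = function(e) c(NA_real_, NA_real_))
  }
  fail <- function(reason) { res$exclusion <<- reason; res }

  if (is.null(sel$before)) return(fail(paste0("before pirouette: ", sel$before_reason)))
  ph_b <- longest_stopping_phase(detect_stopping_phases(track, sel$before, config$criteria))
  if (is.null(ph_b)) return(fail("no stopping phase in the before pirouette"))
  res$before_phase <- ph_b
  res$before_gaze_nest_deg <- phase_gaze(track, ph_b, track$nest)
  if (!any(is.na(res$fictive_nest)))
    res$before_gaze_fictive_deg <- phase_gaze(track, ph_b, res$fictive_nest)

  if (is.null(sel$after)) return(fail(paste0("after pirouette: ", sel$after_reason)))
  ph_a <- longest_stopping_phase(detect_stopping_phases(track, sel$after, config$criteria))
  if (is.null(ph_a)) return(fail("no stopping phase in the after pirouette"))
  res$after_phase <- ph_a
  res$after_gaze_nest_deg <- phase_gaze(track, ph_a, track$nest)
  if (any(is.na(res$fictive_nest)))
    return(fail("fictive nest undefined (no frame at or after switch-on, or mandible at the nest)"))
  res$after_gaze_fictive_deg <- phase_gaze(track, ph_a, res$fictive_nest)
  res
}

summarize_block <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 2)
    return(list(n = length(angles), angles = angles, summary = NULL,
                histogram = bin_angles(angles)))
  list(n = length(angles), angles = angles, summary = rayleigh_test(angles),
       histogram = bin_angles(angles))
}

#' Analyze a field-alteration experiment
#'
#' For each ant: select the pirouette pair around the coil event, detect
#' stopping phases, take the longest phase per pirouette, and compute its
#' gaze relative to the nest (both pirouettes) and to the fictive nest
#' (constructed at the switch-on frame).  Experiment-level output: circular
#' summaries for before/nest, after/nest, after/fictive and - as a
#' simulator-validation control beyond the usual three rose panels -
#' before/fictive, plus the before-vs-after Mardia-Watson-Wheeler comparison
#' relative to the nest.  Ants failing any stage are excluded with a
#' machine-readable reason, never silently.
#'
#' @param dataset list of per-ant entries `list(track, annotations, event)`,
#'   e.g. from [simulate_experiment()] or [read_dataset()]; all events must
#'   share one alteration angle.
#' @param config an [analysis_config()].
#' @return an object of class `lw_report`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_ants = 4, seed = 7))
#' rep <- analyze_experiment(sim$dataset)
#' rep$summaries$after_fictive$summary
#' @export
analyze_experiment <- function(dataset, config = analysis_config()) {
  if (!length(dataset)) stop("empty dataset", call. = FALSE)
  thetas <- vapply(dataset, function(a) a$event$alteration_deg, numeric(1))
  if (length(unique(thetas)) != 1L)
    stop("mixed alteration angles across ants: ", paste(unique(thetas), collapse = ", "),
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  ants <- lapply(dataset, analyze_one_ant, config = config)

  ants_df <- do.call(rbind, lapply(ants, function(a) data.frame(
    ant_id = a$ant_id,
    before_gaze_nest_deg = a$before_gaze_nest_deg,
    before_gaze_fictive_deg = a$before_gaze_fictive_deg,
    after_gaze_nest_deg = a$after_gaze_nest_deg,
    after_gaze_fictive_deg = a$after_gaze_fictive_deg,
    fictive_x_cm = a$fictive_nest[1], fictive_y_cm = a$fictive_nest[2],
    excluded = !is.null(a$exclusion),
    exclusion = if (is.null(a$exclusion)) NA_character_ else a$exclusion,
    stringsAsFactors = FALSE)))

  summaries <- list(
    before_nest    = summarize_block(ants_df$before_gaze_nest_deg),
    after_nest     = summarize_block(ants_df$after_gaze_nest_deg),
    after_fictive  = summarize_block(ants_df$after_gaze_fictive_deg),
    before_fictive = summarize_block(ants_df$before_gaze_fictive_deg))

  a1 <- ants_df$before_gaze_nest_deg[!is.na(ants_df$before_gaze_nest_deg)]
  a2 <- ants_df$after_gaze_nest_deg[!is.na(ants_df$after_gaze_nest_deg)]
  mww <- if (length(a1) >= 2 && length(a2) >= 2)
    mww_test(a1, a2, method = config$mww_method, n_perm = config$n_perm) else NULL

  structure(list(alteration_deg = thetas[1], n_ants = length(dataset),
                 ants = ants_df, summaries = summaries, mww = mww,
                 config = config,
                 version = as.character(utils::packageVersion("antgaze")),
                 seed = config$seed),
            class = "lw_report")
}

#' @export
print.lw_report <- function(x, ...) {
  cat(sprintf("learning-walk experiment report: theta = %g deg, %d ants (%d excluded)\n",
              x$alteration_deg, x$n_ants, sum(x$ants$excluded)))
  for (nm in names(x$summaries)) {
    b <- x$summaries[[nm]]
    cat(sprintf("-- %s (n = %d)\n", nm, b$n))
    if (!is.null(b$summary)) print(b$summary)
  }
  if (!is.null(x$mww)) print(x$mww)
  invisible(x)
}

summary_to_list <- function(block) {
  out <- list(n = block$n, angles_deg = block$angles,
              histogram_10deg = as.list(block$histogram))
  if (!is.null(block$summary)) out <- c(out, unclass(block$summary)[
    c("R", "r", "Z", "p", "mu_deg", "ci_lo_deg", "ci_hi_deg",
      "ci_half_width_deg", "ci_reliable")])
  out
}

#' Write a report to JSON and TSV
#'
#' Writes `<prefix>.json` (full report, including the per-block 10°
#' histograms), `<prefix>_ants.tsv` (one row per ant) and
#' `<prefix>_summaries.tsv` (one row per summary block).  Output is
#' deterministic: identical reports serialize byte-identically.
#'
#' @param report an `lw_report` from [analyze_experiment()].
#' @param prefix output path prefix (directories are created as needed).
#' @return invisibly, the vector of file paths written.
#' @export
render_report <- function(report, prefix) {
  stopifnot(inherits(report, "lw_report"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  j <- list(version = report$version,
            seed = report$seed,
            alpha = cfg$alpha,
            alteration_deg = report$alteration_deg,
            n_ants = report$n_ants,
            config = list(gaze_tol_deg = cfg$criteria$gaze_tol_deg,
                          min_duration_ms = cfg$criteria$min_duration_ms,
                          max_forward_speed = cfg$criteria$max_forward_speed,
                          max_angular_speed = cfg$criteria$max_angular_speed,
                          min_dist_cm = cfg$min_dist_cm,
                          mww_method = cfg$mww_method, n_perm = cfg$n_perm),
            ants = report$ants,
            summaries = lapply(report$summaries, summary_to_list),
            mww = if (is.null(report$mww)) NULL else unclass(report$mww))
  paths <- c(json = paste0(prefix, ".json"),
             ants = paste0(prefix, "_ants.tsv"),
             summaries = paste0(prefix, "_summaries.tsv"))
  jsonlite::write_json(j, paths["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  utils::write.table(report$ants, paths["ants"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  sm <- do.call(rbind, lapply(names(report$summaries), function(nm) {
    b <- report$summaries[[nm]]
    s <- b$summary
    data.frame(block = nm, n = b$n,
               r = if (is.null(s)) NA else s$r, Z = if (is.null(s)) NA else s$Z,
               p = if (is.null(s)) NA else s$p,
               mu_deg = if (is.null(s)) NA else s$mu_deg,
               ci_lo_deg = if (is.null(s)) NA else s$ci_lo_deg,
               ci_hi_deg = if (is.null(s)) NA else s$ci_hi_deg,
               ci_reliable = if (is.null(s)) NA else s$ci_reliable)
  }))
  utils::write.table(sm, paths["summaries"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Read back a JSON report
#'
#' @param path a `<prefix>.json` file written by [render_report()].
#' @return the parsed report as a list.
#' @export
read_report_json <- function(path) jsonlite::fromJSON(path, simplifyVector = TRUE)
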