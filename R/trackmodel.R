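# Data model and I/O for tracked learning walks.
#
# A track stores per-frame mandible and thorax positions (cm, arena frame:
# x east, y north, origin at the platform center / nest tube exit) at a known
# frame rate, together with the nest position and the platform bounds.
# Events (coil switch-on) and pirouette annotations live in a JSON sidecar.

#' Construct a learning-walk track
#'
#' @param frames data frame with columns `frame` (0-based integer), `t_s`
#'   (seconds, strictly increasing), `mand_x_cm`, `mand_y_cm`, `thor_x_cm`,
#'   `thor_y_cm` (cm).
#' @param fps frame rate, frames per second (default 50).
#' @param ant_id label for the individual.
#' @param nest nest entrance position `c(x, y)` in cm (default the origin).
#' @param platform bounding box `c(xmin, xmax, ymin, ymax)` in cm; default a
#'   60 cm × 60 cm platform centered on the nest.
#' @return an object of class `lw_track`.
#' @export
lw_track <- function(frames, fps = 50, ant_id = "ant",
                     nest = c(0, 0), platform = c(-30, 30, -30, 30)) {
  req <- c("frame", "t_s", "mand_x_cm", "mand_y_cm", "thor_x_cm", "thor_y_cm")
  miss <- setdiff(req, names(frames))
  if (length(miss)) stop("frames is missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  frames <- as.data.frame(frames)[, req]
  if (nrow(frames) > 0) {
    num <- as.matrix(frames[, -1])
    if (any(!is.finite(num)))
      stop("non-finite value at row ", which(rowSums(!is.finite(num)) > 0)[1], call. = FALSE)
    if (nrow(frames) > 1 && any(diff(frames$t_s) <= 0))
      stop("time not strictly increasing at row ", which(diff(frames$t_s) <= 0)[1] + 1,
           call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1 || fps <= 0) stop("`fps` must be > 0", call. = FALSE)
  stopifnot(length(nest) == 2, is.finite(nest), length(platform) == 4)
  structure(list(frames = frames, fps = fps, ant_id = as.character(ant_id),
                 nest = as.numeric(nest), platform = as.numeric(platform)),
            class = "lw_track")
}

#' @export
print.lw_track <- function(x, ...) {
  cat(sprintf("lw_track '%s': %d frames @ %g fps (%.2f s), nest at (%.2f, %.2f) cm\n",
              x$ant_id, nrow(x$frames), x$fps,
              if (nrow(x$frames)) diff(range(x$frames$t_s)) else 0,
              x$nest[1], x$nest[2]))
  invisible(x)
}

# n x 2 coordinate matrices
mand_xy <- function(track) as.matrix(track$frames[, c("mand_x_cm", "mand_y_cm")])
thor_xy <- function(track) as.matrix(track$frames[, c("thor_x_cm", "thor_y_cm")])

#' Indices of degenerate frames
#'
#' A frame is degenerate when mandible and thorax coincide (within `tol` cm):
#' the body axis, and hence the gaze direction, is undefined there.  Such
#' frames are retained in the track but excluded from heading-based
#' computations.
#'
#' @param track an [lw_track()].
#' @param tol coincidence tolerance in cm.
#' @return integer vector of row indices.
#' @export
degenerate_frames <- function(track, tol = 1e-6) {
  d <- sqrt(rowSums((mand_xy(track) - thor_xy(track))^2))
  which(d < tol)
}

#' Coil switch-on event
#'
#' @param switch_on_t time the Helmholtz coil was switched on, seconds.
#' @param alteration_deg the horizontal-component alteration angle theta,
#'   degrees (positive clockwise/eastward).
#' @return an object of class `coil_event`.
#' @export
coil_event <- function(switch_on_t, alteration_deg) {
  stopifnot_scalar(switch_on_t, "switch_on_t")
  stopifnot_scalar(alteration_deg, "alteration_deg")
  structure(list(switch_on_t = switch_on_t, alteration_deg = alteration_deg),
            class = "coil_event")
}

#' Pirouette annotations table
#'
#' @param start,end 0-based frame numbers (start < end), vectors.
#' @param label `"before"`, `"after"` or `"unlabeled"`.
#' @return a data frame with columns `start`, `end`, `label`.
#' @export
pirouette_annotations <- function(start, end, label = "unlabeled") {
  stopifnot(length(start) == length(end), all(start < end))
  label <- rep_len(as.character(label), length(start))
  stopifnot(all(label %in% c("before", "after", "unlabeled")))
  data.frame(start = as.integer(start), end = as.integer(end), label = label,
             stringsAsFactors = FALSE)
}

#' Read a track from CSV
#'
#' The CSV must have header columns `frame`, `t_s`, `mand_x_cm`, `mand_y_cm`,
#' `thor_x_cm`, `thor_y_cm`.  Degenerate frames (mandible = thorax within
#' 1e-6 cm) are flagged with a warning, not dropped.
#'
#' @param path CSV file path.
#' @param meta optional list with `fps`, `ant_id`, `nest`, `platform`
#'   (e.g. from [read_track_meta()]).
#' @return an [lw_track()].
#' @export
read_track_csv <- function(path, meta = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "t_s", "mand_x_cm", "mand_y_cm", "thor_x_cm", "thor_y_cm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")),
                         call. = FALSE)
  tr <- lw_track(df,
                 fps = meta$fps %||% 50,
                 ant_id = meta$ant_id %||% sub("\\.csv$", "", basename(path)),
                 nest = meta$nest %||% c(0, 0),
                 platform = meta$platform %||% c(-30, 30, -30, 30))
  dg <- degenerate_frames(tr)
  if (length(dg))
    warning(sprintf("%s: %d degenerate frame(s) (mandible = thorax) at row(s) %s",
                    path, length(dg), paste(utils::head(dg, 10), collapse = ", ")),
            call. = FALSE)
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a track to CSV
#'
#' Numbers are written with 6 decimals; [read_track_csv()] on the output
#' reproduces the track exactly at that precision.
#'
#' @param track an [lw_track()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_track_csv <- function(track, path) {
  stopifnot(inherits(track, "lw_track"))
  f <- track$frames
  out <- data.frame(frame = f$frame,
                    t_s = sprintf("%.6f", f$t_s),
                    mand_x_cm = sprintf("%.6f", f$mand_x_cm),
                    mand_y_cm = sprintf("%.6f", f$mand_y_cm),
                    thor_x_cm = sprintf("%.6f", f$thor_x_cm),
                    thor_y_cm = sprintf("%.6f", f$thor_y_cm))
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the per-ant JSON sidecar (events and annotations)
#'
#' Expected layout:
#' `{ant_id, nest: [x, y], fps, coil: {switch_on_t, alteration_deg},
#'   pirouettes: [{start, end, label}]}`.
#'
#' @param path JSON file path.
#' @return a list with `ant_id`, `nest`, `fps`, `coil` (a [coil_event()] or
#'   `NULL`) and `pirouettes` (annotation data frame or `NULL`).
#' @export
read_track_meta <- function(path) {
  j <- jsonlite::fromJSON(path)
  out <- list(ant_id = j$ant_id %||% NULL,
              nest = if (!is.null(j$nest)) as.numeric(j$nest) else NULL,
              fps = j$fps %||% NULL,
              platform = if (!is.null(j$platform)) as.numeric(j$platform) else NULL,
              coil = NULL, pirouettes = NULL)
  if (!is.null(j$coil))
    out$coil <- coil_event(j$coil$switch_on_t, j$coil$alteration_deg)
  if (!is.null(j$pirouettes) && NROW(j$pirouettes) > 0) {
    p <- as.data.frame(j$pirouettes)
    out$pirouettes <- pirouette_annotations(p$start, p$end,
                                            p$label %||% "unlabeled")
  }
  out
}

#' Write the per-ant JSON sidecar
#'
#' @param track an [lw_track()].
#' @param event a [coil_event()] or `NULL`.
#' @param annotations a [pirouette_annotations()] data frame or `NULL`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_track_meta <- function(track, event, annotations, path) {
  j <- list(ant_id = track$ant_id, nest = track$nest, fps = track$fps,
            platform = track$platform)
  if (!is.null(event)) j$coil <- list(switch_on_t = event$switch_on_t,
                                      alteration_deg = event$alteration_deg)
  if (!is.null(annotations)) j$pirouettes <- annotations
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Validate a track and report findings
#'
#' Checks for irregular frame spacing (> 10% deviation from `1/fps`),
#' out-of-platform points, degenerate frames, and body-length outliers
#' (mandible-thorax distance > 3x the median).
#'
#' @param track an [lw_track()].
#' @return a data frame with columns `type`, `frame` (0-based frame number),
#'   `message`; zero rows for a clean track.
#' @export
validate_track <- function(track) {
  stopifnot(inherits(track, "lw_track"))
  f <- track$frames
  findings <- list()
  add <- function(type, frame, message)
    findings[[length(findings) + 1L]] <<- data.frame(type = type, frame = frame,
                                                     message = message,
                                                     stringsAsFactors = FALSE)
  if (nrow(f) > 1) {
    dt <- diff(f$t_s)
    bad <- which(abs(dt - 1 / track$fps) > 0.1 / track$fps)
    for (i in bad) add("irregular_spacing", f$frame[i + 1],
                       sprintf("frame interval %.4f s vs expected %.4f s", dt[i], 1 / track$fps))
  }
  if (nrow(f) > 0) {
    pb <- track$platform
    m <- mand_xy(track); th <- thor_xy(track)
    outside <- which(m[, 1] < pb[1] | m[, 1] > pb[2] | m[, 2] < pb[3] | m[, 2] > pb[4] |
                     th[, 1] < pb[1] | th[, 1] > pb[2] | th[, 2] < pb[3] | th[, 2] > pb[4])
    for (i in outside) add("out_of_platform", f$frame[i], "point outside the platform bounds")
    dg <- degenerate_frames(track)
    for (i in dg) add("degenerate", f$frame[i], "mandible coincides with thorax")
    bl <- sqrt(rowSums((m - th)^2))
    med <- stats::median(bl)
    if (med > 0) {
      for (i in which(bl > 3 * med))
        add("body_length_outlier", f$frame[i],
            sprintf("mandible-thorax distance %.3f cm > 3x median (%.3f cm)", bl[i], med))
    }
  }
  if (!length(findings))
    return(data.frame(type = character(), frame = integer(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

#' Read a dataset directory
#'
#' Pairs each `<id>.json` sidecar with its `<id>.csv` track and assembles the
#' list-of-ants structure consumed by [analyze_experiment()].
#'
#' @param dir directory containing `<id>.csv` + `<id>.json` pairs.
#' @return a list with one element per ant: `list(track, annotations, event)`.
#' @export
read_dataset <- function(dir) {
  metas <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(metas)) stop("no .json sidecars found in ", dir, call. = FALSE)
  lapply(metas, function(mp) {
    meta <- read_track_meta(mp)
    csv <- sub("\\.json$", ".csv", mp)
    if (!file.exists(csv)) stop("no track CSV for sidecar ", mp, call. = FALSE)
    track <- read_track_csv(csv, meta)
    list(track = track, annotations = meta$pirouettes, event = meta$coil)
  })
}

#' Write a dataset directory
#'
#' Inverse of [read_dataset()]; writes one CSV + JSON pair per ant.
#'
#' @param dataset list of `list(track, annotations, event)` entries.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ant in dataset) {
    base <- file.path(dir, ant$track$ant_id)
    write_track_csv(ant$track, paste0(base, ".csv"))
    write_track_meta(ant$track, ant$event, ant$annotations, paste0(base, ".json"))
  }
  invisible(dir)
}
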