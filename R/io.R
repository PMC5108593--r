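#' Run configuration
#'
#' Bundles every threshold and filter width with I/O settings. Defaults
#' equal the printed constants of the assay: 0.2 / 2 / 4 mm/s speed
#' thresholds, 125 deg/s sharp-turn threshold, 0.32 / 1.2 / 2.4 s filter
#' widths, 3 / 2.5 / 5 / 16 mm distance rules, 0.31 mm displacement
#' merge, 30 s long-visit minimum, 60 s non-eater cutoff, 300 / 240 s
#' rolling window, 10% lost-frame cap, 0.155 mm/px, 50 fps.
#'
#' @param activity activity thresholds ([activity_thresholds()]).
#' @param events event thresholds ([event_thresholds()]).
#' @param mm_per_px,fps calibration.
#' @param qc_max_lost lost-frame cap (fraction).
#' @param pos_width_s,walk_width_s,rest_width_s filter supports, s.
#' @param window_s,step_s rolling-window parameters, s.
#' @param non_eater_min non-eater cutoff, minutes.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `forage_config`.
#' @export
forage_config <- function(activity = activity_thresholds(),
                          events = event_thresholds(),
                          mm_per_px = 0.155, fps = 50,
                          qc_max_lost = 0.10,
                          pos_width_s = 0.32, walk_width_s = 1.2,
                          rest_width_s = 2.4,
                          window_s = 300, step_s = 240,
                          non_eater_min = 1, seed = 1L) {
  structure(list(activity = activity, events = events,
                 mm_per_px = mm_per_px, fps = fps,
                 qc_max_lost = qc_max_lost,
                 pos_width_s = pos_width_s, walk_width_s = walk_width_s,
                 rest_width_s = rest_width_s,
                 window_s = window_s, step_s = step_s,
                 non_eater_min = non_eater_min, seed = seed),
            class = "forage_config")
}

# small deterministic content hash (31-polynomial over the serialized
# config, mod a Mersenne prime so arithmetic stays exact in doubles)
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a trajectory CSV
#'
#' Expected columns: `frame`, optional `time_s`, and `body_x`, `body_y`,
#' `head_x`, `head_y` (optionally `tail_x`, `tail_y`), either bare (with
#' `units` supplied) or suffixed `_px` / `_mm`. Pixel input is converted
#' to mm at load using `mm_per_px`.
#'
#' @param path CSV file path.
#' @param units `"mm"`, `"px"`, or `NULL` to infer from column suffixes.
#' @param mm_per_px calibration. @param fps frames per second.
#' @return a `forage_track` in mm.
#' @export
read_trajectory <- function(path, units = NULL, mm_per_px = 0.155, fps = 50) {
  df <- data.table::fread(path, data.table = FALSE)
  nm <- names(df)
  pick <- function(base) {
    for (suf in c("", "_mm", "_px")) if (paste0(base, suf) %in% nm)
      return(paste0(base, suf))
    NA_character_
  }
  cols <- vapply(c("body_x", "body_y", "head_x", "head_y"), pick, "")
  if (any(is.na(cols)))
    stop("missing mandatory columns: ",
         paste(names(cols)[is.na(cols)], collapse = ", "))
  if (is.null(units)) {
    units <- if (any(grepl("_px$", cols))) "px"
             else if (any(grepl("_mm$", cols))) "mm"
             else stop("units not declared: pass `units` or suffix columns _px/_mm")
  }
  if (!"frame" %in% nm) stop("missing mandatory column: frame")
  if (any(diff(df$frame) <= 0))
    stop("frames out of order at row(s): ",
         paste(utils::head(which(diff(df$frame) <= 0) + 1L, 5), collapse = ", "))
  tcols <- vapply(c("tail_x", "tail_y"), pick, "")
  tail <- if (!any(is.na(tcols))) as.matrix(df[, tcols]) else NULL
  tr <- raw_track(df$frame,
                  head = as.matrix(df[, cols[3:4]]),
                  body = as.matrix(df[, cols[1:2]]),
                  tail = tail, units = units, fps = fps,
                  time = if ("time_s" %in% nm) df$time_s else NULL)
  if (units == "px") {
    tr$head <- tr$head * mm_per_px
    tr$body <- tr$body * mm_per_px
    tr$tail <- tr$tail * mm_per_px
    tr$units <- "mm"
  }
  tr
}

#' Write a trajectory CSV (mm)
#'
#' @param track a `forage_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(track, path) {
  stopifnot(track$units == "mm")
  df <- data.frame(frame = track$frame, time_s = track$time,
                   body_x_mm = track$body[, 1], body_y_mm = track$body[, 2],
                   head_x_mm = track$head[, 1], head_y_mm = track$head[, 2],
                   tail_x_mm = track$tail[, 1], tail_y_mm = track$tail[, 2])
  data.table::fwrite(df, path)
  invisible(path)
}

events_table <- function(seg, fps) {
  tag <- function(ev, kind) {
    if (!nrow(ev)) return(NULL)
    data.frame(kind = kind, patch_id = ev$patch_id,
               substrate = ev$substrate,
               start_frame = ev$start - 1L, end_frame = ev$end - 1L,
               duration_s = ev$duration_s,
               min_dist_mm = if ("min_dist_mm" %in% names(ev))
                 ev$min_dist_mm else NA_real_)
  }
  out <- rbind(tag(seg$encounters, "encounter"),
               tag(seg$micromovements, "micromovement"),
               tag(seg$visits, "visit"))
  if (is.null(out))
    out <- data.frame(kind = character(0), patch_id = integer(0),
                      substrate = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration_s = numeric(0),
                      min_dist_mm = numeric(0))
  out
}

#' Run the full analysis pipeline over a set of trajectory files
#'
#' For every trajectory: QC (lost-frame rule), smoothing, ethogram,
#' event segmentation and the per-fly metric set; writes per-fly
#' ethogram/bout/event CSVs, a combined metrics CSV and a JSON manifest
#' (config hash, seed, QC exclusions) into `out_dir`. Re-running with
#' the same inputs and config is idempotent.
#'
#' @param paths character vector of trajectory CSV paths.
#' @param a a `forage_arena`.
#' @param out_dir output directory (created if needed).
#' @param config a [forage_config()].
#' @param units passed to [read_trajectory()].
#' @return invisibly, a list with `metrics` (data.frame, one row per
#'   passing fly) and `manifest`.
#' @export
run_pipeline <- function(paths, a, out_dir, config = forage_config(),
                         units = NULL) {
  if (length(paths) == 0) stop("no input trajectories given")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("input files not found: ",
                            paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  excluded <- character(0)
  rows <- list()
  for (p in paths) {
    id <- tools::file_path_sans_ext(basename(p))
    raw <- read_trajectory(p, units = units,
                           mm_per_px = config$mm_per_px, fps = config$fps)
    qc <- qc_track(raw)
    if (qc$lost_fraction > config$qc_max_lost) {
      excluded <- c(excluded, id)
      next
    }
    tr <- smooth_track(raw, mm_per_px = config$mm_per_px,
                       pos_width_s = config$pos_width_s,
                       walk_width_s = config$walk_width_s,
                       rest_width_s = config$rest_width_s)
    labels <- ethogram(tr, config$activity)
    seg <- segment_events(tr, a, labels = labels, th = config$events)
    met <- fly_metrics(tr, a, seg = seg, th = config$events)
    met <- cbind(fly = id, lost_fraction = qc$lost_fraction, met,
                 config_hash = hash)
    rows[[id]] <- met
    et <- ethogram_tables(labels)
    data.table::fwrite(et$frames, file.path(out_dir, paste0(id, "_ethogram.csv")))
    data.table::fwrite(et$bouts, file.path(out_dir, paste0(id, "_bouts.csv")))
    data.table::fwrite(events_table(seg, config$fps),
                       file.path(out_dir, paste0(id, "_events.csv")))
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(metrics))
    data.table::fwrite(metrics, file.path(out_dir, "metrics.csv"))
  manifest <- list(config_hash = hash, seed = config$seed,
                   n_input = length(paths),
                   n_analyzed = length(rows), excluded = excluded,
                   package_version = as.character(utils::packageVersion("flyforage")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metrics = metrics, manifest = manifest))
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper pairing [simulate_fly()] with the CSV/JSON
#' writers: emits one trajectory CSV and one ground-truth visits CSV per
#' fly plus the arena JSON.
#'
#' @param params a [forager_params()] (or preset name from
#'   [make_presets()]).
#' @param n_flies number of flies.
#' @param out_dir output directory.
#' @param duration_s assay duration per fly, s.
#' @param seed base seed; fly i uses `seed + i - 1`.
#' @param a arena (standard arena when `NULL`).
#' @return invisibly, the vector of trajectory paths.
#' @export
simulate_cohort <- function(params, n_flies, out_dir, duration_s = 7200,
                            seed = 1, a = NULL) {
  if (is.character(params)) params <- make_presets()[[params]]
  if (is.null(a)) a <- build_standard_arena()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_arena(a, file.path(out_dir, "arena.json"))
  paths <- character(n_flies)
  for (i in seq_len(n_flies)) {
    sim <- simulate_fly(params, a, duration_s = duration_s,
                        seed = seed + i - 1)
    paths[i] <- file.path(out_dir, sprintf("fly%03d.csv", i))
    write_trajectory(sim$track, paths[i])
    data.table::fwrite(sim$truth$visits,
                       file.path(out_dir, sprintf("fly%03d_truth_visits.csv", i)))
  }
  invisible(paths)
}
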