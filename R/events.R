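#' Patch-event thresholds
#'
#' Distance rules are head-to-patch-center distances on the smoothed
#' head: an encounter is a crossing of the 3 mm ring; food
#' micromovements require the head within 2.5 mm; visit continuity and
#' encounter merging use the 5 mm ring; interruptions with total head
#' displacement at most 2 px (0.31 mm) are merged; long visits last at
#' least 30 s.
#'
#' @param encounter_radius,micromove_radius,visit_merge_radius mm.
#' @param displacement_merge mm (2 px at 0.155 mm/px).
#' @param long_visit_min_s seconds.
#' @return list of thresholds.
#' @export
event_thresholds <- function(encounter_radius = 3, micromove_radius = 2.5,
                             visit_merge_radius = 5,
                             displacement_merge = 0.31,
                             long_visit_min_s = 30) {
  stopifnot(micromove_radius < encounter_radius,
            encounter_radius < visit_merge_radius)
  list(encounter_radius = encounter_radius,
       micromove_radius = micromove_radius,
       visit_merge_radius = visit_merge_radius,
       displacement_merge = displacement_merge,
       long_visit_min_s = long_visit_min_s)
}

# logical mask -> matrix of half-open [start, end) runs of TRUE
mask_runs <- function(mask) {
  r <- rle(mask)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  cbind(start = start[r$values], end = end[r$values] + 1L)
}

# TRUE when the head never strays more than `tol` from its position at
# the first gap frame ("2 px total displacement" rule, strict reading)
gap_is_stationary <- function(head, gs, ge, tol) {
  if (ge < gs) return(TRUE)
  ref <- head[gs, ]
  d <- sqrt((head[gs:ge, 1] - ref[1])^2 + (head[gs:ge, 2] - ref[2])^2)
  max(d) <= tol
}

# merge consecutive same-patch intervals; `ok_gap(gap_start, gap_end)`
# decides mergeability (frames inclusive). Repeats to fixpoint.
merge_intervals <- function(iv, ok_gap) {
  if (nrow(iv) <= 1) return(iv)
  repeat {
    merged_any <- FALSE
    out <- list(iv[1, ])
    for (i in 2:nrow(iv)) {
      last <- out[[length(out)]]
      gs <- last[2]; ge <- iv[i, 1] - 1L
      if (ok_gap(gs, ge)) {
        last[2] <- iv[i, 2]
        out[[length(out)]] <- last
        merged_any <- TRUE
      } else out[[length(out) + 1L]] <- iv[i, ]
    }
    iv <- do.call(rbind, out)
    if (!merged_any || nrow(iv) <= 1) return(iv)
  }
}

empty_events <- function() {
  data.frame(patch_id = integer(0), substrate = character(0),
             start = integer(0), end = integer(0), duration_s = numeric(0))
}

#' Detect patch encounters
#'
#' Raw encounters are maximal runs of frames with head distance to a
#' patch center at or below the 3 mm threshold. Consecutive same-patch
#' encounters are merged when (a) during the gap the head never moves
#' more than 0.31 mm from its position at the start of the gap, or (b)
#' the head distance to that patch center never exceeds 5 mm during the
#' gap; merging is repeated to fixpoint. Encounters on different patches
#' are never merged.
#'
#' @param track a `forage_smooth`.
#' @param a a `forage_arena`.
#' @param th thresholds from [event_thresholds()].
#' @return data.frame of encounters: `patch_id`, `substrate`, `start`,
#'   `end` (half-open 1-based frames), `duration_s`; ordered by start.
#' @export
detect_encounters <- function(track, a, th = event_thresholds()) {
  D <- patch_distance_matrix(track$head, a)
  out <- list()
  for (k in seq_len(nrow(a$patches))) {
    iv <- mask_runs(D[, k] <= th$encounter_radius)
    if (nrow(iv) == 0) next
    ok <- function(gs, ge) {
      gap_is_stationary(track$head, gs, ge, th$displacement_merge) ||
        max(D[gs:ge, k]) <= th$visit_merge_radius
    }
    iv <- merge_intervals(iv, ok)
    out[[length(out) + 1L]] <-
      data.frame(patch_id = a$patches$id[k],
                 substrate = a$patches$substrate[k],
                 start = iv[, 1], end = iv[, 2])
  }
  finish_events(out, track$fps)
}

finish_events <- function(out, fps) {
  if (!length(out)) return(empty_events())
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  ev$duration_s <- (ev$end - ev$start) / fps
  rownames(ev) <- NULL
  ev
}

#' Detect food micromovements
#'
#' Frames that are classified as micromovement while the head is within
#' 2.5 mm of a patch center, grouped into runs per patch; interruptions
#' during which the head stays within 0.31 mm of its position at the
#' start of the interruption are merged (no false new micromovements).
#'
#' @param labels a `forage_ethogram`.
#' @param track a `forage_smooth`.
#' @param a a `forage_arena`.
#' @param th thresholds from [event_thresholds()].
#' @return data.frame like [detect_encounters()].
#' @export
detect_food_micromovements <- function(labels, track, a,
                                       th = event_thresholds()) {
  D <- patch_distance_matrix(track$head, a)
  near <- D <= th$micromove_radius
  if (any(rowSums(near) > 1))
    stop("head within micromovement radius of two patches; arena layout violated")
  micro <- labels$label == "micromovement"
  out <- list()
  for (k in seq_len(nrow(a$patches))) {
    iv <- mask_runs(micro & near[, k])
    if (nrow(iv) == 0) next
    ok <- function(gs, ge)
      gap_is_stationary(track$head, gs, ge, th$displacement_merge)
    iv <- merge_intervals(iv, ok)
    out[[length(out) + 1L]] <-
      data.frame(patch_id = a$patches$id[k],
                 substrate = a$patches$substrate[k],
                 start = iv[, 1], end = iv[, 2])
  }
  finish_events(out, track$fps)
}

#' Group food micromovements into visits
#'
#' A visit is a series of consecutive same-patch food micromovements
#' during which the head distance to the patch center never exceeds 5 mm
#' in between. The visit spans the first micromovement's start to the
#' last one's end; per-visit summaries record the minimum head distance
#' to the patch center and the number of distinct calibration-grid cells
#' (0.155 mm, arena-origin aligned) covered by the head.
#'
#' @param micromovements output of [detect_food_micromovements()].
#' @param track a `forage_smooth`.
#' @param a a `forage_arena`.
#' @param th thresholds from [event_thresholds()].
#' @return data.frame of visits with `patch_id`, `substrate`, `start`,
#'   `end`, `duration_s`, `n_micromovements`, `min_dist_mm`,
#'   `area_cells`.
#' @export
build_visits <- function(micromovements, track, a, th = event_thresholds()) {
  out <- list()
  for (k in seq_len(nrow(a$patches))) {
    mm <- micromovements[micromovements$patch_id == a$patches$id[k], ,
                         drop = FALSE]
    if (nrow(mm) == 0) next
    ctr <- c(a$patches$x[k], a$patches$y[k])
    d <- sqrt((track$head[, 1] - ctr[1])^2 + (track$head[, 2] - ctr[2])^2)
    iv <- cbind(start = mm$start, end = mm$end)
    counts <- rep(1L, nrow(iv))
    if (nrow(iv) > 1) {
      ok <- function(gs, ge) ge < gs || max(d[gs:ge]) <= th$visit_merge_radius
      # track constituent counts alongside the merge
      merged <- list(c(iv[1, ], 1L))
      for (i in 2:nrow(iv)) {
        last <- merged[[length(merged)]]
        gs <- last[2]; ge <- iv[i, 1] - 1L
        if (ok(gs, ge)) {
          last[2] <- iv[i, 2]; last[3] <- last[3] + 1L
          merged[[length(merged)]] <- last
        } else merged[[length(merged) + 1L]] <- c(iv[i, ], 1L)
      }
      m <- do.call(rbind, merged)
      iv <- m[, 1:2, drop = FALSE]
      counts <- m[, 3]
    }
    span <- function(i) iv[i, 1]:(iv[i, 2] - 1L)
    grid <- a$mm_per_px
    out[[length(out) + 1L]] <- data.frame(
      patch_id = a$patches$id[k], substrate = a$patches$substrate[k],
      start = iv[, 1], end = iv[, 2],
      n_micromovements = counts,
      min_dist_mm = vapply(seq_len(nrow(iv)),
                           function(i) min(d[span(i)]), 0),
      area_cells = vapply(seq_len(nrow(iv)), function(i) {
        s <- span(i)
        length(unique(paste(floor(track$head[s, 1] / grid),
                            floor(track$head[s, 2] / grid))))
      }, 0L))
  }
  ev <- finish_events(out, track$fps)
  if (!nrow(ev)) {
    ev <- cbind(empty_events(), n_micromovements = integer(0),
                min_dist_mm = numeric(0), area_cells = integer(0))
  }
  ev
}

#' Latency to the first long visit
#'
#' Time from assay start to the onset of the first visit of the given
#' substrate lasting at least `min_s` seconds. When no visit qualifies,
#' the assay duration is returned flagged as censored.
#'
#' @param visits output of [build_visits()].
#' @param track a `forage_smooth` (for frame-to-time conversion).
#' @param substrate `"yeast"` or `"sucrose"`.
#' @param min_s minimum qualifying duration, s.
#' @param assay_s assay duration, s (default: track length).
#' @return list with `latency_s`, `censored`, and `frame` (1-based onset
#'   frame, `NA` when censored).
#' @export
latency_to_first_long_visit <- function(visits, track, substrate = "yeast",
                                        min_s = 30,
                                        assay_s = track$n / track$fps) {
  v <- visits[visits$substrate == substrate & visits$duration_s >= min_s, ,
              drop = FALSE]
  if (nrow(v) == 0)
    return(list(latency_s = assay_s, censored = TRUE, frame = NA_integer_))
  f <- min(v$start)
  list(latency_s = (f - 1L) / track$fps, censored = FALSE, frame = f)
}

#' Run the full event segmentation for one fly
#'
#' @param track a `forage_smooth`.
#' @param labels a `forage_ethogram` (computed from `track` when `NULL`).
#' @param a a `forage_arena`.
#' @param th event thresholds. @param ath activity thresholds.
#' @return list with `encounters`, `micromovements`, `visits`, `labels`.
#' @export
segment_events <- function(track, a, labels = NULL,
                           th = event_thresholds(),
                           ath = activity_thresholds()) {
  if (is.null(labels)) labels <- ethogram(track, ath)
  enc <- detect_encounters(track, a, th)
  mm <- detect_food_micromovements(labels, track, a, th)
  vis <- build_visits(mm, track, a, th)
  list(encounters = enc, micromovements = mm, visits = vis, labels = labels)
}
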