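#' Activity classification thresholds
#'
#' Defaults follow the printed classification rules: rest at filtered
#' head speed <= 0.2 mm/s, walk at > 2 mm/s, sharp turns at angular-speed
#' local maxima >= 125 deg/s with body speed below 4 mm/s. The optional
#' 2 mm/s lower body-speed bound for sharp turns (used in the figure
#' description but not the operational definition) is off by default.
#'
#' @param rest_max,walk_min mm/s.
#' @param sharpturn_angular_min degrees/s.
#' @param sharpturn_body_speed_max,sharpturn_body_speed_min mm/s;
#'   `sharpturn_body_speed_min = NULL` disables the lower bound.
#' @param sharpturn_hysteresis fraction of the angular threshold at which
#'   a sharp-turn event's extent ends around its peak.
#' @return list of thresholds.
#' @export
activity_thresholds <- function(rest_max = 0.2, walk_min = 2,
                                sharpturn_angular_min = 125,
                                sharpturn_body_speed_max = 4,
                                sharpturn_body_speed_min = NULL,
                                sharpturn_hysteresis = 0.5) {
  stopifnot(rest_max < walk_min, walk_min < sharpturn_body_speed_max)
  list(rest_max = rest_max, walk_min = walk_min,
       sharpturn_angular_min = sharpturn_angular_min,
       sharpturn_body_speed_max = sharpturn_body_speed_max,
       sharpturn_body_speed_min = sharpturn_body_speed_min,
       sharpturn_hysteresis = sharpturn_hysteresis)
}

activity_levels <- c("rest", "micromovement", "walk")

#' Classify every frame into rest / micromovement / walk
#'
#' A frame is *walk* when the 1.2 s-filtered head speed exceeds
#' `walk_min`; among non-walk frames, *rest* when the 2.4 s-filtered head
#' speed is at or below `rest_max`; the remaining non-walk frames are
#' *micromovement*. Walk takes precedence because resting is only
#' classified within non-walking segments.
#'
#' @param track a `forage_smooth`.
#' @param th thresholds from [activity_thresholds()].
#' @return a `forage_ethogram`: list with `label` (factor per frame),
#'   `bouts` (half-open `[start, end)` 1-based frame intervals tiling the
#'   track), and `fps`.
#' @export
classify_activity <- function(track, th = activity_thresholds()) {
  lab <- ifelse(track$head_speed_walk > th$walk_min, "walk",
         ifelse(track$head_speed_rest <= th$rest_max, "rest", "micromovement"))
  lab <- factor(lab, levels = activity_levels)
  r <- rle(as.character(lab))
  end <- cumsum(r$lengths)
  bouts <- data.frame(label = r$values,
                      start = end - r$lengths + 1L,
                      end = end + 1L,
                      stringsAsFactors = FALSE)
  bouts$duration_s <- (bouts$end - bouts$start) / track$fps
  structure(list(label = lab, bouts = bouts, fps = track$fps,
                 sharp_turn = rep(FALSE, track$n)),
            class = "forage_ethogram")
}

#' @export
print.forage_ethogram <- function(x, ...) {
  tb <- table(x$label)
  cat(sprintf("<forage_ethogram> %d frames: %s; %d sharp-turn frames\n",
              length(x$label),
              paste(sprintf("%s %.1f%%", names(tb), 100 * tb / length(x$label)),
                    collapse = ", "),
              sum(x$sharp_turn)))
  invisible(x)
}

#' Detect sharp-turn events
#'
#' An event is anchored at a strict local maximum of |angular speed|
#' above `sharpturn_angular_min` whose body speed at the peak frame is
#' below `sharpturn_body_speed_max` (and above the optional lower bound,
#' when set). The event extent grows from the peak until |angular speed|
#' falls below `sharpturn_hysteresis` times the threshold; overlapping
#' extents are merged. Sharp turn is an overlay flag on top of the
#' exclusive rest/micromovement/walk labels.
#'
#' @param angular_speed signed degrees/s per frame.
#' @param body_speed mm/s per frame.
#' @param th thresholds from [activity_thresholds()].
#' @return list with `events` (data.frame `start`, `end` half-open,
#'   `peak_frame`, `peak_abs_deg_s`) and `flag` (logical per frame).
#' @export
detect_sharp_turns <- function(angular_speed, body_speed,
                               th = activity_thresholds()) {
  a <- abs(angular_speed)
  n <- length(a)
  flag <- logical(n)
  events <- list()
  if (n >= 3) {
    core <- a[2:(n - 1)]
    is_peak <- which(core > a[1:(n - 2)] & core > a[3:n] &
                     core > th$sharpturn_angular_min) + 1L
    is_peak <- is_peak[body_speed[is_peak] < th$sharpturn_body_speed_max]
    if (!is.null(th$sharpturn_body_speed_min))
      is_peak <- is_peak[body_speed[is_peak] > th$sharpturn_body_speed_min]
    lo <- th$sharpturn_hysteresis * th$sharpturn_angular_min
    for (p in is_peak) {
      s <- p
      while (s > 1 && a[s - 1] >= lo) s <- s - 1L
      e <- p
      while (e < n && a[e + 1] >= lo) e <- e + 1L
      events[[length(events) + 1L]] <- c(s, e + 1L, p, a[p])
    }
  }
  if (length(events)) {
    ev <- do.call(rbind, events)
    ev <- ev[order(ev[, 1]), , drop = FALSE]
    merged <- list(ev[1, ])
    if (nrow(ev) > 1) {
      for (i in 2:nrow(ev)) {
        last <- merged[[length(merged)]]
        if (ev[i, 1] <= last[2]) {  # overlap/abut -> merge
          last[2] <- max(last[2], ev[i, 2])
          if (ev[i, 4] > last[4]) { last[3] <- ev[i, 3]; last[4] <- ev[i, 4] }
          merged[[length(merged)]] <- last
        } else merged[[length(merged) + 1L]] <- ev[i, ]
      }
    }
    ev <- do.call(rbind, merged)
    out <- data.frame(start = ev[, 1], end = ev[, 2],
                      peak_frame = ev[, 3], peak_abs_deg_s = ev[, 4])
    for (i in seq_len(nrow(out))) flag[out$start[i]:(out$end[i] - 1L)] <- TRUE
  } else {
    out <- data.frame(start = integer(0), end = integer(0),
                      peak_frame = integer(0), peak_abs_deg_s = numeric(0))
  }
  list(events = out, flag = flag)
}

#' Full per-frame ethogram (activity labels + sharp-turn overlay)
#'
#' @param track a `forage_smooth`.
#' @param th thresholds from [activity_thresholds()].
#' @return a `forage_ethogram` with the `sharp_turn` flag filled in and a
#'   `sharp_turn_events` table.
#' @export
ethogram <- function(track, th = activity_thresholds()) {
  eg <- classify_activity(track, th)
  st <- detect_sharp_turns(track$angular_speed, track$body_speed, th)
  eg$sharp_turn <- st$flag
  eg$sharp_turn_events <- st$events
  eg
}

#' Export an ethogram as per-frame and bout tables
#'
#' @param eg a `forage_ethogram`.
#' @return list of two data.frames: `frames` (frame, label, sharp_turn)
#'   and `bouts` (label, start_frame, end_frame, duration_s).
#' @export
ethogram_tables <- function(eg) {
  list(frames = data.frame(frame = seq_along(eg$label) - 1L,
                           label = as.character(eg$label),
                           sharp_turn = as.integer(eg$sharp_turn)),
       bouts = data.frame(label = eg$bouts$label,
                          start_frame = eg$bouts$start - 1L,
                          end_frame = eg$bouts$end - 1L,
                          duration_s = eg$bouts$duration_s))
}
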