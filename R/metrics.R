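#' Micromovement totals and cumulative curve
#'
#' Totals are reported in minutes; the cumulative curve is sampled per
#' frame so its final value equals the total.
#'
#' @param micromovements event table from [detect_food_micromovements()].
#' @param substrate `"yeast"` or `"sucrose"`.
#' @param n_frames track length in frames.
#' @param fps frames per second.
#' @return list with `total_min`, `n_events`, and `cumulative_min`
#'   (numeric per frame).
#' @export
micromovement_metrics <- function(micromovements, substrate, n_frames, fps) {
  mm <- micromovements[micromovements$substrate == substrate, , drop = FALSE]
  inmask <- logical(n_frames)
  for (i in seq_len(nrow(mm)))
    inmask[mm$start[i]:(mm$end[i] - 1L)] <- TRUE
  cum <- cumsum(inmask) / fps / 60
  list(total_min = sum(mm$duration_s) / 60, n_events = nrow(mm),
       cumulative_min = cum)
}

# frames in which the fly is inside any event interval of a table
event_frame_mask <- function(ev, n_frames) {
  m <- logical(n_frames)
  for (i in seq_len(nrow(ev))) m[ev$start[i]:(ev$end[i] - 1L)] <- TRUE
  m
}

#' Encounter-level metrics: count, rate and stopping probability
#'
#' The encounter rate divides the number of encounters by the minutes
#' the fly spent walking with its head further than the micromovement
#' radius from every patch center ("walking outside the food patches").
#' P(stop) is the fraction of encounters containing at least one food
#' micromovement on the same patch. With zero encounters the rate is 0
#' and P(stop) is `NA` (undefined, not 0).
#'
#' @param encounters,micromovements event tables (one fly).
#' @param labels a `forage_ethogram`.
#' @param track a `forage_smooth`.
#' @param a a `forage_arena`.
#' @param substrate substrate to score.
#' @param th event thresholds.
#' @return list with `n_encounters`, `rate_per_min`, `p_stop`.
#' @export
encounter_metrics <- function(encounters, micromovements, labels, track, a,
                              substrate = "yeast", th = event_thresholds()) {
  enc <- encounters[encounters$substrate == substrate, , drop = FALSE]
  mm <- micromovements[micromovements$substrate == substrate, , drop = FALSE]
  D <- patch_distance_matrix(track$head, a)
  outside <- apply(D > th$micromove_radius, 1, all)
  walk_out_min <- sum(labels$label == "walk" & outside) / track$fps / 60
  n <- nrow(enc)
  if (n == 0)
    return(list(n_encounters = 0L, rate_per_min = 0, p_stop = NA_real_))
  stopped <- vapply(seq_len(n), function(i) {
    any(mm$patch_id == enc$patch_id[i] &
        mm$start < enc$end[i] & mm$end > enc$start[i])
  }, TRUE)
  list(n_encounters = n,
       rate_per_min = if (walk_out_min > 0) n / walk_out_min else NA_real_,
       p_stop = mean(stopped))
}

#' Visit-level metrics
#'
#' Aggregates per-visit summaries for one substrate: total and mean
#' visit duration (min), mean of the per-visit minimum head distance to
#' the patch center (mm), mean area covered (distinct 0.155 mm grid
#' cells), and the mean 1.2 s-filtered body speed and mean |angular
#' speed| over all in-visit frames. With zero visits the aggregates are
#' `NA`.
#'
#' @param visits table from [build_visits()].
#' @param track a `forage_smooth`.
#' @param substrate substrate to score.
#' @return list of aggregates.
#' @export
visit_metrics <- function(visits, track, substrate = "yeast") {
  v <- visits[visits$substrate == substrate, , drop = FALSE]
  if (nrow(v) == 0)
    return(list(n_visits = 0L, total_min = 0, mean_duration_min = NA_real_,
                mean_min_dist_mm = NA_real_, mean_area_cells = NA_real_,
                body_speed_mm_s = NA_real_, angular_speed_deg_s = NA_real_))
  inmask <- event_frame_mask(v, track$n)
  list(n_visits = nrow(v),
       total_min = sum(v$duration_s) / 60,
       mean_duration_min = mean(v$duration_s) / 60,
       mean_min_dist_mm = mean(v$min_dist_mm),
       mean_area_cells = mean(v$area_cells),
       body_speed_mm_s = mean(track$body_speed_f[inmask]),
       angular_speed_deg_s = mean(abs(track$angular_speed[inmask])))
}

#' Windowed total visit duration (rolling exploitation curve)
#'
#' For each 5-min window advanced in 4-min steps, sums the overlap of
#' every visit with the window (visits crossing a boundary contribute
#' their overlap to each window). Across-fly medians of these series
#' give the population exploitation time course.
#'
#' @param visits table from [build_visits()] (one fly; filter substrate
#'   beforehand if desired).
#' @param assay_s assay duration, s.
#' @param fps frames per second (visit frames -> seconds).
#' @param window_s,step_s window width and step, s.
#' @param substrate optional substrate filter.
#' @return data.frame with `window_start_s`, `window_end_s`, `value_s`.
#' @export
sliding_window_visit_duration <- function(visits, assay_s, fps = 50,
                                          window_s = 300, step_s = 240,
                                          substrate = NULL) {
  if (!is.null(substrate))
    visits <- visits[visits$substrate == substrate, , drop = FALSE]
  starts <- step_s * (seq_len(max(1, ceiling(assay_s / step_s))) - 1)
  starts <- starts[starts < assay_s]
  vs <- (visits$start - 1) / fps
  ve <- (visits$end - 1) / fps
  val <- vapply(starts, function(w0) {
    w1 <- min(w0 + window_s, assay_s)
    sum(pmax(0, pmin(ve, w1) - pmax(vs, w0)))
  }, 0)
  data.frame(window_start_s = starts,
             window_end_s = pmin(starts + window_s, assay_s),
             value_s = val)
}

#' Classify yeast-to-yeast visit transitions
#'
#' For each pair of consecutive yeast visits the transition is *same*
#' when both visits are on the same patch and the head stayed within
#' 16 mm of that patch center throughout the inter-visit interval;
#' *adjacent* when the patches differ, their centers are within 16 mm,
#' and the head stayed within 16 mm of the previous patch center
#' throughout; *distant* otherwise (center distance > 16 mm or head
#' excursion > 16 mm at any point). Only transitions between visited
#' yeast patches are considered; intervening sucrose visits do not break
#' a yeast-to-yeast transition. Probabilities divide class counts by the
#' number of transitions so they sum to 1.
#'
#' @param visits visit table (all substrates; yeast is selected inside).
#' @param track a `forage_smooth`.
#' @param a a `forage_arena`.
#' @param adjacency_mm the 16 mm rule threshold.
#' @param substrate substrate whose visits define transitions.
#' @return list with `transitions` (data.frame `from_patch`, `to_patch`,
#'   `class`, `path_mm`, `max_excursion_mm`, `to_start`) and
#'   `probabilities` (named numeric same/adjacent/distant, `NA` when no
#'   transitions exist).
#' @export
classify_transitions <- function(visits, track, a, adjacency_mm = 16,
                                 substrate = "yeast") {
  v <- visits[visits$substrate == substrate, , drop = FALSE]
  v <- v[order(v$start), , drop = FALSE]
  probs <- c(same = NA_real_, adjacent = NA_real_, distant = NA_real_)
  if (nrow(v) < 2)
    return(list(transitions = data.frame(from_patch = integer(0),
                                         to_patch = integer(0),
                                         class = character(0),
                                         path_mm = numeric(0),
                                         max_excursion_mm = numeric(0),
                                         to_start = integer(0)),
                probabilities = probs))
  step <- c(sqrt(diff(track$head[, 1])^2 + diff(track$head[, 2])^2), 0)
  recs <- lapply(seq_len(nrow(v) - 1L), function(i) {
    from <- v$patch_id[i]; to <- v$patch_id[i + 1L]
    k <- match(from, a$patches$id)
    ctr <- c(a$patches$x[k], a$patches$y[k])
    gap <- v$end[i]:(v$start[i + 1L])  # last in-visit boundary inclusive
    d <- sqrt((track$head[gap, 1] - ctr[1])^2 +
              (track$head[gap, 2] - ctr[2])^2)
    maxd <- max(d)
    ctr_dist <- sqrt((a$patches$x[k] - a$patches$x[match(to, a$patches$id)])^2 +
                     (a$patches$y[k] - a$patches$y[match(to, a$patches$id)])^2)
    cls <- if (maxd > adjacency_mm) "distant"
           else if (from == to) "same"
           else if (ctr_dist <= adjacency_mm) "adjacent"
           else "distant"
    path <- if (v$start[i + 1L] > v$end[i])
      sum(step[v$end[i]:(v$start[i + 1L] - 1L)]) else 0
    data.frame(from_patch = from, to_patch = to, class = cls,
               path_mm = path, max_excursion_mm = maxd,
               to_start = v$start[i + 1L])
  })
  tr <- do.call(rbind, recs)
  tb <- table(factor(tr$class, levels = c("same", "adjacent", "distant")))
  probs[] <- as.numeric(tb) / nrow(tr)
  list(transitions = tr, probabilities = probs)
}

#' Rescale median transition probabilities to sum to 100%
#'
#' Helper for pie-chart style summaries: across-fly medians of the three
#' transition probabilities need not sum to one; this renormalizes them
#' to percentages.
#'
#' @param med named numeric (same/adjacent/distant medians).
#' @return named numeric percentages summing to 100.
#' @export
scale_transition_medians <- function(med) 100 * med / sum(med)

#' Mean path length traveled to the next yeast visit
#'
#' For every interval from the end of a visit to any patch to the start
#' of the next yeast visit, sums the frame-to-frame smoothed-head
#' displacements, then averages across intervals.
#'
#' @param visits visit table (all substrates).
#' @param track a `forage_smooth`.
#' @param substrate destination substrate.
#' @return mean distance in mm (`NA` with no qualifying interval).
#' @export
distance_to_next_yeast_visit <- function(visits, track, substrate = "yeast") {
  v <- visits[order(visits$start), , drop = FALSE]
  if (nrow(v) < 2) return(NA_real_)
  step <- c(sqrt(diff(track$head[, 1])^2 + diff(track$head[, 2])^2), 0)
  j <- which(v$substrate == substrate)
  j <- j[j > 1]  # needs a preceding visit (of any substrate)
  if (!length(j)) return(NA_real_)
  dists <- vapply(j, function(k) {
    if (v$start[k] > v$end[k - 1L])
      sum(step[v$end[k - 1L]:(v$start[k] - 1L)]) else 0
  }, 0)
  mean(dists)
}

#' Yeast quartiles: satiation-anchored time windows
#'
#' The cumulative yeast-micromovement time from the latency point (first
#' long yeast visit) onward is taken as 100% of "yeast time"; quartile
#' boundaries are the absolute frames at which 25/50/75/100% of that
#' time have accumulated. Each window therefore contains 25% (+/- one
#' frame) of yeast time but spans a different amount of assay time.
#'
#' @param micromovements event table (yeast selected inside).
#' @param latency output of [latency_to_first_long_visit()].
#' @param track a `forage_smooth`.
#' @param min_frames minimum yeast-micromovement frames after latency.
#' @return data.frame with one row per quartile: `quartile`, `start`,
#'   `end` (half-open frames), `yeast_frames`; or `NULL` when the
#'   latency is censored or there is too little yeast time.
#' @export
yeast_quartiles <- function(micromovements, latency, track, min_frames = 4) {
  if (latency$censored) return(NULL)
  mm <- micromovements[micromovements$substrate == "yeast", , drop = FALSE]
  mask <- event_frame_mask(mm, track$n)
  mask[seq_len(max(0, latency$frame - 1L))] <- FALSE
  yf <- which(mask)
  total <- length(yf)
  if (total < min_frames) return(NULL)
  cuts <- round(seq_len(4) * total / 4)
  ends <- yf[cuts] + 1L           # half-open window ends
  starts <- c(latency$frame, ends[1:3])
  data.frame(quartile = 1:4, start = starts, end = ends,
             yeast_frames = diff(c(0, cuts)))
}

#' Exploration/exploitation metrics within a frame window
#'
#' Recomputes the quartile-dynamics parameter set restricted to a
#' window: yeast visits are attributed to a window by their start frame;
#' transitions by the start of their destination visit.
#'
#' @param window list or row with `start`, `end` (half-open frames).
#' @param visits,track,a as in [classify_transitions()].
#' @return one-row data.frame of window metrics.
#' @export
window_metrics <- function(window, visits, track, a) {
  vy <- visits[visits$substrate == "yeast", , drop = FALSE]
  inw <- vy$start >= window$start & vy$start < window$end
  tr <- classify_transitions(visits, track, a)
  trs <- tr$transitions
  trw <- trs[trs$to_start >= window$start & trs$to_start < window$end, ,
             drop = FALSE]
  probs <- c(same = NA_real_, adjacent = NA_real_, distant = NA_real_)
  if (nrow(trw)) {
    tb <- table(factor(trw$class, levels = names(probs)))
    probs[] <- as.numeric(tb) / nrow(trw)
  }
  vin <- vy[inw, , drop = FALSE]
  frames <- intersect(which(event_frame_mask(vy, track$n)),
                      window$start:(window$end - 1L))
  data.frame(n_visits = sum(inw),
             mean_visit_duration_min =
               if (any(inw)) mean(vin$duration_s) / 60 else NA_real_,
             mean_min_dist_mm =
               if (any(inw)) mean(vin$min_dist_mm) else NA_real_,
             angular_speed_deg_s =
               if (length(frames)) mean(abs(track$angular_speed[frames]))
               else NA_real_,
             p_same = probs["same"], p_adjacent = probs["adjacent"],
             p_distant = probs["distant"],
             mean_transition_path_mm =
               if (nrow(trw)) mean(trw$path_mm) else NA_real_,
             row.names = NULL)
}

#' Population-level metrics within a condition
#'
#' Non-eaters are flies whose total yeast visit duration is below one
#' minute; the coefficient of variation is sd/mean of the per-fly total
#' yeast micromovement durations.
#'
#' @param total_visit_min numeric per fly, total yeast visit duration
#'   (min).
#' @param total_micromove_min numeric per fly, total yeast micromovement
#'   duration (min).
#' @param non_eater_min threshold in minutes.
#' @return list with `fraction_non_eaters` and `cv_micromovement_total`.
#' @export
population_metrics <- function(total_visit_min, total_micromove_min,
                               non_eater_min = 1) {
  if (length(total_visit_min) < 2) stop("need at least 2 flies per condition")
  m <- mean(total_micromove_min)
  list(fraction_non_eaters = mean(total_visit_min < non_eater_min),
       cv_micromovement_total =
         if (m > 0) stats::sd(total_micromove_min) / m else NA_real_)
}

#' The full per-fly parameter set
#'
#' Computes the per-fly exploitation, exploration and locomotor activity
#' parameters from one fly's segmented events: micromovement and visit
#' totals/counts/averages per substrate, encounter count/rate and
#' P(stop), latency to the first long yeast visit, on-patch locomotion,
#' transition probabilities, mean distance to the next yeast visit, and
#' mean body speed outside visits.
#'
#' @param track a `forage_smooth`.
#' @param a a `forage_arena`.
#' @param seg output of [segment_events()] (computed when `NULL`).
#' @param th event thresholds. @param ath activity thresholds.
#' @return one-row data.frame.
#' @export
fly_metrics <- function(track, a, seg = NULL, th = event_thresholds(),
                        ath = activity_thresholds()) {
  if (is.null(seg)) seg <- segment_events(track, a, th = th, ath = ath)
  labels <- seg$labels
  assay_s <- track$n / track$fps
  mmy <- micromovement_metrics(seg$micromovements, "yeast", track$n, track$fps)
  mms <- micromovement_metrics(seg$micromovements, "sucrose", track$n, track$fps)
  ency <- encounter_metrics(seg$encounters, seg$micromovements, labels,
                            track, a, "yeast", th)
  vy <- visit_metrics(seg$visits, track, "yeast")
  vs <- visit_metrics(seg$visits, track, "sucrose")
  lat <- latency_to_first_long_visit(seg$visits, track, "yeast",
                                     th$long_visit_min_s, assay_s)
  tr <- classify_transitions(seg$visits, track, a)
  outside <- !event_frame_mask(seg$visits, track$n)
  data.frame(
    total_yeast_micromove_min = mmy$total_min,
    n_yeast_micromove = mmy$n_events,
    total_sucrose_micromove_min = mms$total_min,
    n_sucrose_micromove = mms$n_events,
    total_yeast_visit_min = vy$total_min,
    n_yeast_visits = vy$n_visits,
    mean_yeast_visit_min = vy$mean_duration_min,
    total_sucrose_visit_min = vs$total_min,
    n_sucrose_visits = vs$n_visits,
    n_yeast_encounters = ency$n_encounters,
    yeast_encounter_rate_per_min = ency$rate_per_min,
    p_stop_yeast = ency$p_stop,
    latency_long_yeast_visit_min = lat$latency_s / 60,
    latency_censored = lat$censored,
    mean_min_dist_mm = vy$mean_min_dist_mm,
    mean_area_cells = vy$mean_area_cells,
    body_speed_visits_mm_s = vy$body_speed_mm_s,
    angular_speed_visits_deg_s = vy$angular_speed_deg_s,
    p_same = unname(tr$probabilities["same"]),
    p_adjacent = unname(tr$probabilities["adjacent"]),
    p_distant = unname(tr$probabilities["distant"]),
    n_transitions = nrow(tr$transitions),
    dist_to_next_yeast_visit_mm =
      distance_to_next_yeast_visit(seg$visits, track),
    speed_outside_mm_s =
      if (any(outside)) mean(track$body_speed_f[outside]) else NA_real_)
}
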