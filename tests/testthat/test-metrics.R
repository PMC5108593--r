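ev_row <- function(patch, sub, start, end, fps = 50) {
  data.frame(patch_id = patch, substrate = sub, start = start, end = end,
             duration_s = (end - start) / fps)
}

test_that("micromovement totals and cumulative curve conserve time", {
  fps <- 50
  mm <- rbind(ev_row(1, "yeast", 101, 101 + 30 * fps),
              ev_row(1, "yeast", 5001, 5001 + 90 * fps))
  n <- 10000
  m <- micromovement_metrics(mm, "yeast", n, fps)
  expect_equal(m$total_min, 2)          # 30 s + 90 s
  expect_equal(m$n_events, 2)
  expect_equal(m$cumulative_min[n], m$total_min)
  expect_true(all(diff(m$cumulative_min) >= 0))
  z <- micromovement_metrics(mm[0, ], "yeast", n, fps)
  expect_equal(z$total_min, 0)
  expect_true(all(z$cumulative_min == 0))
})

test_that("p_stop and encounter rate follow their definitions", {
  a <- arena(data.frame(id = 1, x = 0, y = 0, radius = 1.5,
                        substrate = "yeast"))
  fps <- 50
  # 10 encounters; micromovements inside 4 of them; 6 min of walking
  # far from the patch
  n <- 12 * 60 * fps
  head <- cbind(rep(10, n), 0)
  hsw <- rep(0.1, n); hsr <- rep(0.1, n)
  enc <- list(); mms <- list()
  for (k in 1:10) {
    s <- 1000 * k; e <- s + 100
    head[s:e, 1] <- 2.4
    enc[[k]] <- ev_row(1, "yeast", s, e + 1L)
    if (k <= 4) mms[[k]] <- ev_row(1, "yeast", s + 10, s + 60)
  }
  # 6 min of walking outside (> 2.5 mm from the patch)
  walk_idx <- (n - 6 * 60 * fps + 1):n
  hsw[walk_idx] <- 3; hsr[walk_idx] <- 3
  tr <- as_smooth_track(head, fps = fps, head_speed_walk = hsw,
                        head_speed_rest = hsr)
  labels <- classify_activity(tr)
  em <- encounter_metrics(do.call(rbind, enc), do.call(rbind, mms),
                          labels, tr, a, "yeast")
  expect_equal(em$p_stop, 0.4)
  # 10 encounters / 6 min walking outside
  expect_equal(em$rate_per_min, 10 / 6, tolerance = 0.01)
  # zero encounters: rate 0 handled upstream, p_stop missing
  em0 <- encounter_metrics(enc[[1]][0, ], mms[[1]][0, ], labels, tr, a, "yeast")
  expect_equal(em0$n_encounters, 0L)
  expect_true(is.na(em0$p_stop))
})

test_that("visit aggregates: durations, min distance, area", {
  fps <- 50
  a <- arena(data.frame(id = 1, x = 0, y = 0, radius = 1.5,
                        substrate = "yeast"))
  # stationary visit at exactly 1.0 mm from the center
  n <- 500
  tr <- as_smooth_track(cbind(rep(1, n), 0), fps = fps,
                        head_speed_walk = rep(1, n),
                        head_speed_rest = rep(1, n))
  seg <- segment_events(tr, a, labels = classify_activity(tr))
  vm <- visit_metrics(seg$visits, tr)
  expect_equal(vm$n_visits, 1L)
  expect_equal(vm$mean_min_dist_mm, 1.0)
  expect_equal(vm$mean_area_cells, 1)   # head never leaves one grid cell
  # visit durations 1, 2, 3 min -> total 6, mean 2
  v <- rbind(ev_row(1, "yeast", 1, 1 + 60 * fps),
             ev_row(1, "yeast", 10000, 10000 + 120 * fps),
             ev_row(1, "yeast", 30000, 30000 + 180 * fps))
  v$min_dist_mm <- 1; v$area_cells <- 5
  big <- as_smooth_track(cbind(seq_len(40000) * 1e-4, 0), fps = fps)
  vm <- visit_metrics(v, big)
  expect_equal(vm$total_min, 6)
  expect_equal(vm$mean_duration_min, 2)
  expect_true(is.na(visit_metrics(v[0, ], big)$mean_duration_min))
})

test_that("sliding-window visit durations clip overlaps", {
  fps <- 50
  # one 300 s visit exactly filling the first window
  v <- ev_row(1, "yeast", 1, 1 + 300 * fps)
  sw <- sliding_window_visit_duration(v, assay_s = 1200, fps = fps)
  expect_equal(sw$window_start_s, c(0, 240, 480, 720, 960))
  expect_equal(sw$value_s[1], 300)
  expect_equal(sw$value_s[2], 60)   # overlap 240..300
  expect_equal(sw$value_s[3], 0)
  # a 6-min visit spanning windows contributes its overlap to each
  v2 <- ev_row(1, "yeast", 1 + 200 * fps, 1 + 560 * fps)
  sw2 <- sliding_window_visit_duration(v2, assay_s = 1200, fps = fps)
  expect_equal(sw2$value_s[1], 100)  # 200..300
  expect_equal(sw2$value_s[2], 300)  # 240..540 fully inside
  expect_equal(sw2$value_s[3], 80)   # 480..560
  # no visits: all-zero series
  expect_true(all(sliding_window_visit_duration(v[0, ], 1200, fps)$value_s == 0))
})

test_that("transition classification follows the 16 mm rules", {
  a <- arena(data.frame(id = 1:2, x = c(0, 10), y = 0, radius = 1.5,
                        substrate = "yeast"))
  fps <- 50
  mk_tr <- function(xs) {
    n <- length(xs)
    as_smooth_track(cbind(xs, 0), fps = fps,
                    head_speed_walk = rep(3, n), head_speed_rest = rep(3, n))
  }
  v2 <- function(p1, p2, s2) rbind(
    cbind(ev_row(p1, "yeast", 1, 101), min_dist_mm = 1, area_cells = 1,
          n_micromovements = 1),
    cbind(ev_row(p2, "yeast", s2, s2 + 100), min_dist_mm = 1, area_cells = 1,
          n_micromovements = 1))
  # same patch, max head distance 12 mm in between -> same
  xs <- c(rep(1, 100), seq(1, 12, length.out = 100),
          seq(12, 1, length.out = 100), rep(1, 100))
  tr <- classify_transitions(v2(1, 1, 301), mk_tr(xs), a)
  expect_equal(tr$transitions$class, "same")
  expect_equal(unname(tr$probabilities), c(1, 0, 0))
  # different patches 10 mm apart, head always <= 16 mm -> adjacent
  xs <- c(rep(1, 100), seq(1, 11, length.out = 200), rep(11, 100))
  tr <- classify_transitions(v2(1, 2, 301), mk_tr(xs), a)
  expect_equal(tr$transitions$class, "adjacent")
  # same patch but 17 mm excursion -> distant
  xs <- c(rep(1, 100), seq(1, 17, length.out = 100),
          seq(17, 1, length.out = 100), rep(1, 100))
  tr <- classify_transitions(v2(1, 1, 301), mk_tr(xs), a)
  expect_equal(tr$transitions$class, "distant")
  # fewer than two yeast visits: empty, probabilities missing
  tr <- classify_transitions(v2(1, 1, 301)[1, ], mk_tr(xs), a)
  expect_equal(nrow(tr$transitions), 0)
  expect_true(all(is.na(tr$probabilities)))
  # pie helper renormalizes medians to 100%
  expect_equal(sum(scale_transition_medians(c(0.2, 0.3, 0.4))), 100)
})

test_that("distance to next yeast visit integrates the head path", {
  a <- arena(data.frame(id = 1:2, x = c(0, 40), y = 0, radius = 1.5,
                        substrate = c("yeast", "yeast")),
             inner_radius = 50)
  fps <- 50
  # straight 20 mm dash between two visits
  xs <- c(rep(0, 100), seq(0, 20, length.out = 201), rep(20, 100))
  tr <- as_smooth_track(cbind(xs, 0), fps = fps)
  v <- rbind(ev_row(1, "yeast", 1, 101), ev_row(2, "yeast", 302, 402))
  expect_equal(distance_to_next_yeast_visit(v, tr), 20, tolerance = 1e-6)
  # abutting visits contribute 0
  v2 <- rbind(ev_row(1, "yeast", 1, 101), ev_row(2, "yeast", 101, 201))
  expect_equal(distance_to_next_yeast_visit(v2, tr), 0)
  # semicircular path of radius r -> ~ pi * r
  r <- 10
  th <- seq(0, pi, length.out = 400)
  arcx <- r * cos(th); arcy <- r * sin(th)
  xs2 <- c(rep(arcx[1], 100), arcx, rep(arcx[400], 100))
  ys2 <- c(rep(arcy[1], 100), arcy, rep(arcy[400], 100))
  tr2 <- as_smooth_track(cbind(xs2, ys2), fps = fps)
  v3 <- rbind(ev_row(1, "yeast", 1, 101), ev_row(2, "yeast", 501, 601))
  expect_equal(distance_to_next_yeast_visit(v3, tr2), pi * r,
               tolerance = 0.02 * pi * r)
})

test_that("yeast quartiles split post-latency yeast time into 25% windows", {
  fps <- 50
  n <- 7200 * fps / 10   # 12 min track for speed
  tr <- as_smooth_track(cbind(seq_len(n) * 1e-4, 0), fps = fps)
  # yeast micromovements: 8 blocks of 30 s spread after latency at 60 s
  mm <- do.call(rbind, lapply(0:7, function(k)
    ev_row(1, "yeast", 60 * fps + k * 4000 + 1, 60 * fps + k * 4000 + 30 * fps)))
  lat <- list(latency_s = 60, censored = FALSE, frame = 60 * fps + 1)
  q <- yeast_quartiles(mm, lat, tr)
  expect_equal(nrow(q), 4)
  total <- sum(mm$end - mm$start)
  expect_true(all(abs(q$yeast_frames - total / 4) <= 1))
  expect_equal(sum(q$yeast_frames), total)       # conservation
  expect_true(all(q$start < q$end))
  expect_equal(q$start[-1], q$end[-4])           # contiguous
  # censored latency: undefined
  expect_null(yeast_quartiles(mm, list(censored = TRUE), tr))
})

test_that("population metrics: non-eater fraction and CV", {
  tv <- c(0.2, 0.5, 0.9, 2, 3, 4, 5, 6, 7, 8)   # 3 of 10 below 1 min
  tm <- c(1, 2, 3)
  pm <- population_metrics(tv, rep(2, 10))
  expect_equal(pm$fraction_non_eaters, 0.3)
  expect_equal(pm$cv_micromovement_total, 0)
  pm2 <- population_metrics(c(2, 2, 2), tm)
  expect_equal(pm2$cv_micromovement_total, sd(tm) / mean(tm))
  expect_error(population_metrics(1, 1), "2 flies")
})

test_that("fly_metrics is internally consistent on a simulated fly", {
  x <- sim_small(seed = 12, dur = 600)
  seg <- segment_events(x$track, x$arena)
  m <- fly_metrics(x$track, x$arena, seg = seg)
  expect_gte(m$total_yeast_visit_min, m$total_yeast_micromove_min - 1e-9)
  if (m$n_transitions > 0)
    expect_equal(m$p_same + m$p_adjacent + m$p_distant, 1)
  expect_true(is.na(m$p_stop_yeast) ||
              (m$p_stop_yeast >= 0 && m$p_stop_yeast <= 1))
  expect_gte(m$speed_outside_mm_s, 0)
})
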