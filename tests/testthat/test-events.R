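# event-rule fixtures are built in code by fixture_suite(); each carries
# hand-derived expected outputs

test_that("handcrafted fixtures reproduce their hand-derived event tables", {
  fx <- fixture_suite()
  seg <- lapply(fx, function(f)
    segment_events(f$track, f$arena, labels = f$labels))
  expect_equal(nrow(seg$graze$encounters), 1)
  expect_equal(nrow(seg$graze$visits), 0)
  expect_equal(nrow(seg$excursion4$encounters), 1)
  expect_equal(nrow(seg$excursion6$encounters), 2)
  expect_equal(nrow(seg$jitter$micromovements), 1)
  expect_equal(nrow(seg$jitter$visits), 1)
  expect_equal(nrow(seg$split_visit$visits), 2)
  expect_equal(nrow(seg$merge_visit$visits), 1)
  lat <- latency_to_first_long_visit(seg$latency$visits, fx$latency$track)
  expect_false(lat$censored)
  expect_equal(lat$latency_s, 600)
  for (nm in c("excursion17", "revisit12", "adjacent10")) {
    tr <- classify_transitions(seg[[nm]]$visits, fx[[nm]]$track, fx[[nm]]$arena)
    expect_equal(nrow(tr$transitions), 1)
    expect_equal(tr$transitions$class, fx[[nm]]$expected$class)
  }
})

test_that("micromovement requires both the label and the 2.5 mm radius", {
  a <- arena(data.frame(id = 1, x = 0, y = 0, radius = 1.5,
                        substrate = "yeast"))
  n <- 200
  mk <- function(dist_mm, hsw) {
    head <- cbind(rep(dist_mm, n), 0)
    tr <- as_smooth_track(head, head_speed_walk = rep(hsw, n),
                          head_speed_rest = rep(1, n))
    segment_events(tr, a, labels = classify_activity(tr))
  }
  expect_equal(nrow(mk(2.0, 1)$micromovements), 1)   # micromovement at 2.0 mm
  expect_equal(nrow(mk(2.0, 3)$micromovements), 0)   # walking: label gate
  expect_equal(nrow(mk(2.6, 1)$micromovements), 0)   # outside 2.5 mm
  expect_equal(nrow(mk(2.6, 1)$encounters), 1)       # ... but encountered
})

test_that("latency handles censoring and qualifying-visit selection", {
  a <- arena(data.frame(id = 1, x = 0, y = 0, radius = 1.5,
                        substrate = "yeast"))
  fps <- 50
  # 45 s visit starting at 100 s
  n <- 200 * fps
  hsw <- rep(3, n); x <- rep(10, n)
  vis <- (100 * fps + 1):(145 * fps)
  hsw[vis] <- 1; x[vis] <- 1.5
  tr <- as_smooth_track(cbind(x, 0), head_speed_walk = hsw,
                        head_speed_rest = rep(1, n))
  seg <- segment_events(tr, a, labels = classify_activity(tr))
  lat <- latency_to_first_long_visit(seg$visits, tr)
  expect_equal(lat$latency_s, 100)
  expect_false(lat$censored)
  # all visits < 30 s: censored at assay end
  hsw <- rep(3, n); x <- rep(10, n)
  vis <- (50 * fps + 1):(60 * fps)
  hsw[vis] <- 1; x[vis] <- 1.5
  tr <- as_smooth_track(cbind(x, 0), head_speed_walk = hsw,
                        head_speed_rest = rep(1, n))
  seg <- segment_events(tr, a, labels = classify_activity(tr))
  lat <- latency_to_first_long_visit(seg$visits, tr)
  expect_true(lat$censored)
  expect_equal(lat$latency_s, n / fps)
})

test_that("segmentation equals the brute-force oracle on random tracks", {
  for (s in 1:30) {
    x <- random_oracle_track(n = 600, seed = 1000 + s)
    labels <- classify_activity(x$track)
    seg <- segment_events(x$track, x$arena, labels = labels)
    orc <- oracle_segment_patch(x$track$head, as.character(labels$label),
                                c(0, 0))
    expect_equal(cbind(seg$encounters$start, seg$encounters$end),
                 unname(orc$encounters), ignore_attr = TRUE)
    expect_equal(cbind(seg$micromovements$start, seg$micromovements$end),
                 unname(orc$micromovements), ignore_attr = TRUE)
    expect_equal(cbind(seg$visits$start, seg$visits$end),
                 unname(orc$visits), ignore_attr = TRUE)
  }
})

test_that("containment invariants: visits within encounters, durations nest", {
  for (s in 1:4) {
    x <- sim_small(seed = 30 + s, dur = 300)
    seg <- segment_events(x$track, x$arena)
    v <- seg$visits; e <- seg$encounters; m <- seg$micromovements
    # every visit has a containing encounter on the same patch
    for (i in seq_len(nrow(v))) {
      expect_true(any(e$patch_id == v$patch_id[i] &
                      e$start <= v$start[i] & e$end >= v$end[i]))
    }
    for (pid in unique(v$patch_id))
      expect_lte(sum(v$patch_id == pid), sum(e$patch_id == pid))
    # each micromovement lies inside an encounter of its patch
    for (i in seq_len(nrow(m)))
      expect_true(any(e$patch_id == m$patch_id[i] &
                      e$start <= m$start[i] & e$end >= m$end[i]))
    # visit duration >= contained micromovement duration per substrate
    for (sub in c("yeast", "sucrose"))
      expect_gte(sum(v$duration_s[v$substrate == sub]),
                 sum(m$duration_s[m$substrate == sub]))
    # intervals within one patch's list are disjoint and ordered
    for (tab in list(v, e, m)) for (pid in unique(tab$patch_id)) {
      tt <- tab[tab$patch_id == pid, ]
      tt <- tt[order(tt$start), ]
      if (nrow(tt) > 1) expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
    }
  }
})

test_that("event tables ignore appended far-away walking frames (locality)", {
  x <- random_oracle_track(n = 500, seed = 77)
  labels <- classify_activity(x$track)
  seg1 <- segment_events(x$track, x$arena, labels = labels)
  # append 100 walking frames > 5 mm from the patch
  far <- cbind(seq(7, 12, length.out = 100), 7)
  head2 <- rbind(x$track$head, far)
  tr2 <- as_smooth_track(head2, fps = 50,
                         head_speed_walk = c(x$track$head_speed_walk, rep(3, 100)),
                         head_speed_rest = c(x$track$head_speed_rest, rep(3, 100)))
  seg2 <- segment_events(tr2, x$arena, labels = classify_activity(tr2))
  expect_equal(seg1$encounters[c("start", "end")],
               seg2$encounters[c("start", "end")])
  expect_equal(seg1$visits[c("start", "end")], seg2$visits[c("start", "end")])
})
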