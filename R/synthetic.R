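#' Parameters of the synthetic forager
#'
#' A semi-Markov forager: activity bouts (rest / micromovement / walk)
#' with correlated-random-walk movement, patch targeting governed by a
#' revisit bias and a distance kernel, stop decisions at patch approach,
#' and visit termination by a constant leaving hazard. Speeds are chosen
#' so that the generated tracks land in the classifier's three speed
#' bands after smoothing.
#'
#' @param speed_walk mean walking speed, mm/s.
#' @param speed_micro mean on-patch micromovement speed, mm/s.
#' @param rest_jitter_mm per-frame positional jitter while resting, mm.
#' @param p_stop_yeast,p_stop_sucrose probability that an encounter with
#'   a patch of that substrate yields a stop (a visit).
#' @param leave_rate hazard of ending a visit, 1/s (mean visit duration
#'   is 1/leave_rate).
#' @param revisit_bias probability that the patch targeted after a visit
#'   is the patch just left.
#' @param local_range distance-kernel scale (mm) for choosing the next
#'   target patch; small values favour nearby (adjacent) patches.
#' @param micro_turn_sd_deg per-frame heading sd during on-patch
#'   micromovement, degrees; controls on-patch angular speed.
#' @param activity fraction of a visit spent micromoving (the rest is
#'   brief on-patch rest).
#' @param pivot_prob probability of a sharp pivot before a transit.
#' @param offpatch_micro_prob,offpatch_rest_prob per-transit probability
#'   of an off-patch micromovement (grooming-like) or rest bout.
#' @return a validated list of class `forager_params`.
#' @export
forager_params <- function(speed_walk = 10, speed_micro = 0.8,
                           rest_jitter_mm = 0.002,
                           p_stop_yeast = 0.5, p_stop_sucrose = 0.35,
                           leave_rate = 0.1, revisit_bias = 0.15,
                           local_range = 20, micro_turn_sd_deg = 4,
                           activity = 0.8, pivot_prob = 0.25,
                           offpatch_micro_prob = 0.08,
                           offpatch_rest_prob = 0.06) {
  p <- list(speed_walk = speed_walk, speed_micro = speed_micro,
            rest_jitter_mm = rest_jitter_mm,
            p_stop_yeast = p_stop_yeast, p_stop_sucrose = p_stop_sucrose,
            leave_rate = leave_rate, revisit_bias = revisit_bias,
            local_range = local_range,
            micro_turn_sd_deg = micro_turn_sd_deg, activity = activity,
            pivot_prob = pivot_prob,
            offpatch_micro_prob = offpatch_micro_prob,
            offpatch_rest_prob = offpatch_rest_prob)
  probs <- c(p$p_stop_yeast, p$p_stop_sucrose, p$revisit_bias, p$activity,
             p$pivot_prob, p$offpatch_micro_prob, p$offpatch_rest_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (p$leave_rate <= 0 || p$local_range <= 0 ||
      p$speed_walk <= 0 || p$speed_micro <= 0)
    stop("rates, ranges and speeds must be > 0")
  structure(p, class = "forager_params")
}

unit_vec <- function(theta) c(cos(theta), sin(theta))

# direction of per-frame displacement, carried forward across tiny steps
heading_from_path <- function(xy, h0) {
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  h <- atan2(dy, dx)
  small <- (dx^2 + dy^2) < 1e-10
  h[small] <- NA
  h <- c(h, NA)
  if (is.na(h[1])) h[1] <- h0
  filled <- !is.na(h)
  if (!all(filled))
    h <- stats::approx(which(filled), h[filled], xout = seq_along(h),
                       method = "constant", rule = 2)$y
  h
}

# straight-ish walk leg from `from` (exclusive) to `to` (inclusive)
seg_walk <- function(from, to, speed, fps, curve_amp = 0) {
  d <- sqrt(sum((to - from)^2))
  n <- max(1L, as.integer(round(d / speed * fps)))
  t <- seq_len(n) / n
  base <- cbind(from[1] + t * (to[1] - from[1]),
                from[2] + t * (to[2] - from[2]))
  if (curve_amp != 0 && d > 1e-9) {
    perp <- c(-(to[2] - from[2]), to[1] - from[1]) / d
    off <- curve_amp * sin(pi * t)
    base <- base + cbind(off * perp[1], off * perp[2])
  }
  base
}

# on-patch (or in-place) correlated wander within `rmax` of `center`
seg_micro <- function(start, center, n, speed, turn_sd_deg, fps,
                      heading0, rmax = 2.0) {
  out <- matrix(0, n, 2)
  cur <- start
  heading <- heading0
  i <- 1L
  step <- speed / fps
  while (i <= n) {
    nb <- min(30L, n - i + 1L)
    rel <- cur - center
    r <- sqrt(sum(rel^2))
    base <- if (r > rmax - 0.4) {
      atan2(-rel[2], -rel[1]) + stats::rnorm(1, 0, 0.5)
    } else heading + stats::rnorm(1, 0, 0.8)
    h <- base + cumsum(stats::rnorm(nb, 0, turn_sd_deg * pi / 180))
    xs <- cur[1] + cumsum(step * cos(h))
    ys <- cur[2] + cumsum(step * sin(h))
    out[i:(i + nb - 1L), ] <- cbind(xs, ys)
    cur <- c(xs[nb], ys[nb])
    heading <- h[nb]
    i <- i + nb
  }
  out
}

seg_rest <- function(pos, n, jitter_sd) {
  cbind(pos[1] + stats::rnorm(n, 0, jitter_sd),
        pos[2] + stats::rnorm(n, 0, jitter_sd))
}

# pivot in place: body centroid fixed, head sweeps an arc
seg_pivot <- function(pos, heading0, fps, angle_deg, omega_deg_s) {
  n <- max(2L, as.integer(round(abs(angle_deg) / omega_deg_s * fps)))
  body_c <- pos - 1.25 * unit_vec(heading0)
  h <- heading0 + sign(angle_deg) * seq_len(n) / n * abs(angle_deg) * pi / 180
  list(head = cbind(body_c[1] + 1.25 * cos(h), body_c[2] + 1.25 * sin(h)),
       heading_end = h[n])
}

# waypoints so a straight leg keeps clearance from non-target patches
route_waypoints <- function(from, to, a, ignore_id, clearance = 4.5) {
  d <- to - from
  len2 <- sum(d^2)
  if (len2 < 1e-12) return(list())
  wps <- list()
  for (k in seq_len(nrow(a$patches))) {
    if (a$patches$id[k] %in% ignore_id) next
    ctr <- c(a$patches$x[k], a$patches$y[k])
    t <- sum((ctr - from) * d) / len2
    if (t <= 0.02 || t >= 0.98) next
    foot <- from + t * d
    away <- foot - ctr
    dist <- sqrt(sum(away^2))
    if (dist < clearance) {
      dir <- if (dist > 1e-9) away / dist else
        c(-d[2], d[1]) / sqrt(len2)
      wp <- ctr + (clearance + 0.5) * dir
      # detour must stay inside the arena wall; flip inward if not
      if (sqrt(sum(wp^2)) > 23.5) wp <- ctr - (clearance + 0.5) * dir
      wps[[length(wps) + 1L]] <- list(t = t, p = wp)
    }
  }
  if (!length(wps)) return(list())
  wps[order(vapply(wps, function(w) w$t, 0))]
}

#' Simulate one foraging fly
#'
#' Generates a 50 fps head/body/tail trajectory in the arena together
#' with a ground-truth log of intended encounters, stop decisions and
#' visits, and per-frame intended activity labels. Deterministic given
#' `seed`.
#'
#' @param params a [forager_params()].
#' @param a a `forage_arena`.
#' @param duration_s assay duration, s.
#' @param fps frames per second.
#' @param seed integer seed.
#' @return list with `track` (a `forage_track`, mm units) and `truth`
#'   (list: `labels` character per frame, `encounters` data.frame
#'   (`patch_id`, `frame`, `stopped`), `visits` data.frame (`patch_id`,
#'   `start`, `end` half-open 1-based frames)).
#' @export
simulate_fly <- function(params, a, duration_s = 7200, fps = 50, seed = 1) {
  stopifnot(inherits(params, "forager_params"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n_total <- as.integer(round(duration_s * fps))
  pxy <- as.matrix(a$patches[, c("x", "y")])
  p_stop <- c(yeast = params$p_stop_yeast, sucrose = params$p_stop_sucrose)

  heads <- list(); headings <- list(); labs <- list()
  n_done <- 0L
  enc_patch <- integer(0); enc_frame <- integer(0); enc_stop <- logical(0)
  vis_patch <- integer(0); vis_start <- integer(0); vis_end <- integer(0)

  # start away from patches
  repeat {
    cur <- stats::runif(2, -15, 15)
    if (min(distances_to_patches(cur, a)) > 5 && sqrt(sum(cur^2)) < 20) break
  }
  heading <- stats::runif(1, -pi, pi)
  last_patch <- NA_integer_

  push <- function(xy, h, label) {
    heads[[length(heads) + 1L]] <<- xy
    headings[[length(headings) + 1L]] <<-
      if (length(h) == nrow(xy)) h else rep(h[1], nrow(xy))
    labs[[length(labs) + 1L]] <<- rep(label, nrow(xy))
    n_done <<- n_done + nrow(xy)
  }

  far_from_patches <- function(p, min_d = 5)
    min(distances_to_patches(p, a)) > min_d

  guard <- 0L
  while (n_done < n_total && guard < 500000L) {
    guard <- guard + 1L

    # occasional off-patch bout (only well away from any patch)
    if (far_from_patches(cur)) {
      u <- stats::runif(1)
      if (u < params$offpatch_rest_prob) {
        n <- as.integer(stats::runif(1, 2, 15) * fps)
        push(seg_rest(cur, n, params$rest_jitter_mm), heading, "rest")
      } else if (u < params$offpatch_rest_prob + params$offpatch_micro_prob) {
        n <- as.integer(stats::runif(1, 2, 6) * fps)
        xy <- seg_micro(cur, cur, n, params$speed_micro,
                        params$micro_turn_sd_deg, fps, heading, rmax = 1.2)
        push(xy, heading_from_path(xy, heading), "micromovement")
        cur <- xy[nrow(xy), ]
      }
    }
    if (n_done >= n_total) break

    # choose target patch
    if (!is.na(last_patch) && stats::runif(1) < params$revisit_bias) {
      tgt <- match(last_patch, a$patches$id)
    } else {
      cand <- which(!(a$patches$id %in% last_patch))
      d <- sqrt((pxy[cand, 1] - cur[1])^2 + (pxy[cand, 2] - cur[2])^2)
      w <- exp(-d / params$local_range)
      tgt <- cand[sample.int(length(cand), 1, prob = w)]
    }
    ctr <- pxy[tgt, ]
    substrate <- a$patches$substrate[tgt]
    stop_dec <- stats::runif(1) < p_stop[[substrate]]

    # optional pivot before setting off
    if (stats::runif(1) < params$pivot_prob) {
      pv <- seg_pivot(cur, heading, fps,
                      angle_deg = sample(c(-1, 1), 1) * stats::runif(1, 90, 180),
                      omega_deg_s = stats::runif(1, 160, 300))
      push(pv$head, heading_from_path(pv$head, heading), "walk")
      heading <- pv$heading_end
      cur <- pv$head[nrow(pv$head), ]
    }

    # aim point on/near the target patch
    appr <- cur - ctr
    appr_th <- atan2(appr[2], appr[1])
    if (stop_dec) {
      aim <- ctr + stats::runif(1, 0.5, 1.5) *
        unit_vec(appr_th + stats::rnorm(1, 0, 0.5))
    } else {
      aim <- ctr + stats::runif(1, 0.8, 2.2) *
        unit_vec(appr_th + pi / 2 * sample(c(-1, 1), 1))
    }

    # walk there, detouring around other patches
    pts <- route_waypoints(cur, aim, a, ignore_id = a$patches$id[tgt])
    legs <- c(lapply(pts, function(w) w$p), list(aim))
    enc_logged <- FALSE
    from <- cur
    speed <- params$speed_walk * stats::runif(1, 0.85, 1.15)
    for (lg in legs) {
      amp <- min(1.0, 0.08 * sqrt(sum((lg - from)^2))) *
        sample(c(-1, 1), 1) * stats::runif(1)
      xy <- seg_walk(from, lg, speed, fps, curve_amp = amp)
      n0 <- n_done
      push(xy, heading_from_path(xy, heading), "walk")
      if (!enc_logged) {
        dtg <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
        hit <- which(dtg <= 3)
        if (length(hit)) {
          enc_patch <- c(enc_patch, a$patches$id[tgt])
          enc_frame <- c(enc_frame, n0 + hit[1])
          enc_stop <- c(enc_stop, stop_dec)
          enc_logged <- TRUE
        }
      }
      from <- lg
    }
    cur <- aim
    heading <- atan2(aim[2] - ctr[2], aim[1] - ctr[1])

    if (stop_dec && n_done < n_total) {
      # visit: alternating micromovement and brief rest on the patch
      dur_s <- max(2, stats::rexp(1, params$leave_rate))
      n_vis <- as.integer(min(dur_s * fps, n_total - n_done))
      v0 <- n_done + 1L
      left <- n_vis
      while (left > 0L) {
        nm <- as.integer(min(left, stats::runif(1, 2, 6) * fps))
        xy <- seg_micro(cur, ctr, nm, params$speed_micro,
                        params$micro_turn_sd_deg, fps, heading, rmax = 2.0)
        push(xy, heading_from_path(xy, heading), "micromovement")
        cur <- xy[nrow(xy), ]
        left <- left - nm
        if (left > 0L && stats::runif(1) < (1 - params$activity)) {
          nr <- as.integer(min(left, stats::runif(1, 0.5, 2.5) * fps))
          push(seg_rest(cur, nr, params$rest_jitter_mm), heading, "rest")
          left <- left - nr
        }
      }
      vis_patch <- c(vis_patch, a$patches$id[tgt])
      vis_start <- c(vis_start, v0)
      vis_end <- c(vis_end, n_done + 1L)
      last_patch <- a$patches$id[tgt]
      # leave: exit point clear of every patch, inside the wall
      exit <- NULL
      for (try in 1:40) {
        cand <- ctr + stats::runif(1, 6, 9) *
          unit_vec(stats::runif(1, -pi, pi))
        if (sqrt(sum(cand^2)) < 23 && far_from_patches(cand, 5)) {
          exit <- cand; break
        }
      }
      if (is.null(exit)) exit <- ctr + 7 * unit_vec(atan2(-ctr[2], -ctr[1]))
      xy <- seg_walk(cur, exit, params$speed_walk, fps, curve_amp = 0)
      push(xy, heading_from_path(xy, heading), "walk")
      cur <- exit
    } else {
      # pass through: continue beyond the patch without stopping;
      # prefer the far side of the approach, widen the angle if the far
      # side leaves the wall or lands on another patch
      exit <- NULL
      for (try in 1:40) {
        ang <- if (try <= 20) appr_th + pi + stats::rnorm(1, 0, 0.6)
               else stats::runif(1, -pi, pi)
        cand <- ctr + stats::runif(1, 6, 10) * unit_vec(ang)
        if (sqrt(sum(cand^2)) < 23 && far_from_patches(cand, 5)) {
          exit <- cand; break
        }
      }
      if (is.null(exit)) exit <- ctr + 7 * unit_vec(atan2(-ctr[2], -ctr[1]))
      xy <- seg_walk(cur, exit, speed, fps, curve_amp = 0)
      push(xy, heading_from_path(xy, heading), "walk")
      cur <- exit
    }
    if (nrow(xy <- heads[[length(heads)]]) > 0)
      heading <- heading_from_path(xy, heading)[nrow(xy)]
  }

  head <- do.call(rbind, heads)[seq_len(n_total), , drop = FALSE]
  hvec <- do.call(c, headings)[seq_len(n_total)]
  lab <- do.call(c, labs)[seq_len(n_total)]
  u <- cbind(cos(hvec), sin(hvec))
  body <- head - 1.25 * u
  tail <- head - 2.5 * u
  keep <- vis_start <= n_total
  vis_end <- pmin(vis_end[keep], n_total + 1L)
  truth <- list(
    labels = lab,
    encounters = data.frame(patch_id = enc_patch, frame = enc_frame,
                            stopped = enc_stop)[enc_frame <= n_total, ],
    visits = data.frame(patch_id = vis_patch[keep],
                        start = vis_start[keep], end = vis_end),
    params = params, seed = seed)
  list(track = raw_track(0:(n_total - 1L), head, body, tail,
                         units = "mm", fps = fps),
       truth = truth)
}

#' Named parameter presets for the five internal states
#'
#' Parameter bundles for virgin/mated females on rich, suboptimal or
#' AA-free pre-assay diets. Values are documented constants chosen to
#' reproduce the qualitative orderings only: exploitation (stop
#' probability, visit duration, on-patch activity) rises and global
#' exploration (distant transitions, transit range) falls with mating
#' and amino-acid challenge.
#'
#' @return named list of `forager_params`: `virgin_rich`,
#'   `virgin_suboptimal`, `mated_rich`, `mated_suboptimal`,
#'   `mated_deprived`.
#' @export
make_presets <- function() {
  # sucrose stopping falls with amino-acid challenge: the compensation
  # is yeast-specific, so challenged presets interrupt their yeast-to-
  # yeast runs with fewer sucrose visits
  list(
    virgin_rich = forager_params(
      p_stop_yeast = 0.20, p_stop_sucrose = 0.50, leave_rate = 0.25,
      revisit_bias = 0.02, local_range = 40, activity = 0.60,
      micro_turn_sd_deg = 3),
    virgin_suboptimal = forager_params(
      p_stop_yeast = 0.30, p_stop_sucrose = 0.45, leave_rate = 0.15,
      revisit_bias = 0.05, local_range = 35, activity = 0.65,
      micro_turn_sd_deg = 3.5),
    mated_rich = forager_params(
      p_stop_yeast = 0.35, p_stop_sucrose = 0.40, leave_rate = 0.10,
      revisit_bias = 0.05, local_range = 40, activity = 0.70,
      micro_turn_sd_deg = 3.5),
    mated_suboptimal = forager_params(
      p_stop_yeast = 0.75, p_stop_sucrose = 0.30, leave_rate = 0.055,
      revisit_bias = 0.25, local_range = 12, activity = 0.75,
      micro_turn_sd_deg = 4),
    mated_deprived = forager_params(
      p_stop_yeast = 0.80, p_stop_sucrose = 0.15, leave_rate = 0.050,
      revisit_bias = 0.40, local_range = 6, activity = 0.90,
      micro_turn_sd_deg = 6))
}

#' Deterministic handcrafted event-rule fixtures
#'
#' Small tracks encoding the edge cases of the event rules, each with
#' hand-derived expected outputs. Tracks are supplied at the
#' smoothed-channel level (via [as_smooth_track()]) with explicitly
#' chosen classifier channels, so the expected event tables can be
#' walked by hand without chasing filter transients.
#'
#' @return named list of fixtures; each has `track` (`forage_smooth`),
#'   `arena`, `labels` (`forage_ethogram`), and `expected` (named list).
#' @export
fixture_suite <- function() {
  fps <- 50
  mini_arena <- arena(data.frame(id = 1, x = 0, y = 0, radius = 1.5,
                                 substrate = "yeast"),
                      inner_radius = 25)
  yy_arena <- arena(data.frame(id = 1:2, x = c(0, 10), y = c(0, 0),
                               radius = 1.5,
                               substrate = c("yeast", "yeast")),
                    inner_radius = 25)
  # channels: walk -> hsw 3; micromovement -> hsw 1, hsr 1; rest -> 0.05
  mk <- function(x, y, hsw, hsr) {
    tr <- as_smooth_track(cbind(x, y), fps = fps,
                          head_speed_walk = hsw, head_speed_rest = hsr)
    list(track = tr, labels = classify_activity(tr))
  }
  fx <- list()

  # one dip to 2.9 mm, retreat to 8 mm: exactly one encounter, no visit
  x <- c(seq(8, 2.9, length.out = 100), seq(2.9, 8, length.out = 100))
  f <- mk(x, rep(0, 200), rep(3, 200), rep(3, 200))
  fx$graze <- c(f, list(arena = mini_arena,
                        expected = list(n_encounters = 1, n_visits = 0)))

  # two 3 mm crossings separated by an excursion to 4 mm: merged by the
  # 5 mm rule into one encounter
  x <- c(seq(8, 2.5, length.out = 80), seq(2.5, 4, length.out = 40),
         seq(4, 2.5, length.out = 40), seq(2.5, 8, length.out = 80))
  f <- mk(x, rep(0, 240), rep(3, 240), rep(3, 240))
  fx$excursion4 <- c(f, list(arena = mini_arena,
                             expected = list(n_encounters = 1)))

  # same but excursion to 6 mm with real displacement: two encounters
  x <- c(seq(8, 2.5, length.out = 80), seq(2.5, 6, length.out = 60),
         seq(6, 2.5, length.out = 60), seq(2.5, 8, length.out = 80))
  f <- mk(x, rep(0, 280), rep(3, 280), rep(3, 280))
  fx$excursion6 <- c(f, list(arena = mini_arena,
                             expected = list(n_encounters = 2)))

  # micromovement interrupted by walk-labeled frames while the head is
  # stationary (< 0.31 mm): merged by the 2-px rule into one event
  n1 <- 100; n2 <- 50; n3 <- 100
  x <- c(rep(2.0, n1), rep(2.05, n2), rep(2.0, n3))
  hsw <- c(rep(1, n1), rep(3, n2), rep(1, n3))
  f <- mk(x, rep(0, n1 + n2 + n3), hsw, rep(1, n1 + n2 + n3))
  fx$jitter <- c(f, list(arena = mini_arena,
                         expected = list(n_micromovements = 1, n_visits = 1)))

  # two micromovement bouts, gap excursion to 6 mm: two visits
  x <- c(rep(2.0, 150), seq(2, 6, length.out = 60),
         seq(6, 2, length.out = 60), rep(2.0, 150))
  hsw <- c(rep(1, 150), rep(3, 120), rep(1, 150))
  f <- mk(x, rep(0, 420), hsw, rep(1, 420))
  fx$split_visit <- c(f, list(arena = mini_arena,
                              expected = list(n_visits = 2)))

  # same but excursion only to 4.5 mm: one visit
  x <- c(rep(2.0, 150), seq(2, 4.5, length.out = 60),
         seq(4.5, 2, length.out = 60), rep(2.0, 150))
  hsw <- c(rep(1, 150), rep(3, 120), rep(1, 150))
  f <- mk(x, rep(0, 420), hsw, rep(1, 420))
  fx$merge_visit <- c(f, list(arena = mini_arena,
                              expected = list(n_visits = 1)))

  # visits 10 s (t = 50 s) and 31 s (t = 600 s): latency 600 s; the fly
  # keeps moving far from the patch in between (no 2-px merge)
  pre1 <- 50 * fps; v1 <- 10 * fps
  gap <- (600 - 60) * fps; v2 <- 31 * fps; post <- 5 * fps
  wander <- function(n) 12 + 3 * sin(seq_len(n) / 25)
  x <- c(wander(pre1), rep(2, v1), wander(gap), rep(2, v2), wander(post))
  n <- length(x)
  hsw <- c(rep(3, pre1), rep(1, v1), rep(3, gap), rep(1, v2), rep(3, post))
  f <- mk(x, rep(0, n), hsw, rep(1, n))
  fx$latency <- c(f, list(arena = mini_arena,
                          expected = list(latency_s = 600)))

  # same-patch revisit with a 17 mm excursion: transition distant
  mk_transition <- function(peak, arena2, to_x = 0) {
    x <- c(rep(1.5, 100), seq(1.5, peak, length.out = 80),
           seq(peak, to_x + 1.5, length.out = 80), rep(to_x + 1.5, 100))
    n <- length(x)
    hsw <- c(rep(1, 100), rep(3, 160), rep(1, 100))
    mk(x, rep(0, n), hsw, rep(1, n))
  }
  f <- mk_transition(17, yy_arena, to_x = 0)
  fx$excursion17 <- c(f, list(arena = yy_arena,
                              expected = list(class = "distant")))
  # revisit with max excursion 12 mm: same
  f <- mk_transition(12, yy_arena, to_x = 0)
  fx$revisit12 <- c(f, list(arena = yy_arena,
                            expected = list(class = "same")))
  # transition to a patch 10 mm away staying within 16 mm: adjacent
  f <- mk_transition(5, yy_arena, to_x = 10)
  fx$adjacent10 <- c(f, list(arena = yy_arena,
                             expected = list(class = "adjacent")))
  fx
}
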