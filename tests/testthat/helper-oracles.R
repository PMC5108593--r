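# Independent brute-force oracles: literal frame-by-frame transcriptions
# of the classification and segmentation rules, kept deliberately naive.

# literal per-frame activity classification
oracle_classify <- function(hsw, hsr, walk_min = 2, rest_max = 0.2) {
  n <- length(hsw)
  out <- character(n)
  for (i in seq_len(n)) {
    if (hsw[i] > walk_min) out[i] <- "walk"
    else if (hsr[i] <= rest_max) out[i] <- "rest"
    else out[i] <- "micromovement"
  }
  out
}

# scan a logical frame mask into 1-based half-open [start, end) intervals
oracle_runs <- function(mask) {
  iv <- NULL
  open <- FALSE
  s <- 0L
  for (i in seq_along(mask)) {
    if (mask[i] && !open) { open <- TRUE; s <- i }
    if (!mask[i] && open) { open <- FALSE; iv <- rbind(iv, c(s, i)) }
  }
  if (open) iv <- rbind(iv, c(s, length(mask) + 1L))
  if (is.null(iv)) matrix(integer(0), 0, 2) else iv
}

oracle_gap_stationary <- function(head, gs, ge, tol) {
  ref <- head[gs, ]
  for (i in gs:ge) {
    if (sqrt(sum((head[i, ] - ref)^2)) > tol) return(FALSE)
  }
  TRUE
}

oracle_merge <- function(iv, ok_gap) {
  repeat {
    if (nrow(iv) <= 1) return(iv)
    changed <- FALSE
    i <- 1L
    while (i < nrow(iv)) {
      if (ok_gap(iv[i, 2], iv[i + 1, 1] - 1L)) {
        iv[i, 2] <- iv[i + 1, 2]
        iv <- iv[-(i + 1), , drop = FALSE]
        changed <- TRUE
      } else i <- i + 1L
    }
    if (!changed) return(iv)
  }
}

# full event segmentation for one patch, rules applied literally
oracle_segment_patch <- function(head, labels, ctr, enc_r = 3, mic_r = 2.5,
                                 merge_r = 5, disp = 0.31) {
  d <- sqrt((head[, 1] - ctr[1])^2 + (head[, 2] - ctr[2])^2)
  enc <- oracle_runs(d <= enc_r)
  enc <- oracle_merge(enc, function(gs, ge) {
    oracle_gap_stationary(head, gs, ge, disp) || all(d[gs:ge] <= merge_r)
  })
  mic <- oracle_runs(labels == "micromovement" & d <= mic_r)
  mic <- oracle_merge(mic, function(gs, ge)
    oracle_gap_stationary(head, gs, ge, disp))
  vis <- oracle_merge(mic, function(gs, ge) all(d[gs:ge] <= merge_r))
  list(encounters = enc, micromovements = mic, visits = vis)
}

# random smooth-level track: wandering head near a patch with stationary
# stretches and label channels that cross every threshold
random_oracle_track <- function(n = 800, seed = 1) {
  set.seed(seed)
  a <- arena(data.frame(id = 1L, x = 0, y = 0, radius = 1.5,
                        substrate = "yeast"))
  pos <- matrix(0, n, 2)
  cur <- stats::runif(2, -4, 4)
  i <- 1L
  while (i <= n) {
    mode <- sample(c("move", "still", "drift"), 1,
                   prob = c(0.5, 0.3, 0.2))
    len <- min(n - i + 1L, sample(10:80, 1))
    if (mode == "still") {
      step <- matrix(stats::rnorm(len * 2, 0, 0.02), len, 2)
    } else if (mode == "drift") {
      dir <- stats::runif(1, -pi, pi)
      step <- cbind(stats::rnorm(len, 0.25 * cos(dir), 0.05),
                    stats::rnorm(len, 0.25 * sin(dir), 0.05))
    } else {
      step <- matrix(stats::rnorm(len * 2, 0, 0.3), len, 2)
    }
    xy <- cbind(cur[1] + cumsum(step[, 1]), cur[2] + cumsum(step[, 2]))
    r <- sqrt(rowSums(xy^2))
    xy[r > 8, ] <- xy[r > 8, ] * (8 / r[r > 8])
    pos[i:(i + len - 1L), ] <- xy
    cur <- xy[len, ]
    i <- i + len
  }
  hsw <- pmax(0, stats::filter(stats::runif(n, 0, 4), rep(1 / 9, 9),
                               circular = TRUE))
  hsr <- pmax(0, hsw + stats::rnorm(n, 0, 0.3))
  tr <- as_smooth_track(pos, fps = 50, head_speed_walk = as.numeric(hsw),
                        head_speed_rest = as.numeric(hsr))
  list(track = tr, arena = a)
}

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c2 + d; k <- a + c2
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small simulated fly shared across tests
sim_small <- function(seed = 1, dur = 600, params = forager_params()) {
  a <- build_standard_arena()
  sim <- simulate_fly(params, a, duration_s = dur, seed = seed)
  tr <- smooth_track(sim$track)
  list(arena = a, sim = sim, track = tr)
}
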