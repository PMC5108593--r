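test_that("gaussian_smooth: normalization, impulse, monotone attenuation", {
  expect_equal(gaussian_smooth(rep(3.7, 200), 0.32, 50), rep(3.7, 200))
  # unit impulse: kernel weights, summing to 1
  imp <- c(rep(0, 100), 1, rep(0, 100))
  sm <- gaussian_smooth(imp, 0.32, 50)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(which.max(sm), 101)
  # sinusoid amplitude shrinks monotonically with filter width
  t <- seq(0, 4, by = 0.02)
  x <- sin(2 * pi * 1.5 * t)
  amp <- sapply(c(0.32, 1.2, 2.4), function(w)
    max(abs(gaussian_smooth(x, w, 50)[50:150])))
  expect_true(all(diff(amp) < 0))
  expect_error(gaussian_smooth(numeric(0), 0.32, 50))
})

test_that("compute_speed matches hand values and a naive oracle", {
  # 0.04 mm per frame at 50 fps -> 2 mm/s
  xy <- cbind(seq(0, by = 0.04, length.out = 10), 0)
  expect_equal(compute_speed(xy, 50), rep(2, 10))
  expect_equal(compute_speed(cbind(rep(1, 5), rep(2, 5)), 50), rep(0, 5))
  set.seed(11)
  xy <- matrix(cumsum(rnorm(200, 0, 0.1)), 100, 2)
  sp <- compute_speed(xy, 50)
  naive <- sapply(1:99, function(i) sqrt(sum((xy[i + 1, ] - xy[i, ])^2)) * 50)
  expect_equal(sp[1:99], naive)
  expect_equal(sp[100], naive[99])
})

test_that("angular speed: constant heading, wraparound, circular walking", {
  n <- 50
  head <- cbind(seq_len(n), 0); tail <- cbind(seq_len(n) - 1, 0)
  expect_equal(compute_angular_speed(head, tail, 50), rep(0, n))
  # 179 deg then -179 deg: shortest arc +2 deg -> +100 deg/s at 50 fps
  h <- rbind(c(cos(179 * pi / 180), sin(179 * pi / 180)),
             c(cos(-179 * pi / 180), sin(-179 * pi / 180)))
  expect_equal(compute_angular_speed(h, matrix(0, 2, 2), 50),
               c(100, 100), tolerance = 1e-9)
  # circle: 1 revolution / 12 s -> 30 deg/s
  fps <- 50; tt <- seq(0, 12, by = 1 / fps); th <- 2 * pi * tt / 12
  head <- cbind(10 * cos(th), 10 * sin(th))
  tail <- cbind(9.7 * cos(th - 0.02), 9.7 * sin(th - 0.02))
  av <- compute_angular_speed(head, tail, fps)
  expect_equal(mean(abs(av)), 30, tolerance = 0.01 * 30)
})

test_that("speed channels are invariant under rigid motions", {
  set.seed(5)
  xy <- matrix(cumsum(rnorm(400, 0, 0.2)), 200, 2)
  tail <- xy - 0.5
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy2 <- xy %*% R + matrix(c(5, -3), 200, 2, byrow = TRUE)
  tail2 <- tail %*% R + matrix(c(5, -3), 200, 2, byrow = TRUE)
  expect_equal(compute_speed(xy2, 50), compute_speed(xy, 50),
               tolerance = 1e-9)
  expect_equal(compute_angular_speed(xy2, tail2, 50),
               compute_angular_speed(xy, tail, 50), tolerance = 1e-6)
})

test_that("assign_head recovers ground truth on forward walks and flips bad seeds", {
  # forward walk with known head = leading endpoint
  n <- 300
  body <- cbind(seq(0, 30, length.out = n), 0)
  true_head <- body + matrix(c(1.25, 0), n, 2, byrow = TRUE)
  true_tail <- body - matrix(c(1.25, 0), n, 2, byrow = TRUE)
  set.seed(9)
  swap <- runif(n) < 0.5  # endpoints arrive in random order
  e1 <- ifelse(cbind(swap, swap), true_tail, true_head)
  e2 <- ifelse(cbind(swap, swap), true_head, true_tail)
  res <- assign_head(e1, e2, body)
  expect_equal(res$head, true_head)
  # adversarial seed: force backwards labeling, flip must correct it
  res2 <- assign_head(e1, e2, body, seed_head = true_tail[1, ])
  expect_equal(res2$head, true_head)
  # stationary fly: labels constant and flagged low-confidence
  bodyc <- matrix(1, 20, 2)
  r3 <- assign_head(bodyc + 0.5, bodyc - 0.5, bodyc)
  expect_true(all(r3$head[, 1] == r3$head[1, 1]))
  expect_true(any(r3$low_confidence))
})

test_that("lost-frame QC: boundary at exactly 10%", {
  mk <- function(n_lost, n = 200) {
    head <- cbind(seq_len(n) * 0.1, 0)
    if (n_lost > 0) head[sample(2:(n - 1), n_lost), ] <- NA
    raw_track(0:(n - 1), head, head)
  }
  set.seed(2)
  expect_true(qc_track(mk(0))$pass)
  expect_true(qc_track(mk(20))$pass)    # exactly 10%
  expect_false(qc_track(mk(22))$pass)   # 11%
})

test_that("smooth_track interpolates gaps and fills all channels", {
  n <- 500
  head <- cbind(seq(0, 10, length.out = n), sin(seq(0, 4, length.out = n)))
  head[100:104, ] <- NA
  tr <- smooth_track(raw_track(0:(n - 1), head, head - 0.02))
  expect_equal(tr$n, n)
  expect_true(all(is.finite(tr$head)))
  expect_true(all(tr$head_speed >= 0))
  expect_true(any(tr$gap_mask))
  for (ch in c("head_speed", "body_speed", "angular_speed",
               "head_speed_walk", "head_speed_rest", "body_speed_f"))
    expect_length(tr[[ch]], n)
})

test_that("px input is converted once at load", {
  n <- 100
  head_px <- cbind(seq_len(n), rep(50, n))
  raw <- raw_track(0:(n - 1), head_px, head_px, units = "px")
  tr <- smooth_track(raw, mm_per_px = 0.155)
  expect_equal(tr$head[50, 1], 50 * 0.155, tolerance = 1e-6)
})
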