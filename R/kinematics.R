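#' Gaussian smoothing of a per-frame series
#'
#' Linear filtering with a truncated, renormalized Gaussian kernel. The
#' `width_s` argument is the total kernel support in seconds; the kernel
#' spans `round(width_s * fps)` frames with sd = width/6 frames (so the
#' stated 16/60/120-frame filter widths are literal support, not sd). At
#' the series ends the kernel is renormalized over the available samples,
#' so constant series map to themselves everywhere.
#'
#' @param x numeric vector (one channel, one value per frame).
#' @param width_s kernel support in seconds (> 0).
#' @param fps frames per second.
#' @return smoothed numeric vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, width_s, fps) {
  if (length(x) == 0) stop("cannot smooth an empty series")
  stopifnot(width_s > 0, fps > 0)
  w <- max(1L, as.integer(round(width_s * fps)))
  half <- w %/% 2L
  if (half == 0L) return(x)
  k <- stats::dnorm(seq(-half, half), sd = w / 6)
  k <- k / sum(k)
  n <- length(x)
  if (n == 1L) return(x)
  # renormalize over available support: conv(x, k) / conv(1, k)
  num <- stats::convolve(c(rep(0, half), x, rep(0, half)), k, type = "filter")
  den <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), k, type = "filter")
  num / den
}

# smooth each column of an n x 2 position matrix
smooth_xy <- function(xy, width_s, fps) {
  cbind(gaussian_smooth(xy[, 1], width_s, fps),
        gaussian_smooth(xy[, 2], width_s, fps))
}

#' Translational speed from per-frame positions
#'
#' `speed[i] = |p[i+1] - p[i]| * fps`; the last frame replicates the
#' penultimate value so the channel keeps full length.
#'
#' @param xy n x 2 matrix of positions, mm.
#' @param fps frames per second.
#' @return numeric vector of speeds, mm/s.
#' @export
compute_speed <- function(xy, fps) {
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 frames to compute speed")
  step <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  c(step, step[n - 1]) * fps
}

#' Signed angular speed from head and tail positions
#'
#' The heading is the direction of the head-minus-tail vector; the
#' angular speed is the shortest-arc heading difference between
#' consecutive frames times fps, in degrees/s. Frames with coincident
#' head and tail carry the previous heading forward.
#'
#' @param head,tail n x 2 matrices, mm (smoothed centroids).
#' @param fps frames per second.
#' @return numeric vector, degrees/s, signed; positive = counterclockwise.
#' @export
compute_angular_speed <- function(head, tail, fps) {
  n <- nrow(head)
  if (n < 2) stop("need at least 2 frames")
  dx <- head[, 1] - tail[, 1]
  dy <- head[, 2] - tail[, 2]
  h <- atan2(dy, dx) * 180 / pi
  degen <- (dx == 0 & dy == 0)
  if (any(degen)) {
    for (i in which(degen)) h[i] <- if (i > 1) h[i - 1] else 0
  }
  d <- (diff(h) + 180) %% 360 - 180
  d[d == -180] <- 180   # shortest arc lands in (-180, 180]
  c(d, d[n - 1]) * fps
}

#' Disambiguate head vs tail from unlabeled body-axis endpoints
#'
#' Within each interval between jumps, per-frame identity is first
#' propagated by proximity to the previous head position; then the whole
#' interval's labeling is kept or globally flipped to maximize agreement
#' between the body axis direction and the direction of displacement
#' (flies walk forward most of the time).
#'
#' @param e1,e2 n x 2 matrices of the two unlabeled axis endpoints.
#' @param body n x 2 matrix of body centroid positions.
#' @param jump_frames integer vector of frame indices at which tracking
#'   jumped (interval boundaries); may be empty.
#' @param seed_head optional length-2 head position for frame 1; when
#'   `NULL` the first interval is seeded by net displacement direction.
#' @return list with `head` (n x 2), `tail` (n x 2), and `low_confidence`
#'   (logical, one per inter-jump interval with near-zero net displacement).
#' @export
assign_head <- function(e1, e2, body, jump_frames = integer(0), seed_head = NULL) {
  n <- nrow(e1)
  bounds <- sort(unique(c(1L, as.integer(jump_frames), n + 1L)))
  bounds <- bounds[bounds >= 1L & bounds <= n + 1L]
  if (bounds[1] != 1L) bounds <- c(1L, bounds)
  if (bounds[length(bounds)] != n + 1L) bounds <- c(bounds, n + 1L)
  take1 <- logical(n)  # TRUE -> head is e1
  lowconf <- logical(length(bounds) - 1L)
  for (iv in seq_len(length(bounds) - 1L)) {
    s <- bounds[iv]; e <- bounds[iv + 1L] - 1L
    idx <- s:e
    # seed frame choice
    if (iv == 1L && !is.null(seed_head)) {
      take1[s] <- sum((e1[s, ] - seed_head)^2) <= sum((e2[s, ] - seed_head)^2)
    } else {
      disp <- body[e, ] - body[s, ]
      if (sum(disp^2) < 1e-12) {
        take1[s] <- TRUE
        lowconf[iv] <- TRUE
      } else {
        take1[s] <- sum((e1[s, ] - body[s, ]) * disp) >=
                    sum((e2[s, ] - body[s, ]) * disp)
      }
    }
    # proximity propagation
    if (length(idx) > 1) {
      for (i in idx[-1]) {
        prev <- if (take1[i - 1]) e1[i - 1, ] else e2[i - 1, ]
        take1[i] <- sum((e1[i, ] - prev)^2) <= sum((e2[i, ] - prev)^2)
      }
    }
    # forward-walking correction: flip whole interval if that aligns
    # heading with displacement better
    hd <- ifelse(take1[idx], 1, -1)
    ax <- e1[idx, , drop = FALSE] - e2[idx, , drop = FALSE]
    axis_dir <- ax * hd
    dis <- rbind(diff(body[idx, , drop = FALSE]), c(0, 0))
    score <- sum(axis_dir[, 1] * dis[, 1] + axis_dir[, 2] * dis[, 2])
    if (score < 0) take1[idx] <- !take1[idx]
  }
  head <- unname(ifelse(cbind(take1, take1), e1, e2))
  tail <- unname(ifelse(cbind(take1, take1), e2, e1))
  list(head = head, tail = tail, low_confidence = lowconf)
}

#' Raw tracking table
#'
#' Bundles per-frame positions into a `forage_track`. `frame` is 0-based
#' as emitted by trackers; internally everything is indexed 1-based.
#' Missing frames are rows with `NA` positions.
#'
#' @param frame integer vector, 0-based, strictly increasing.
#' @param head,body n x 2 matrices; `tail` optional (reconstructed as the
#'   head reflected through the body when absent).
#' @param units `"mm"` or `"px"`.
#' @param fps frames per second.
#' @param time optional time vector in s (defaults to `frame / fps`).
#' @return a `forage_track`.
#' @export
raw_track <- function(frame, head, body, tail = NULL, units = "mm",
                      fps = 50, time = NULL) {
  stopifnot(units %in% c("mm", "px"))
  if (any(diff(frame) <= 0)) stop("frames must be strictly increasing")
  if (is.null(time)) time <- frame / fps
  tail_reconstructed <- is.null(tail)
  if (tail_reconstructed) tail <- 2 * body - head
  structure(list(frame = as.integer(frame), time = time,
                 head = head, body = body, tail = tail,
                 units = units, fps = fps,
                 tail_reconstructed = tail_reconstructed),
            class = "forage_track")
}

#' @export
print.forage_track <- function(x, ...) {
  cat(sprintf("<forage_track> %d frames @ %g fps (%.1f min), units %s\n",
              length(x$frame), x$fps, length(x$frame) / x$fps / 60, x$units))
  invisible(x)
}

#' Lost-frame quality control
#'
#' A fly passes QC when at most 10% of its frames are lost (missing rows
#' or NA positions); strictly more than 10% fails.
#'
#' @param raw a `forage_track`.
#' @return list with `lost_fraction` and `pass`.
#' @export
qc_track <- function(raw) {
  span <- raw$frame[length(raw$frame)] - raw$frame[1] + 1L
  present <- sum(!is.na(raw$head[, 1]) & !is.na(raw$body[, 1]))
  lost <- 1 - present / span
  list(lost_fraction = lost, pass = lost <= 0.10 + 1e-12)
}

# linear interpolation of NA runs in an n x 2 matrix; returns matrix +
# logical mask of filled frames
interp_gaps <- function(xy) {
  filled <- is.na(xy[, 1]) | is.na(xy[, 2])
  if (any(filled)) {
    idx <- seq_len(nrow(xy))
    for (j in 1:2) {
      xy[, j] <- stats::approx(idx[!filled], xy[!filled, j], xout = idx,
                               rule = 2)$y
    }
  }
  list(xy = xy, filled = filled)
}

#' Smooth a raw track and derive all kinematic channels
#'
#' Converts pixel input to mm, linearly interpolates missing frames
#' (retaining a gap mask), Gaussian-smooths head/body/tail positions
#' (0.32 s support), and computes head/body speed, signed angular speed,
#' and the extra-filtered head-speed channels used for walk (1.2 s) and
#' rest (2.4 s) classification. Body speed is additionally 1.2 s-filtered
#' into `body_speed_f` for the on-patch locomotion metrics.
#'
#' @param raw a `forage_track`.
#' @param mm_per_px pixel calibration, used when `raw$units == "px"`.
#' @param pos_width_s,walk_width_s,rest_width_s Gaussian filter supports
#'   in seconds for positions, the walk channel and the rest channel.
#' @return a `forage_smooth` with per-frame channels.
#' @export
smooth_track <- function(raw, mm_per_px = 0.155, pos_width_s = 0.32,
                         walk_width_s = 1.2, rest_width_s = 2.4) {
  fps <- raw$fps
  scl <- if (raw$units == "px") mm_per_px else 1
  gh <- interp_gaps(raw$head * scl)
  gb <- interp_gaps(raw$body * scl)
  gt <- interp_gaps(raw$tail * scl)
  head_s <- smooth_xy(gh$xy, pos_width_s, fps)
  body_s <- smooth_xy(gb$xy, pos_width_s, fps)
  tail_s <- smooth_xy(gt$xy, pos_width_s, fps)
  head_speed <- compute_speed(head_s, fps)
  body_speed <- compute_speed(body_s, fps)
  structure(list(
    frame = raw$frame, time = raw$time, fps = fps,
    head = head_s, body = body_s, tail = tail_s,
    head_speed = head_speed,
    body_speed = body_speed,
    angular_speed = compute_angular_speed(head_s, tail_s, fps),
    head_speed_walk = gaussian_smooth(head_speed, walk_width_s, fps),
    head_speed_rest = gaussian_smooth(head_speed, rest_width_s, fps),
    body_speed_f = gaussian_smooth(body_speed, walk_width_s, fps),
    gap_mask = gh$filled | gb$filled,
    n = length(raw$frame)
  ), class = "forage_smooth")
}

#' Construct a `forage_smooth` directly from channels
#'
#' Escape hatch for fixtures and unit tests: builds the smoothed-track
#' container from explicitly supplied channels without any filtering.
#' Channels not supplied are derived from the positions.
#'
#' @param head n x 2 matrix, mm. @param fps frames/s.
#' @param body,tail optional n x 2 matrices (default: `head`).
#' @param head_speed_walk,head_speed_rest,body_speed,angular_speed
#'   optional channel overrides.
#' @return a `forage_smooth`.
#' @export
as_smooth_track <- function(head, fps = 50, body = head, tail = body,
                            head_speed_walk = NULL, head_speed_rest = NULL,
                            body_speed = NULL, angular_speed = NULL) {
  n <- nrow(head)
  head_speed <- compute_speed(head, fps)
  if (is.null(body_speed)) body_speed <- compute_speed(body, fps)
  if (is.null(angular_speed))
    angular_speed <- compute_angular_speed(head, tail, fps)
  if (is.null(head_speed_walk)) head_speed_walk <- head_speed
  if (is.null(head_speed_rest)) head_speed_rest <- head_speed
  structure(list(frame = 0:(n - 1), time = (0:(n - 1)) / fps, fps = fps,
                 head = head, body = body, tail = tail,
                 head_speed = head_speed, body_speed = body_speed,
                 angular_speed = angular_speed,
                 head_speed_walk = head_speed_walk,
                 head_speed_rest = head_speed_rest,
                 body_speed_f = body_speed,
                 gap_mask = logical(n), n = n),
            class = "forage_smooth")
}

#' @export
print.forage_smooth <- function(x, ...) {
  cat(sprintf("<forage_smooth> %d frames @ %g fps (%.1f min)\n",
              x$n, x$fps, x$n / x$fps / 60))
  invisible(x)
}
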