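#' Foraging arena geometry
#'
#' An arena is a flat circular area of radius `inner_radius` mm containing
#' circular food patches of two substrates, yeast and sucrose. All
#' coordinates are in mm in an arena-centered frame (y up). Distance-based
#' event rules downstream (3 / 2.5 / 5 mm) are head-to-patch-center
#' distances and do not use the patch radius.
#'
#' @param patches data.frame with columns `id`, `x`, `y`, `radius`,
#'   `substrate` (one of `"yeast"`, `"sucrose"`).
#' @param inner_radius radius of the flat inner area, mm.
#' @param mm_per_px pixel calibration used when converting pixel input.
#' @param fps video frame rate, frames per second.
#' @return An object of class `forage_arena`.
#' @export
arena <- function(patches, inner_radius = 25, mm_per_px = 0.155, fps = 50) {
  stopifnot(is.data.frame(patches),
            all(c("id", "x", "y", "radius", "substrate") %in% names(patches)))
  patches$substrate <- as.character(patches$substrate)
  if (!all(patches$substrate %in% c("yeast", "sucrose")))
    stop("substrate must be 'yeast' or 'sucrose'")
  if (any(patches$radius <= 0)) stop("patch radius must be > 0")
  if (any(sqrt(patches$x^2 + patches$y^2) > inner_radius))
    stop("all patch centers must lie within inner_radius")
  a <- structure(list(patches = patches, inner_radius = inner_radius,
                      mm_per_px = mm_per_px, fps = fps),
                 class = "forage_arena")
  a
}

#' @export
print.forage_arena <- function(x, ...) {
  tb <- table(x$patches$substrate)
  cat(sprintf("<forage_arena> %d patches (%s), inner radius %.1f mm, %.3f mm/px, %g fps\n",
              nrow(x$patches),
              paste(sprintf("%d %s", tb, names(tb)), collapse = ", "),
              x$inner_radius, x$mm_per_px, x$fps))
  invisible(x)
}

#' Build the standard 18-patch arena
#'
#' Places 12 patches on an outer ring and 6 on an inner ring, substrates
#' alternating within each ring, so that the layout satisfies the design
#' constraints: 9 yeast and 9 sucrose patches, pairwise center distance
#' >= 10 mm, and every patch has at least one adjacent (center distance
#' <= 16 mm) patch of each substrate. The exact ring radii are an
#' implementation choice; `seed` only applies a random global rotation.
#'
#' @param seed optional integer; rotates the whole layout by a random
#'   angle. `NULL` gives the unrotated reference layout.
#' @param inner_radius,mm_per_px,fps passed to [arena()].
#' @return A `forage_arena` with 18 patches.
#' @export
build_standard_arena <- function(seed = NULL, inner_radius = 25,
                                 mm_per_px = 0.155, fps = 50) {
  rot <- 0
  if (!is.null(seed)) {
    rot <- local({
      set.seed(as.integer(seed) %% .Machine$integer.max)
      stats::runif(1, 0, 2 * pi)
    })
  }
  ring <- function(n, r, phase) {
    th <- phase + rot + 2 * pi * (seq_len(n) - 1) / n
    cbind(x = r * cos(th), y = r * sin(th))
  }
  # radii chosen so that every spacing rule holds: outer chord 11.4 mm,
  # inner chord 12.5 mm, closest cross-ring pairs 10.4 mm, and each
  # outer patch reaches two inner patches of opposite substrate (15.9 mm)
  outer <- ring(12, 22, 0)
  inner <- ring(6, 12.5, pi / 12)  # staggered half an outer step
  xy <- rbind(outer, inner)
  substrate <- c(rep(c("yeast", "sucrose"), 6), rep(c("yeast", "sucrose"), 3))
  p <- data.frame(id = seq_len(18), x = xy[, "x"], y = xy[, "y"],
                  radius = 1.5, substrate = substrate)
  a <- arena(p, inner_radius = inner_radius, mm_per_px = mm_per_px, fps = fps)
  validate_arena(a)
  a
}

#' Validate arena layout invariants
#'
#' Checks pairwise spacing (>= 10 mm), substrate counts for the standard
#' 18-patch layout, and the mixed-substrate adjacency requirement.
#' @param a a `forage_arena`.
#' @return `a`, invisibly; raises an error on violation.
#' @export
validate_arena <- function(a) {
  p <- a$patches
  d <- as.matrix(stats::dist(p[, c("x", "y")]))
  diag(d) <- Inf
  if (min(d) < 10 - 1e-9)
    stop(sprintf("patch layout violates the 10 mm spacing (min %.2f mm)", min(d)))
  adj <- adjacency(a)
  for (i in seq_len(nrow(p))) {
    nb <- p$substrate[adj[i, ]]
    if (!("yeast" %in% nb) || !("sucrose" %in% nb))
      stop("every patch must have adjacent patches of both substrates")
  }
  invisible(a)
}

#' Euclidean distance from a point to every patch center
#'
#' @param point numeric length-2, mm.
#' @param a a `forage_arena`.
#' @return numeric vector, one distance (mm) per patch.
#' @export
distances_to_patches <- function(point, a) {
  stopifnot(length(point) == 2, all(is.finite(point)))
  sqrt((a$patches$x - point[1])^2 + (a$patches$y - point[2])^2)
}

# n x 2 matrix of head positions -> n x n_patches distance matrix
patch_distance_matrix <- function(xy, a) {
  p <- a$patches
  dx <- outer(xy[, 1], p$x, "-")
  dy <- outer(xy[, 2], p$y, "-")
  sqrt(dx^2 + dy^2)
}

#' Patch adjacency matrix
#'
#' Two patches are adjacent when their center distance is <= 16 mm
#' (the same threshold that classifies adjacent-patch transitions).
#'
#' @param a a `forage_arena`.
#' @param max_dist adjacency threshold, mm.
#' @return symmetric logical matrix with `FALSE` diagonal.
#' @export
adjacency <- function(a, max_dist = 16) {
  d <- as.matrix(stats::dist(a$patches[, c("x", "y")]))
  m <- d <= max_dist
  diag(m) <- FALSE
  m
}

#' Read / write an arena as JSON
#'
#' The on-disk schema is
#' `{mm_per_px, fps, inner_radius_mm, patches: [{id, x_mm, y_mm, radius_mm, substrate}]}`.
#'
#' @param a a `forage_arena`.
#' @param path file path.
#' @return `read_arena` returns a `forage_arena`; `write_arena` returns
#'   `path` invisibly.
#' @export
write_arena <- function(a, path) {
  obj <- list(mm_per_px = a$mm_per_px, fps = a$fps,
              inner_radius_mm = a$inner_radius,
              patches = data.frame(id = a$patches$id,
                                   x_mm = a$patches$x, y_mm = a$patches$y,
                                   radius_mm = a$patches$radius,
                                   substrate = a$patches$substrate))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_arena
#' @export
read_arena <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$patches
  arena(data.frame(id = p$id, x = p$x_mm, y = p$y_mm, radius = p$radius_mm,
                   substrate = p$substrate),
        inner_radius = obj$inner_radius_mm,
        mm_per_px = obj$mm_per_px, fps = obj$fps)
}
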