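#' Parametric scattering media
#'
#' The scattering coefficient sigma(x) is represented as a positive baseline
#' plus characteristic-function features: intervals ("bumps") on `[0, 1]` for
#' slab problems, or disks on `[0, 1]^2`.  Interval membership is closed
#' (`a <= x <= b`, up to a 1e-12 floating-point tolerance so that grid nodes
#' landing on an endpoint are included); disk membership is strict
#' (`|x - c| < r`), so a point exactly on a disk rim takes the baseline value.
#'
#' @param baseline Positive background value of sigma.
#' @param bumps A data frame with columns `a`, `b`, `h`: interval
#'   `[a, b]` within `[0, 1]` and height `h >= 0`.
#' @return An object of class `media_bumps` / `media_disks` (both inherit
#'   from `media`).
#' @seealso [evaluate_sigma()], [example_media()], [three_bump_medium()]
#' @export
media_bumps <- function(baseline = 1, bumps = tibble(a = numeric(), b = numeric(), h = numeric())) {
  bumps <- as_tibble(bumps)
  stopifnot(is.numeric(baseline), length(baseline) == 1L, baseline > 0)
  stopifnot(all(c("a", "b", "h") %in% names(bumps)))
  if (nrow(bumps)) {
    if (any(bumps$a > bumps$b)) abort("bump intervals need a <= b")
    if (any(bumps$a < -1e-12 | bumps$b > 1 + 1e-12)) abort("bump intervals must lie within [0, 1]")
    if (any(bumps$h < 0)) abort("bump heights must be nonnegative")
  }
  structure(list(baseline = baseline, bumps = bumps, dim = 1L),
            class = c("media_bumps", "media"))
}

#' @rdname media_bumps
#' @param disks A data frame with columns `cx`, `cy`, `r`, `h`: centre,
#'   radius `r > 0` and height `h >= 0`.  A zero radius is allowed as the
#'   degenerate empty disk.
#' @export
media_disks <- function(baseline = 1, disks = tibble(cx = numeric(), cy = numeric(), r = numeric(), h = numeric())) {
  disks <- as_tibble(disks)
  stopifnot(is.numeric(baseline), length(baseline) == 1L, baseline > 0)
  stopifnot(all(c("cx", "cy", "r", "h") %in% names(disks)))
  if (nrow(disks)) {
    if (any(disks$r < 0)) abort("disk radii must be nonnegative")
    if (any(disks$h < 0)) abort("disk heights must be nonnegative")
  }
  structure(list(baseline = baseline, disks = disks, dim = 2L),
            class = c("media_disks", "media"))
}

#' @export
print.media <- function(x, ...) {
  feat <- if (x$dim == 1L) x$bumps else x$disks
  cat(sprintf("<%s> baseline %g, %d feature(s)\n", class(x)[1], x$baseline, nrow(feat)))
  if (nrow(feat)) print(feat)
  invisible(x)
}

#' The three-bump slab medium
#'
#' The piecewise-constant slab profile
#' `sigma(x) = 1 + 9 X_\[0.05, 0.15\](x) + 19 X_\[0.35, 0.45\](x) + 29 X_\[0.75, 0.85\](x)`
#' used by the forward diffusion-limit study.
#' @return A [media_bumps()] object.
#' @export
three_bump_medium <- function() {
  media_bumps(1, tibble(
    a = c(0.05, 0.35, 0.75),
    b = c(0.15, 0.45, 0.85),
    h = c(9, 19, 29)
  ))
}

# fixed disk centres for the five-disk example
five_disk_centres <- function() {
  tibble(
    cx = c(0.5, 0.2, 0.75, 0.8, 0.3),
    cy = c(0.5, 0.35, 0.2, 0.85, 0.8)
  )
}

#' Reference disk media for the reconstruction examples
#'
#' Example 1 is a single disk centred at (0.5, 0.5) parameterised by
#' `params = c(r, h)`.  Example 2 is a five-disk medium with fixed centres
#' (0.5, 0.5), (0.2, 0.35), (0.75, 0.2), (0.8, 0.85), (0.3, 0.8) and ten free
#' parameters `params = c(h1..h5, r1..r5)`.
#'
#' @param example 1 or 2.
#' @param params Numeric vector: length 2 (`r`, `h`) for example 1, length 10
#'   (`h1..h5`, `r1..r5`) for example 2.
#' @return A [media_disks()] object.
#' @examples
#' example_media(1, c(0.4, 10))       # the single-disk truth
#' example_media(2, example2_truth()) # the five-disk truth
#' @export
example_media <- function(example, params) {
  stopifnot(example %in% c(1, 2))
  params <- as.numeric(params)
  if (example == 1) {
    if (length(params) != 2L) abort("example 1 takes parameters c(r, h)")
    if (params[1] < 0) abort("radius must be nonnegative")
    media_disks(1, tibble(cx = 0.5, cy = 0.5, r = params[1], h = params[2]))
  } else {
    if (length(params) != 10L) abort("example 2 takes parameters c(h1..h5, r1..r5)")
    h <- params[1:5]; r <- params[6:10]
    if (any(r < 0)) abort("radii must be nonnegative")
    cc <- five_disk_centres()
    media_disks(1, tibble(cx = cc$cx, cy = cc$cy, r = r, h = h))
  }
}

#' True parameters of the five-disk medium
#'
#' Heights 5, 1, 7, 4, 10 and radii 0.19, 0.10, 0.09, 0.13, 0.04, in the
#' `c(h1..h5, r1..r5)` ordering used by [example_media()].
#' @return Named numeric vector of length 10.
#' @export
example2_truth <- function() {
  c(h1 = 5, h2 = 1, h3 = 7, h4 = 4, h5 = 10,
    r1 = 0.19, r2 = 0.10, r3 = 0.09, r4 = 0.13, r5 = 0.04)
}

#' Evaluate the scattering coefficient at points
#'
#' Returns baseline plus the summed heights of all features containing each
#' point.  Intervals are closed (with a 1e-12 tolerance); disk membership is
#' strict (`|x - c| < r`).
#'
#' @param media A `media` object.
#' @param points For slab media, a numeric vector of positions in `[0, 1]`
#'   (or a data frame with column `x`); for disk media a two-column
#'   matrix/data frame of positions in `[0, 1]^2`.
#' @return Numeric vector of sigma values.
#' @export
evaluate_sigma <- function(media, points) UseMethod("evaluate_sigma")

#' @export
evaluate_sigma.media_bumps <- function(media, points) {
  if (is.data.frame(points)) points <- points$x
  x <- as.numeric(points)
  tol <- 1e-12
  if (any(x < -tol | x > 1 + tol)) abort("points outside the domain [0, 1]")
  sig <- rep(media$baseline, length(x))
  for (k in seq_len(nrow(media$bumps))) {
    inside <- x >= media$bumps$a[k] - tol & x <= media$bumps$b[k] + tol
    sig <- sig + media$bumps$h[k] * inside
  }
  sig
}

#' @export
evaluate_sigma.media_disks <- function(media, points) {
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  if (ncol(points) != 2L) abort("disk media take two-column points")
  tol <- 1e-12
  if (any(points < -tol | points > 1 + tol)) abort("points outside the domain [0, 1]^2")
  sig <- rep(media$baseline, nrow(points))
  for (k in seq_len(nrow(media$disks))) {
    d2 <- (points[, 1] - media$disks$cx[k])^2 + (points[, 2] - media$disks$cy[k])^2
    sig <- sig + media$disks$h[k] * (d2 < media$disks$r[k]^2)
  }
  sig
}

# sigma sampled at the spatial nodes of a grid
sigma_on_grid <- function(media, grid) {
  if (grid$dim != media$dim) abort("media dimension does not match grid dimension")
  evaluate_sigma(media, node_points(grid))
}

#' Discrete admissibility report for a medium
#'
#' Computes the three norms `max |sigma|`, `max |1/sigma|` and
#' `max |grad(1/sigma)|` on the grid nodes (the gradient by centred finite
#' differences, one-sided at the boundary) and compares their maximum against
#' the bound `c_star`.  For characteristic-function media the continuum
#' gradient does not exist, so this is a verification aid on the discrete
#' grid, not a gate: solvers do not require it to pass.
#'
#' @param media A `media` object.
#' @param grid A [phase_grid()] of matching dimension.
#' @param c_star Positive admissibility bound.
#' @return A one-row tibble with the three norms, their maximum, the bound
#'   and a logical `pass`.
#' @export
check_admissibility <- function(media, grid, c_star) {
  stopifnot(is.numeric(c_star), c_star > 0)
  sig <- sigma_on_grid(media, grid)
  inv <- 1 / sig
  dx <- grid$dx
  grad_max <- if (grid$dim == 1L) {
    g <- num_grad_1d(inv, dx)
    max(abs(g))
  } else {
    m <- matrix(inv, nrow = grid$nx)
    gx <- apply(m, 2, num_grad_1d, dx = dx)
    gy <- t(apply(m, 1, num_grad_1d, dx = dx))
    max(sqrt(gx^2 + gy^2))
  }
  norms <- c(sigma_sup = max(abs(sig)),
             inv_sigma_sup = max(abs(inv)),
             grad_inv_sigma_sup = grad_max)
  tibble(
    sigma_sup = norms[[1]], inv_sigma_sup = norms[[2]],
    grad_inv_sigma_sup = norms[[3]],
    max_norm = max(norms), c_star = c_star,
    pass = max(norms) < c_star
  )
}

# centred differences inside, one-sided at the ends
num_grad_1d <- function(v, dx) {
  n <- length(v)
  g <- numeric(n)
  if (n >= 3) g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dx)
  g[1] <- (v[2] - v[1]) / dx
  g[n] <- (v[n] - v[n - 1]) / dx
  g
}

#' Read and write media as JSON
#'
#' Media serialise as `{"baseline": ..., "bumps": [{"a","b","h"}, ...]}` or
#' `{"baseline": ..., "disks": [{"cx","cy","r","h"}, ...]}`.
#'
#' @param media A `media` object.
#' @param path File path.
#' @return `write_media()` returns `media` invisibly; `read_media()` returns
#'   the reconstructed `media` object.
#' @export
write_media <- function(media, path) {
  obj <- if (media$dim == 1L) {
    list(baseline = media$baseline, bumps = media$bumps)
  } else {
    list(baseline = media$baseline, disks = media$disks)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(media)
}

#' @rdname write_media
#' @export
read_media <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$bumps)) {
    media_bumps(obj$baseline, as_tibble(obj$bumps))
  } else if (!is.null(obj$disks)) {
    media_disks(obj$baseline, as_tibble(obj$disks))
  } else {
    abort("JSON does not describe a bumps or disks medium")
  }
}
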