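#' Phase-space grid for the transport and diffusion solvers
#'
#' Builds the shared tensor grid used by every solver in the package: spatial
#' nodes `x_i = i * dx` on `[0, 1]` (slab) or `[0, 1]^2` (unit square), and a
#' cell-centred set of angular ordinates on the unit circle,
#' `theta_m = (m - 1/2) * dv` with `dv = 2 * pi / n_angles` and equal weights
#' `w_m = 1 / n_angles`.  The angular measure is normalised (`sum(w) == 1`),
#' matching the convention in which the collision operator averages rather
#' than integrates.  Cell-centring guarantees that no ordinate has
#' `cos(theta) == 0` or `sin(theta) == 0`, so upwinding is always well defined.
#'
#' A slab grid (`dim = 1`) is the pseudo-2D configuration: one spatial
#' dimension but a full circle of directions, with transport acting through
#' `cos(theta)` only.
#'
#' @param dx Spatial step; `1 / dx` must be (close to) an integer.
#'   Default 0.05, giving 21 nodes per dimension.
#' @param n_angles Number of angular ordinates on the circle. Default 16,
#'   i.e. `dv = 2 * pi / 16`.
#' @param dim Spatial dimension: 1 (slab / pseudo-2D) or 2 (unit square).
#'
#' @return An object of class `phase_grid`: a list with the axis nodes, a
#'   `nodes` tibble (one row per spatial node with index and coordinates), the
#'   angular ordinates (`theta`, `mu = cos(theta)`, `eta = sin(theta)`,
#'   `weights`), and a `boundary` tibble with one row per (node, side) pair
#'   (corner nodes in 2-D appear twice, once per touching side).
#'
#' @examples
#' g <- phase_grid(dx = 0.25, n_angles = 8, dim = 2)
#' g$n_nodes       # 25
#' sum(g$weights)  # 1
#' @export
phase_grid <- function(dx = 0.05, n_angles = 16, dim = 2) {
  stopifnot(dx > 0, n_angles >= 2, dim %in% c(1L, 2L))
  n_cells <- round(1 / dx)
  if (abs(n_cells * dx - 1) > 1e-9) {
    abort("`dx` must divide [0, 1] into an integer number of cells.")
  }
  nx <- n_cells + 1L
  xs <- seq(0, 1, length.out = nx)
  dv <- 2 * pi / n_angles
  theta <- (seq_len(n_angles) - 0.5) * dv
  mu <- cos(theta)
  eta <- sin(theta)
  if (any(abs(mu) < 1e-12) || any(abs(eta) < 1e-12)) {
    abort("angular set places an ordinate on a coordinate axis; choose a different `n_angles`.")
  }
  weights <- rep(1 / n_angles, n_angles)

  if (dim == 1L) {
    nodes <- tibble(
      node = seq_len(nx), i = seq_len(nx), x = xs
    )
    boundary <- tibble(
      node = c(1L, nx),
      side = c("left", "right"),
      nx_out = c(-1, 1), ny_out = c(0, 0)
    )
  } else {
    ij <- expand.grid(i = seq_len(nx), j = seq_len(nx))
    nodes <- tibble(
      node = seq_len(nx * nx), i = ij$i, j = ij$j,
      x = xs[ij$i], y = xs[ij$j]
    )
    sides <- list(
      left   = list(sel = nodes$i == 1L,  n = c(-1, 0)),
      right  = list(sel = nodes$i == nx,  n = c(1, 0)),
      bottom = list(sel = nodes$j == 1L,  n = c(0, -1)),
      top    = list(sel = nodes$j == nx,  n = c(0, 1))
    )
    boundary <- purrr::imap_dfr(sides, function(s, nm) {
      tibble(node = nodes$node[s$sel], side = nm,
             nx_out = s$n[1], ny_out = s$n[2])
    })
  }

  structure(
    list(
      dx = dx, dim = dim, nx = nx, xs = xs,
      nodes = nodes, n_nodes = nrow(nodes),
      n_angles = n_angles, dv = dv, theta = theta,
      mu = mu, eta = eta, weights = weights,
      boundary = boundary
    ),
    class = "phase_grid"
  )
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf(
    "<phase_grid> dim %d | %d spatial nodes (dx = %g) | %d angles (dv = 2pi/%d)\n",
    x$dim, x$n_nodes, x$dx, x$n_angles, x$n_angles
  ))
  invisible(x)
}

#' Boundary nodes of a grid
#'
#' @param grid A [phase_grid()].
#' @param corners In 2-D, whether to include the four corner nodes (each
#'   once). Ignored for slab grids.
#' @return A tibble with one row per distinct boundary node, ordered by node
#'   index, with coordinates.
#' @export
boundary_nodes <- function(grid, corners = TRUE) {
  b <- grid$boundary
  counts <- table(b$node)
  keep <- unique(b$node)
  if (!corners && grid$dim == 2L) {
    keep <- as.integer(names(counts)[counts == 1L])
  }
  grid$nodes %>%
    filter(.data$node %in% keep) %>%
    arrange(.data$node)
}

# node index from (i, j) on a 2-D grid, i fastest
node_id <- function(grid, i, j = NULL) {
  if (grid$dim == 1L) return(i)
  (j - 1L) * grid$nx + i
}

# spatial points of all nodes as a matrix (n_nodes x dim)
node_points <- function(grid) {
  if (grid$dim == 1L) matrix(grid$nodes$x, ncol = 1)
  else cbind(grid$nodes$x, grid$nodes$y)
}

# outward-pointing sides for each boundary (node, side) row, as components
# of v . n for each angle: returns matrix (rows of grid$boundary) x n_angles
boundary_vdotn <- function(grid) {
  vn <- outer(grid$boundary$nx_out, grid$mu) +
    outer(grid$boundary$ny_out, grid$eta)
  vn
}

# trapezoid quadrature weights over the grid nodes (1-D vector or tensor)
trapezoid_weights <- function(grid) {
  w1 <- rep(grid$dx, grid$nx)
  w1[c(1L, grid$nx)] <- grid$dx / 2
  if (grid$dim == 1L) return(w1)
  w1[grid$nodes$i] * w1[grid$nodes$j]
}
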