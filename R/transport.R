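#' Angular collision operator
#'
#' Applies `L f = <f>_v - f`, where `<f>_v` is the weighted angular average
#' under the normalised measure.  `L` annihilates functions that are constant
#' in angle, and its weighted average is zero for any `f` (particle
#' conservation in a scattering event).
#'
#' @param f Numeric vector over angles, or a matrix with one row per spatial
#'   node and one column per angle.
#' @param weights Angular quadrature weights summing to 1.
#' @return Same shape as `f`.
#' @examples
#' g <- phase_grid(dx = 0.5, n_angles = 16, dim = 1)
#' apply_collision(rep(3, 16), g$weights)  # all zeros
#' @export
apply_collision <- function(f, weights) {
  if (abs(sum(weights) - 1) > 1e-9) abort("angular weights must sum to 1")
  if (is.matrix(f)) {
    if (ncol(f) != length(weights)) abort("f and weights have mismatched angle counts")
    avg <- as.numeric(f %*% weights)
    sweep(-f, 1, avg, "+")
  } else {
    if (length(f) != length(weights)) abort("f and weights have mismatched angle counts")
    sum(weights * f) - f
  }
}

# Cached sparsity pattern and coefficient split for the discrete-ordinates
# operator at a fixed (grid, epsilon).  The assembled matrix is
#   A(sigma) = base + diag-block( sigma_n / epsilon ) * collision,
# so only the value slot changes between media: A@x = base_x + s[node] * coef_x.
# Rows are indexed u = (m - 1) * n_nodes + n.  Inflow rows carry an identity
# equation f = phi.
rte_operator <- function(grid, epsilon) {
  if (epsilon <= 0) abort("epsilon must be positive")
  nn <- grid$n_nodes
  nv <- grid$n_angles
  dx <- grid$dx
  nx <- grid$nx
  mu <- grid$mu
  eta <- grid$eta
  w <- grid$weights
  nodes <- grid$nodes

  ii <- vector("list", nv); jj <- vector("list", nv)
  vb <- vector("list", nv); vc <- vector("list", nv)
  bc_u <- vector("list", nv); bc_n <- vector("list", nv); bc_m <- vector("list", nv)

  for (m in seq_len(nv)) {
    off <- (m - 1L) * nn
    if (grid$dim == 1L) {
      bc <- (nodes$i == 1L & mu[m] > 0) | (nodes$i == nx & mu[m] < 0)
    } else {
      bc <- (nodes$i == 1L & mu[m] > 0) | (nodes$i == nx & mu[m] < 0) |
        (nodes$j == 1L & eta[m] > 0) | (nodes$j == nx & eta[m] < 0)
    }
    nb <- which(bc)
    nf <- which(!bc)
    r <- off + nf

    i_m <- off + nb; j_m <- off + nb
    b_m <- rep(1, length(nb)); c_m <- rep(0, length(nb))

    # upwind x-transport: for mu > 0 use (f_i - f_{i-1})/dx, else (f_i - f_{i+1})/dx
    up_x <- if (mu[m] > 0) node_id(grid, nodes$i[nf] - 1L, nodes$j[nf])
            else node_id(grid, nodes$i[nf] + 1L, nodes$j[nf])
    i_m <- c(i_m, r, r); j_m <- c(j_m, off + nf, off + up_x)
    b_m <- c(b_m, rep(abs(mu[m]) / dx, length(nf)), rep(-abs(mu[m]) / dx, length(nf)))
    c_m <- c(c_m, numeric(2L * length(nf)))

    if (grid$dim == 2L) {
      up_y <- if (eta[m] > 0) node_id(grid, nodes$i[nf], nodes$j[nf] - 1L)
              else node_id(grid, nodes$i[nf], nodes$j[nf] + 1L)
      i_m <- c(i_m, r, r); j_m <- c(j_m, off + nf, off + up_y)
      b_m <- c(b_m, rep(abs(eta[m]) / dx, length(nf)), rep(-abs(eta[m]) / dx, length(nf)))
      c_m <- c(c_m, numeric(2L * length(nf)))
    }

    # collision - (sigma / eps) (<f> - f): coefficient  w_mm - delta_{m,mm},
    # sign folded so that the assembled row is  transport + s * (delta - w)
    for (mm in seq_len(nv)) {
      i_m <- c(i_m, r); j_m <- c(j_m, (mm - 1L) * nn + nf)
      c_m <- c(c_m, rep((mm == m) - w[mm], length(nf)))
      b_m <- c(b_m, numeric(length(nf)))
    }

    ii[[m]] <- i_m; jj[[m]] <- j_m; vb[[m]] <- b_m; vc[[m]] <- c_m
    bc_u[[m]] <- off + nb; bc_n[[m]] <- nb; bc_m[[m]] <- rep(m, length(nb))
  }

  i_all <- unlist(ii); j_all <- unlist(jj)
  n_tot <- nn * nv
  a_base <- sparseMatrix(i = i_all, j = j_all, x = unlist(vb), dims = c(n_tot, n_tot))
  a_coef <- sparseMatrix(i = i_all, j = j_all, x = unlist(vc), dims = c(n_tot, n_tot))
  stopifnot(identical(a_base@i, a_coef@i), identical(a_base@p, a_coef@p))
  node_of_pos <- ((a_base@i) %% nn) + 1L  # @i is 0-based

  # node-major permutation (all angles of one node adjacent): the collision
  # coupling then forms dense diagonal blocks, which the sparse LU factors
  # measurably faster than the angle-major layout
  perm <- as.integer(outer((seq_len(nv) - 1L) * nn, seq_len(nn), "+"))

  list(
    grid = grid, epsilon = epsilon,
    pattern = a_base, base_x = a_base@x, coef_x = a_coef@x,
    node_of_pos = node_of_pos, perm = perm,
    bc_u = unlist(bc_u), bc_n = unlist(bc_n), bc_m = unlist(bc_m)
  )
}

# assembled matrix for a specific sigma field (values at grid nodes)
rte_matrix_from_sigma <- function(op, sigma) {
  a <- op$pattern
  a@x <- op$base_x + (sigma[op$node_of_pos] / op$epsilon) * op$coef_x
  a
}

# right-hand side(s) from inflow matrices phi (n_nodes x n_angles); phi_list
# may be a single matrix or a list of them (one column of B per entry)
rte_rhs <- function(op, phi_list) {
  if (is.matrix(phi_list)) phi_list <- list(phi_list)
  n_tot <- op$grid$n_nodes * op$grid$n_angles
  b <- matrix(0, n_tot, length(phi_list))
  sel <- cbind(op$bc_n, op$bc_m)
  for (k in seq_along(phi_list)) {
    b[op$bc_u, k] <- phi_list[[k]][sel]
  }
  b
}

#' Assemble the discrete-ordinates transport system
#'
#' Builds the sparse linear system for the scaled transport equation
#' `v . grad f = (sigma / epsilon) (<f>_v - f)` with first-order upwinding in
#' space and inflow boundary rows `f = phi` on the incoming set (directions
#' with `v . n < 0` at a boundary node).  The matrix is square of size
#' (number of spatial nodes) x (number of angles).
#'
#' @param grid A [phase_grid()].
#' @param media A `media` object of matching dimension.
#' @param epsilon Positive Knudsen number.
#' @param inflow Inflow data: a matrix `n_nodes x n_angles` whose entries are
#'   read on the incoming boundary set (see [inflow_constant()],
#'   [inflow_sides()], [inflow_delta()], [compatible_inflow()]).
#' @return An `rte_system` object (matrix, right-hand side, and metadata)
#'   for [solve_rte()].
#' @export
assemble_rte <- function(grid, media, epsilon, inflow) {
  op <- rte_operator(grid, epsilon)
  sigma <- sigma_on_grid(media, grid)
  if (any(sigma <= 0)) abort("sigma must be positive on the grid")
  a <- rte_matrix_from_sigma(op, sigma)
  b <- rte_rhs(op, inflow)[, 1]
  structure(list(A = a, b = b, grid = grid, epsilon = epsilon,
                 phi = inflow, op = op, sigma = sigma),
            class = "rte_system")
}

#' Solve an assembled transport system
#'
#' Sparse direct (LU) solve of the upwind discrete-ordinates system, with a
#' relative residual check at `rtol`.
#'
#' @param system An `rte_system` from [assemble_rte()].
#' @param rtol Relative residual tolerance (default 1e-10).
#' @return A `phase_solution`: the phase-space field `f` (nodes x angles)
#'   together with the grid, epsilon and the inflow that produced it.
#' @export
solve_rte <- function(system, rtol = 1e-10) {
  stopifnot(inherits(system, "rte_system"))
  f <- Matrix::solve(system$A, system$b)
  f <- as.numeric(f)
  res <- sqrt(sum((as.numeric(system$A %*% f) - system$b)^2))
  rhs_norm <- sqrt(sum(system$b^2))
  if (res > rtol * max(rhs_norm, 1e-300)) {
    abort(sprintf("transport solve did not reach tolerance: residual %.3e", res))
  }
  structure(
    list(f = matrix(f, nrow = system$grid$n_nodes),
         grid = system$grid, epsilon = system$epsilon, phi = system$phi),
    class = "phase_solution"
  )
}

# factorise once, solve for many inflow columns; returns n_tot x K matrix.
# The solve runs in the node-major ordering (op$perm) and is mapped back.
rte_solve_multi <- function(op, sigma, b) {
  a <- rte_matrix_from_sigma(op, sigma)
  p <- op$perm
  ap <- a[p, p]
  zp <- as.matrix(Matrix::solve(Matrix::lu(ap), b[p, , drop = FALSE]))
  y <- zp
  y[p, ] <- zp
  y
}

#' @export
print.phase_solution <- function(x, ...) {
  cat(sprintf("<phase_solution> dim %d | %d nodes x %d angles | epsilon = %g\n",
              x$grid$dim, x$grid$n_nodes, x$grid$n_angles, x$epsilon))
  invisible(x)
}

#' Velocity-averaged density (fluence)
#'
#' `rho(x) = sum_m w_m f(x, theta_m)`: the light intensity as a function of
#' physical space alone.
#'
#' @param sol A `phase_solution` from [solve_rte()].
#' @return A tibble of node coordinates with column `rho`.
#' @export
fluence <- function(sol) {
  stopifnot(inherits(sol, "phase_solution"))
  out <- sol$grid$nodes
  out$rho <- fluence_vec(sol$f, sol$grid$weights)
  out
}

fluence_vec <- function(f, weights) as.numeric(f %*% weights)

# the dimensional constant in the boundary-current normalisation; the angular
# set is the full circle in both the slab and square configurations, for which
# <(v . n)^2> = 1/2
current_cd <- function(grid) 0.5

#' Outgoing boundary current of a transport solution
#'
#' The albedo-operator datum
#' `h_RTE(x) = (1 / (C_d * epsilon)) * sum_m w_m (v_m . n) f(x, theta_m)`,
#' evaluated at boundary nodes with the net (full-circle) angular moment:
#' outgoing directions contribute the computed solution and incoming
#' directions the prescribed inflow (which the solution rows enforce exactly).
#' The literal outgoing-only half-range moment is available via
#' `outgoing_only = TRUE`; its leading term is the O(1/epsilon) density moment
#' and it does not converge to the diffusion datum, so the net current is the
#' default.  At a 2-D corner node the two touching sides are averaged.
#'
#' @param sol A `phase_solution`.
#' @param nodes Boundary node indices (default: all distinct boundary nodes).
#' @param outgoing_only If `TRUE`, restrict the angular sum to `v . n > 0`.
#' @return A tibble with node index, coordinates and current `h`.
#' @export
boundary_current <- function(sol, nodes = NULL, outgoing_only = FALSE) {
  grid <- sol$grid
  bt <- grid$boundary
  if (is.null(nodes)) nodes <- sort(unique(bt$node))
  if (!all(nodes %in% bt$node)) abort("requested node is not on the boundary")
  vn <- boundary_vdotn(grid)  # (boundary rows) x angles
  if (outgoing_only) vn <- vn * (vn > 0)
  wmat <- matrix(grid$weights, nrow = nrow(vn), ncol = grid$n_angles, byrow = TRUE)
  h_side <- rowSums(vn * wmat * sol$f[bt$node, , drop = FALSE]) /
    (current_cd(grid) * sol$epsilon)
  agg <- tibble(node = bt$node, h = h_side) %>%
    group_by(.data$node) %>%
    summarise(h = mean(.data$h), .groups = "drop")
  out <- grid$nodes %>%
    filter(.data$node %in% nodes) %>%
    left_join(agg, by = "node") %>%
    arrange(.data$node)
  out
}

#' Constant, side-wise and point-source inflow data
#'
#' Inflow data live on the incoming boundary set; the package represents them
#' as a full `n_nodes x n_angles` matrix whose values are only read at
#' boundary nodes for incoming directions.
#'
#' * `inflow_constant()`: the same value everywhere.
#' * `inflow_sides()`: one value per side (`left`, `right`, and in 2-D
#'   `bottom`, `top`); the slab diffusion-limit study uses
#'   `inflow_sides(grid, left = 1, right = 0)`.
#' * `inflow_delta()`: a Kronecker-delta light source, isotropic over the
#'   incoming directions at a single boundary node.
#'
#' @param grid A [phase_grid()].
#' @param value Constant inflow value / source amplitude.
#' @return An inflow matrix.
#' @export
inflow_constant <- function(grid, value = 1) {
  matrix(value, grid$n_nodes, grid$n_angles)
}

#' @rdname inflow_constant
#' @param left,right,bottom,top Side values.
#' @export
inflow_sides <- function(grid, left = 0, right = 0, bottom = 0, top = 0) {
  phi <- matrix(0, grid$n_nodes, grid$n_angles)
  vals <- c(left = left, right = right, bottom = bottom, top = top)
  for (s in unique(grid$boundary$side)) {
    nds <- grid$boundary$node[grid$boundary$side == s]
    phi[nds, ] <- vals[[s]]
  }
  phi
}

#' @rdname inflow_constant
#' @param node Boundary node index carrying the source.
#' @export
inflow_delta <- function(grid, node, value = 1) {
  if (!node %in% grid$boundary$node) abort("source node is not on the boundary")
  phi <- matrix(0, grid$n_nodes, grid$n_angles)
  phi[node, ] <- value
  phi
}
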