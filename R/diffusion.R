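# Cached pattern for the conservation-form diffusion operator on the grid's
# spatial nodes.  Interior row n:  sum_faces a_face (rho_nb - rho_n) / dx^2 = 0
# with a = 1/sigma sampled at face midpoints; boundary rows are identity
# (Dirichlet).  Face-midpoint sampling makes the scheme identical to
# lowest-order FEM with elementwise-constant coefficients, and nodally exact
# in 1-D when coefficient jumps align with nodes.
de_operator <- function(grid) {
  nn <- grid$n_nodes
  nodes <- grid$nodes
  nx <- grid$nx
  dx <- grid$dx
  bnodes <- unique(grid$boundary$node)
  interior <- setdiff(seq_len(nn), bnodes)

  # faces: for each interior node, its 2*dim faces with midpoints
  nb <- list(
    list(di = -1L, dj = 0L), list(di = 1L, dj = 0L)
  )
  if (grid$dim == 2L) {
    nb <- c(nb, list(list(di = 0L, dj = -1L), list(di = 0L, dj = 1L)))
  }
  ii <- integer(0); jj <- integer(0); face_id <- integer(0); sgn <- numeric(0)
  mids <- NULL
  nfaces <- 0L
  for (k in seq_along(nb)) {
    i2 <- nodes$i[interior] + nb[[k]]$di
    j2 <- if (grid$dim == 2L) nodes$j[interior] + nb[[k]]$dj else NULL
    nbr <- node_id(grid, i2, j2)
    fid <- nfaces + seq_along(interior)
    nfaces <- nfaces + length(interior)
    mid_x <- (grid$xs[nodes$i[interior]] + grid$xs[i2]) / 2
    mid <- if (grid$dim == 2L) {
      cbind(mid_x, (grid$xs[nodes$j[interior]] + grid$xs[j2]) / 2)
    } else matrix(mid_x, ncol = 1)
    mids <- rbind(mids, mid)
    # off-diagonal +a_face, diagonal -a_face
    ii <- c(ii, interior, interior)
    jj <- c(jj, nbr, interior)
    face_id <- c(face_id, fid, fid)
    sgn <- c(sgn, rep(1 / dx^2, length(interior)), rep(-1 / dx^2, length(interior)))
  }
  # boundary identity rows
  ii <- c(ii, bnodes); jj <- c(jj, bnodes)
  face_id <- c(face_id, rep(0L, length(bnodes)))
  sgn <- c(sgn, rep(1, length(bnodes)))

  # pattern with placeholder values; refilled per media via triplets
  list(grid = grid, interior = interior, bnodes = bnodes,
       ii = ii, jj = jj, face_id = face_id, sgn = sgn, face_mid = mids)
}

de_matrix_from_media <- function(op, media) {
  a_face <- 1 / evaluate_sigma(media, op$face_mid)
  vals <- ifelse(op$face_id == 0L, op$sgn, op$sgn * a_face[pmax(op$face_id, 1L)])
  sparseMatrix(i = op$ii, j = op$jj, x = vals,
               dims = c(op$grid$n_nodes, op$grid$n_nodes))
}

#' Dirichlet boundary data
#'
#' Boundary data for the diffusion solver, as a full-length vector over the
#' grid nodes whose values are read at boundary nodes only.
#' `dirichlet_sides()` assigns one value per side (2-D corners take the value
#' of the last side listed that touches them, evaluated in the order left,
#' right, bottom, top); `dirichlet_delta()` puts a unit (or `value`) load on
#' one boundary node, zero elsewhere -- the diffusion-side analogue of a
#' Kronecker-delta light source.
#'
#' @param grid A [phase_grid()].
#' @param left,right,bottom,top Side values.
#' @return Numeric vector of length `grid$n_nodes`.
#' @export
dirichlet_sides <- function(grid, left = 0, right = 0, bottom = 0, top = 0) {
  xi <- numeric(grid$n_nodes)
  vals <- c(left = left, right = right, bottom = bottom, top = top)
  for (s in c("left", "right", "bottom", "top")) {
    nds <- grid$boundary$node[grid$boundary$side == s]
    if (length(nds)) xi[nds] <- vals[[s]]
  }
  xi
}

#' @rdname dirichlet_sides
#' @param node Boundary node carrying the load.
#' @param value Load value.
#' @export
dirichlet_delta <- function(grid, node, value = 1) {
  if (!node %in% grid$boundary$node) abort("node is not on the boundary")
  xi <- numeric(grid$n_nodes)
  xi[node] <- value
  xi
}

#' Solve the limiting diffusion equation
#'
#' Solves `div( (1/sigma) grad rho ) = 0` with Dirichlet data `xi` on the
#' boundary (the dimensional constant in front of the operator cancels in
#' this boundary-value problem and is dropped).  The conservation-form
#' finite-difference scheme samples `1/sigma` at face midpoints, which for
#' piecewise-constant media equals lowest-order FEM with elementwise
#' coefficients.
#'
#' @param grid A [phase_grid()].
#' @param media A `media` object of matching dimension.
#' @param xi Dirichlet data: vector of length `n_nodes` (read at boundary
#'   nodes), e.g. from [dirichlet_sides()] or [dirichlet_delta()].
#' @param rtol Relative residual tolerance.
#' @return A `de_solution` with the nodal field `rho`.
#' @export
solve_de <- function(grid, media, xi, rtol = 1e-10) {
  op <- de_operator(grid)
  a <- de_matrix_from_media(op, media)
  b <- numeric(grid$n_nodes)
  b[op$bnodes] <- xi[op$bnodes]
  rho <- as.numeric(Matrix::solve(a, b))
  res <- sqrt(sum((as.numeric(a %*% rho) - b)^2))
  if (res > rtol * max(sqrt(sum(b^2)), 1)) {
    abort(sprintf("diffusion solve did not reach tolerance: residual %.3e", res))
  }
  structure(list(rho = rho, grid = grid, media = media, xi = xi),
            class = "de_solution")
}

# factorise once, solve K Dirichlet loads; Xi is n_nodes x K (values at
# boundary nodes); returns n_nodes x K
de_solve_multi <- function(op, media, xi_mat) {
  a <- de_matrix_from_media(op, media)
  b <- matrix(0, op$grid$n_nodes, ncol(xi_mat))
  b[op$bnodes, ] <- xi_mat[op$bnodes, , drop = FALSE]
  as.matrix(Matrix::solve(a, b))
}

#' @export
print.de_solution <- function(x, ...) {
  cat(sprintf("<de_solution> dim %d | %d nodes\n", x$grid$dim, x$grid$n_nodes))
  invisible(x)
}

#' Dirichlet-to-Neumann boundary datum of a diffusion solution
#'
#' `h_DE(x) = (1/sigma) d(rho)/dn` at boundary nodes, with the outward normal
#' derivative approximated by the second-order one-sided difference
#' `(3 rho_b - 4 rho_1 + rho_2) / (2 dx)` along the inward grid line.  At a
#' 2-D corner the two touching sides are averaged.
#'
#' @param sol A `de_solution` from [solve_de()].
#' @param nodes Boundary node indices (default: all distinct boundary nodes).
#' @return A tibble with node index, coordinates and flux `h`.
#' @export
dtn_flux <- function(sol, nodes = NULL) {
  grid <- sol$grid
  bt <- grid$boundary
  if (is.null(nodes)) nodes <- sort(unique(bt$node))
  rho <- sol$rho
  sig_b <- evaluate_sigma(sol$media, node_points(grid))[bt$node]
  h_side <- numeric(nrow(bt))
  for (k in seq_len(nrow(bt))) {
    nd <- bt$node[k]
    i <- grid$nodes$i[nd]
    j <- if (grid$dim == 2L) grid$nodes$j[nd] else NULL
    di <- -as.integer(bt$nx_out[k]); dj <- -as.integer(bt$ny_out[k])
    n1 <- node_id(grid, i + di, if (is.null(j)) NULL else j + dj)
    n2 <- node_id(grid, i + 2L * di, if (is.null(j)) NULL else j + 2L * dj)
    dn <- (3 * rho[nd] - 4 * rho[n1] + rho[n2]) / (2 * grid$dx)
    h_side[k] <- dn / sig_b[k]
  }
  agg <- tibble(node = bt$node, h = h_side) %>%
    group_by(.data$node) %>%
    summarise(h = mean(.data$h), .groups = "drop")
  grid$nodes %>%
    filter(.data$node %in% nodes) %>%
    left_join(agg, by = "node") %>%
    arrange(.data$node)
}
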