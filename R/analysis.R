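#' L2(dx) distance between two nodal fields
#'
#' Trapezoid-weighted discrete L2 norm of the difference:
#' `sqrt(sum_i (a_i - b_i)^2 w_i)` with interior weight `dx` and end weight
#' `dx / 2` (tensorised in 2-D when a grid is supplied).
#'
#' @param rho_a,rho_b Numeric vectors on the same grid.
#' @param dx Grid spacing (1-D fields).
#' @param grid Alternatively, a [phase_grid()] whose trapezoid weights are
#'   used (required for 2-D fields).
#' @return Nonnegative scalar.
#' @export
l2_error <- function(rho_a, rho_b, dx = NULL, grid = NULL) {
  if (length(rho_a) != length(rho_b)) abort("fields live on different grids")
  w <- if (!is.null(grid)) {
    trapezoid_weights(grid)
  } else {
    stopifnot(!is.null(dx))
    w1 <- rep(dx, length(rho_a))
    w1[c(1L, length(rho_a))] <- dx / 2
    w1
  }
  sqrt(sum((rho_a - rho_b)^2 * w))
}

#' Gaussian-kernel density estimate on a parameter grid
#'
#' Product-Gaussian KDE of MCMC draws, evaluated at the cell centres of a
#' regular grid over a box and renormalised so the discrete integral over the
#' box is 1.  The default per-dimension bandwidth is Silverman's
#' rule-of-thumb ([stats::bw.nrd0()]).
#'
#' @param samples Matrix or data frame of draws (rows = draws, columns =
#'   dimensions; at most 2 for a full grid -- marginalise first for
#'   higher-dimensional chains).
#' @param lower,upper Box bounds, one entry per dimension.
#' @param cells Cells per dimension (default 100).
#' @param bandwidth Optional per-dimension bandwidth override.
#' @return A `grid_density` tibble with the cell-centre coordinates and the
#'   normalised `density`; the axes, cell measure and bandwidth are attached
#'   as attributes.
#' @export
kde_density <- function(samples, lower, upper, cells = 100, bandwidth = NULL) {
  s <- as.matrix(samples)
  d <- ncol(s)
  if (d > 2L) abort("full-grid KDE supports at most 2 dimensions; marginalise first")
  stopifnot(length(lower) == d, length(upper) == d, all(lower < upper))
  if (nrow(s) < 2L) abort("need at least 2 samples")
  spread <- vapply(seq_len(d), function(k) stats::sd(s[, k]), numeric(1))
  if (any(spread == 0) && is.null(bandwidth)) {
    abort("degenerate samples: zero spread in some dimension")
  }
  if (is.null(bandwidth)) {
    bandwidth <- vapply(seq_len(d), function(k) bw.nrd0(s[, k]), numeric(1))
  }
  if (any(bandwidth <= 0)) abort("degenerate samples: zero spread in some dimension")
  width <- (upper - lower) / cells
  axes <- lapply(seq_len(d), function(k) lower[k] + (seq_len(cells) - 0.5) * width[k])
  # per-dimension kernel matrices (cells x n), combined as a product kernel
  kmats <- lapply(seq_len(d), function(k)
    outer(axes[[k]], s[, k], function(g, x) dnorm(g, x, bandwidth[k])))
  if (d == 1L) {
    dens <- rowMeans(kmats[[1]])
    coords <- tibble(x1 = axes[[1]])
  } else {
    coords <- tibble(x1 = rep(axes[[1]], times = cells),
                     x2 = rep(axes[[2]], each = cells))
    dens <- as.numeric(kmats[[1]] %*% t(kmats[[2]]))  # cells1 x cells2, x1 fastest
  }
  cell_measure <- prod(width)
  total <- sum(dens) * cell_measure
  if (total <= 0) abort("KDE mass vanishes on the grid")
  out <- dplyr::bind_cols(coords, tibble(density = as.numeric(dens) / total))
  nm <- colnames(s)
  structure(out,
            class = c("grid_density", class(out)),
            axes = axes, cell_measure = cell_measure,
            bandwidth = bandwidth,
            dim_names = if (is.null(nm)) paste0("x", seq_len(d)) else nm)
}

check_same_grid <- function(p, q) {
  ap <- attr(p, "axes"); aq <- attr(q, "axes")
  if (length(ap) != length(aq) ||
      !isTRUE(all.equal(ap, aq, tolerance = 1e-12))) {
    abort("densities live on different grids")
  }
}

normalize_density <- function(p) {
  v <- p$density
  v / (sum(v) * attr(p, "cell_measure"))
}

#' Hellinger distance between two grid densities
#'
#' `d_H(p, q) = sqrt( (1/2) * sum (sqrt(p) - sqrt(q))^2 * cell )`, computed
#' after both inputs are renormalised on their (shared) grid.  Bounded in
#' `[0, 1]`; 0 iff the densities agree on the grid and 1 for disjoint
#' supports.
#'
#' @param p,q `grid_density` objects on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
hellinger <- function(p, q) {
  check_same_grid(p, q)
  cp <- normalize_density(p); cq <- normalize_density(q)
  h2 <- 0.5 * sum((sqrt(cp) - sqrt(cq))^2) * attr(p, "cell_measure")
  sqrt(min(max(h2, 0), 1))
}

#' Kullback-Leibler divergence between two grid densities
#'
#' `KL(p || q) = sum p * log(p / q) * cell` on renormalised inputs, with both
#' densities floored at `floor` before the logarithm so that empty tails of
#' the second argument contribute a large-but-finite penalty rather than an
#' infinity.
#'
#' @param p,q `grid_density` objects on the same grid.
#' @param floor Density floor (default 1e-30).
#' @return Nonnegative scalar.
#' @export
kl_divergence <- function(p, q, floor = 1e-30) {
  check_same_grid(p, q)
  cp <- pmax(normalize_density(p), floor)
  cq <- pmax(normalize_density(q), floor)
  sum(cp * (log(cp) - log(cq))) * attr(p, "cell_measure")
}

#' Cost model for the two-level sampler
#'
#' For a budget of `k` accepted samples, one-level sampling costs
#' `Cost1 = (k / r1) C_R` target solves, while the two-level scheme costs
#' `Cost2 = (k / (alpha beta)) C_D + (k / beta) C_R`: every proposal is
#' screened by the cheap surrogate (cost `C_D`) and only pre-accepted ones
#' reach the expensive solver (cost `C_R`).  When `C_D << C_R` the cost
#' ratio approaches `r1 / beta`, so the saving of the two-level scheme comes
#' from `beta > r1`.
#'
#' @param r1 One-level acceptance rate, in (0, 1].
#' @param beta Second-level acceptance rate, in (0, 1].
#' @param c_d,c_r Cost of one surrogate / target posterior evaluation
#'   (`c_d >= 0`, `c_r > 0`).
#' @param k Accepted-sample budget.
#' @param alpha First-level (pre-)acceptance rate, in (0, 1].
#' @return A one-row tibble: the inputs, `cost1`, `cost2`, their `ratio`,
#'   and the `ratio_limit = r1 / beta` reached as `c_d -> 0`.
#' @export
cost_model <- function(r1, beta, c_d, c_r, k = 1, alpha = 1) {
  if (any(c(r1, beta, alpha) <= 0) || any(c(r1, beta, alpha) > 1)) {
    abort("rates must lie in (0, 1]")
  }
  if (c_r <= 0 || c_d < 0) abort("costs must be positive (c_d may be zero)")
  cost1 <- k / r1 * c_r
  cost2 <- k / (alpha * beta) * c_d + k / beta * c_r
  tibble(
    r1 = r1, beta = beta, alpha = alpha, c_d = c_d, c_r = c_r, k = k,
    cost1 = cost1, cost2 = cost2,
    ratio = cost2 / cost1, ratio_limit = r1 / beta
  )
}

#' Empirical solve costs for the cost model
#'
#' Median wall-clock time of a single forward-map evaluation under each
#' model, over `reps` repetitions of the same medium, for use as `c_d` and
#' `c_r` in [cost_model()].
#'
#' @param media A `media` object.
#' @param design An [experiment_design()].
#' @param reps Repetitions (default 10).
#' @return A one-row tibble with `c_d` and `c_r` in seconds.
#' @export
measure_costs <- function(media, design, reps = 10) {
  cache_de <- design_cache(design, "DE")
  cache_rte <- design_cache(design, "RTE")
  t_de <- vapply(seq_len(reps), function(i)
    system.time(forward_vector(media, design, "DE", cache_de))[["elapsed"]],
    numeric(1))
  t_rte <- vapply(seq_len(reps), function(i)
    system.time(forward_vector(media, design, "RTE", cache_rte))[["elapsed"]],
    numeric(1))
  tibble(c_d = median(t_de), c_r = median(t_rte))
}
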