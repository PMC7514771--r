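test_that("default layouts give 20 sources and 80 detectors at dx = 0.05", {
  g <- phase_grid(dx = 0.05, n_angles = 16, dim = 2)
  expect_length(default_sources(g), 20)
  expect_length(default_detectors(g), 80)
  d <- experiment_design(g, epsilon = 1)
  expect_equal(d$K, 20)
  expect_equal(d$J, 80)
  expect_error(experiment_design(g, 1, sources = 89L), "boundary")
})

test_that("diffusion forward map matches a dense hand-assembled oracle", {
  g <- phase_grid(dx = 0.25, n_angles = 4, dim = 2)
  m <- media_disks(1, tibble::tibble(cx = 0.5, cy = 0.5, r = 0.3, h = 4))
  src <- default_sources(g)[2]
  det <- default_detectors(g)
  d <- experiment_design(g, epsilon = 0.5, sources = src, detectors = det,
                         current_scaling = "physical")
  got <- forward_vector(m <- m, d, "DE")

  # dense oracle: assemble the 5-point conservation-form system by loops
  nx <- g$nx; nn <- g$n_nodes
  sig_at <- function(p) evaluate_sigma(m, p)
  A <- matrix(0, nn, nn); b <- numeric(nn)
  bn <- unique(g$boundary$node)
  for (nd in seq_len(nn)) {
    i <- g$nodes$i[nd]; j <- g$nodes$j[nd]
    if (nd %in% bn) {
      A[nd, nd] <- 1
      b[nd] <- if (nd == src) 1 else 0
      next
    }
    for (step in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      nb <- (j + step[2] - 1) * nx + (i + step[1])
      mid <- cbind((g$xs[i] + g$xs[i + step[1]]) / 2,
                   (g$xs[j] + g$xs[j + step[2]]) / 2)
      a_face <- 1 / sig_at(mid)
      A[nd, nb] <- A[nd, nb] + a_face
      A[nd, nd] <- A[nd, nd] - a_face
    }
  }
  rho <- solve(A, b)
  cd <- 0.5
  h_manual <- vapply(seq_along(det), function(jj) {
    nd <- det[jj]
    rows <- which(g$boundary$node == nd)
    hvals <- vapply(rows, function(rr) {
      di <- -g$boundary$nx_out[rr]; dj <- -g$boundary$ny_out[rr]
      i <- g$nodes$i[nd]; j <- g$nodes$j[nd]
      n1 <- (j + dj - 1) * nx + (i + di)
      n2 <- (j + 2 * dj - 1) * nx + (i + 2 * di)
      -cd * d$epsilon * (3 * rho[nd] - 4 * rho[n1] + rho[n2]) /
        (2 * g$dx) / sig_at(cbind(g$nodes$x[nd], g$nodes$y[nd]))
    }, numeric(1))
    mean(hvals)
  }, numeric(1))
  expect_equal(got, h_manual, tolerance = 1e-10)
})

test_that("zero-amplitude sources give a zero measurement for both models", {
  g <- phase_grid(dx = 0.2, n_angles = 8, dim = 2)
  m <- example_media(1, c(0.3, 5))
  d0 <- experiment_design(g, epsilon = 0.5, source_amplitude = 0)
  expect_equal(forward_vector(m, d0, "DE"), rep(0, d0$J * d0$K))
  expect_equal(forward_vector(m, d0, "RTE"), rep(0, d0$J * d0$K))
})

test_that("permuting detectors permutes every source block identically", {
  g <- phase_grid(dx = 0.2, n_angles = 8, dim = 2)
  m <- example_media(1, c(0.3, 5))
  det <- default_detectors(g)
  perm <- sample(seq_along(det))
  d1 <- experiment_design(g, epsilon = 0.5, detectors = det)
  d2 <- experiment_design(g, epsilon = 0.5, detectors = det[perm])
  for (model in c("DE", "RTE")) {
    v1 <- matrix(forward_vector(m, d1, model), d1$J, d1$K)
    v2 <- matrix(forward_vector(m, d2, model), d2$J, d2$K)
    expect_equal(v2, v1[perm, ], tolerance = 1e-12)
  }
})

test_that("forward maps are deterministic", {
  g <- phase_grid(dx = 0.2, n_angles = 8, dim = 2)
  m <- example_media(2, example2_truth())
  d <- experiment_design(g, epsilon = 2^-3)
  expect_identical(forward_vector(m, d, "RTE"), forward_vector(m, d, "RTE"))
  expect_identical(forward_vector(m, d, "DE"), forward_vector(m, d, "DE"))
})

test_that("transport and diffusion maps converge to each other in epsilon", {
  g <- phase_grid(dx = 0.05, n_angles = 16, dim = 2)
  m <- example_media(1, c(0.4, 10))
  gaps <- vapply(c(1, 2^-2, 2^-4, 2^-6), function(eps) {
    d <- experiment_design(g, epsilon = eps)
    max(abs(forward_vector(m, d, "RTE") - forward_vector(m, d, "DE")))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("compatible inflow reduces to the Dirichlet trace at order 0", {
  g <- phase_grid(dx = 0.1, n_angles = 16, dim = 1)
  m <- three_bump_medium()
  # constant field: both orders give constant inflow
  xi_const <- rep(2, g$n_nodes)
  expect_equal(compatible_inflow(g, m, xi_const, 0.1, order = 0),
               matrix(2, g$n_nodes, g$n_angles))
  expect_equal(compatible_inflow(g, m, xi_const, 0.1, order = 1),
               matrix(2, g$n_nodes, g$n_angles))
  # delta trace at order 0
  xi_delta <- numeric(g$n_nodes); xi_delta[1] <- 1
  phi <- compatible_inflow(g, m, xi_delta, 0.1, order = 0)
  expect_equal(phi[1, ], rep(1, g$n_angles))
  expect_equal(phi[2, ], rep(0, g$n_angles))
})

test_that("order-1 compatible data tracks the interior expansion faster", {
  # Theorem-2 contract on a mildly heterogeneous slab: with first-order
  # matched inflow, || f - (rho - eps sigma^-1 v . grad rho) || decays faster
  # than the order-0 defect || f - rho ||.
  g <- phase_grid(dx = 0.005, n_angles = 16, dim = 1)
  m <- media_bumps(2, tibble::tibble(a = 0.4, b = 0.6, h = 2))
  de <- solve_de(g, m, dirichlet_sides(g, left = 1, right = 0))
  sig <- evaluate_sigma(m, g$xs)
  grad_rho <- detomo:::num_grad_1d(de$rho, g$dx)
  interior <- which(g$xs > 0.1 & g$xs < 0.9)  # exclude boundary layers
  defects <- vapply(c(2^-1, 2^-2, 2^-3), function(eps) {
    f0 <- solve_rte(assemble_rte(g, m, eps,
                                 compatible_inflow(g, m, de$rho, eps, order = 0)))$f
    f1 <- solve_rte(assemble_rte(g, m, eps,
                                 compatible_inflow(g, m, de$rho, eps, order = 1)))$f
    t0 <- max(abs(sweep(f0[interior, ], 1, de$rho[interior])))
    corr <- outer(grad_rho / sig, g$mu)
    t1 <- max(abs(f1[interior, ] - (de$rho[interior] - eps * corr[interior, ])))
    c(t0, t1)
  }, numeric(2))
  # both defects shrink with epsilon, and the matched data removes most of
  # the order-0 defect at every epsilon
  expect_true(all(defects[2, ] < 0.5 * defects[1, ]))
  expect_true(all(diff(defects[1, ]) < 0))
  expect_true(all(diff(defects[2, ]) < 0))
})

test_that("seeded synthetic data are reproducible and correctly scaled", {
  g <- phase_grid(dx = 0.1, n_angles = 8, dim = 2)
  m <- example_media(1, c(0.35, 8))
  d <- experiment_design(g, epsilon = 2^-3, noise_var = 1e-4)

  exact <- generate_data(m, d, model = "DE", seed = 4, noise_var = 0)
  expect_equal(exact$measurement$value, forward_vector(m, d, "DE"))

  a <- generate_data(m, d, model = "DE", seed = 4)
  b <- generate_data(m, d, model = "DE", seed = 4)
  expect_identical(a$measurement$value, b$measurement$value)
  expect_false(identical(a$measurement$value,
                         generate_data(m, d, model = "DE", seed = 5)$measurement$value))

  # pooled noise variance across several seeds is close to 1e-4
  resid <- unlist(lapply(1:26, function(s)
    generate_data(m, d, model = "DE", seed = s)$measurement$value - exact$measurement$value))
  expect_gte(length(resid), 1e4)
  expect_gt(stats::var(resid), 0.9e-4)
  expect_lt(stats::var(resid), 1.1e-4)
})
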