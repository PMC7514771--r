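# small shared fixture: cheap diffusion-model evaluator on a coarse grid
make_de_evaluator <- function(data = NULL, noise_var = 1e-4, prior = NULL) {
  g <- phase_grid(dx = 0.25, n_angles = 4, dim = 2)
  design <- experiment_design(g, epsilon = 0.5, noise_var = noise_var)
  if (is.null(prior)) prior <- prior_uniform(c(0, 0), c(0.5, 12), c("r", "h"))
  list(
    ev = posterior_evaluator(prior, data, design,
                             builder = function(th) example_media(1, th),
                             model = "DE", noise_var = noise_var),
    design = design, prior = prior
  )
}

test_that("log posterior is prior plus the Gaussian misfit", {
  g <- phase_grid(dx = 0.25, n_angles = 4, dim = 2)
  design <- experiment_design(g, epsilon = 0.5, noise_var = 1e-4)
  prior <- prior_uniform(c(0, 0), c(0.5, 12), c("r", "h"))
  theta <- c(0.3, 5)
  b_exact <- forward_vector(example_media(1, theta), design, "DE")

  ev <- posterior_evaluator(prior, b_exact, design,
                            function(th) example_media(1, th), model = "DE")
  # perfect fit: likelihood term vanishes
  expect_equal(log_posterior(ev, theta), 0)
  # shift the data so the squared misfit is exactly 2 gamma^2
  gamma2 <- 1e-4
  b_shift <- b_exact + sqrt(2 * gamma2 / length(b_exact))
  ev2 <- posterior_evaluator(prior, b_shift, design,
                             function(th) example_media(1, th), model = "DE")
  expect_equal(log_posterior(ev2, theta), -1, tolerance = 1e-9)
  # outside the box: -Inf without touching the solver
  n0 <- detomo:::n_forward_solves(ev2)
  expect_identical(log_posterior(ev2, c(0.7, 5)), -Inf)
  expect_identical(detomo:::n_forward_solves(ev2), n0)
})

test_that("a flat in-box target accepts every in-support proposal", {
  fx <- make_de_evaluator(data = NULL)
  chain <- mh_sample(fx$ev, n_steps = 200, x0 = c(0.25, 6),
                     proposal_sd = c(0.02, 0.2), seed = 1)
  acc <- attr(chain, "counts")$n_accept
  # every rejection must come from leaving the box
  df <- as.data.frame(chain)
  expect_true(all(df$r >= 0 & df$r <= 0.5 & df$h >= 0 & df$h <= 12))
  expect_gt(acc / 200, 0.9)
  expect_error(mh_sample(fx$ev, 10, x0 = c(2, 2), proposal_sd = 0.1),
               "support")
})

test_that("one-level discrete chain matches its exact transition kernel", {
  target <- c(0.3, 0.7)
  q <- matrix(c(0.4, 0.6, 0.5, 0.5), 2, 2, byrow = TRUE)
  P <- mh_kernel_oracle(target, q)
  # detailed balance and stationarity, exactly
  expect_equal(target[1] * P[1, 2], target[2] * P[2, 1], tolerance = 1e-15)
  expect_equal(as.numeric(target %*% P), target, tolerance = 1e-15)
  # empirical occupation matches the stationary law within 3 binomial sigmas
  n <- 1e5
  states <- mh_sample_discrete(target, q, n, x0 = 1L, seed = 42)
  p_hat <- mean(states == 2)
  se <- sqrt(target[2] * target[1] / n)  # iid bound; chain mixes in one step
  expect_lt(abs(p_hat - 0.7), 3 * se * 3)  # inflate for autocorrelation
})

test_that("two-level discrete chain targets the fine distribution", {
  surrogate <- c(0.5, 0.3, 0.2)
  target <- c(0.2, 0.5, 0.3)
  q <- matrix(1 / 3, 3, 3)
  P2 <- two_level_kernel_oracle(surrogate, target, q)
  # exact detailed balance and stationarity under the *target*
  for (x in 1:3) for (y in 1:3) {
    expect_equal(target[x] * P2[x, y], target[y] * P2[y, x], tolerance = 1e-15)
  }
  expect_equal(as.numeric(target %*% P2), target, tolerance = 1e-15)

  n <- 1e5
  states <- two_level_sample_discrete(surrogate, target, q, n, x0 = 1L, seed = 7)
  counts <- tabulate(states, 3)
  # chi-square against the target
  chisq_t <- sum((counts - n * target)^2 / (n * target))
  # the surrogate is far enough away that the same statistic explodes
  chisq_s <- sum((counts - n * surrogate)^2 / (n * surrogate))
  expect_lt(chisq_t, 30)
  expect_gt(chisq_s, 1000)
})

test_that("second-stage rate follows the closed form of the effective proposal", {
  # continuous 1-D toy: the closed form  min(1, mu_s(x) mu_t(y) / (mu_s(y)
  # mu_t(x)))  must equal  min(1, q2(y, x) mu_t(y) / (q2(x, y) mu_t(x)))
  # with q2 the level-1 effective proposal (off-diagonal part alpha * q)
  mu_s <- function(x) dnorm(x, 0, 1)
  mu_t <- function(x) dnorm(x, 0.3, 1.2)
  qd <- function(x, y) dnorm(y - x, 0, 0.5)
  beta_closed <- function(x, y) min(1, mu_s(x) * mu_t(y) / (mu_s(y) * mu_t(x)))
  beta_q2 <- function(x, y) {
    alpha <- function(a, b) min(1, qd(b, a) * mu_s(b) / (qd(a, b) * mu_s(a)))
    q2 <- function(a, b) alpha(a, b) * qd(a, b)   # off-diagonal density
    min(1, q2(y, x) * mu_t(y) / (q2(x, y) * mu_t(x)))
  }
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(1); y <- rnorm(1)
    expect_equal(beta_closed(x, y), beta_q2(x, y), tolerance = 1e-6)
  }
  # and the effective proposal is sub-stochastic: the integral of its
  # off-diagonal part never exceeds 1
  x <- 0.4
  alpha <- function(a, b) min(1, qd(b, a) * mu_s(b) / (qd(a, b) * mu_s(a)))
  mass <- stats::integrate(function(y) vapply(y, function(yy)
    alpha(x, yy) * qd(x, yy), numeric(1)), x - 8, x + 8)$value
  expect_lt(mass, 1 + 1e-8)
})

test_that("identical surrogate and target always accept at the second level", {
  fx <- make_de_evaluator(data = NULL)
  prior <- fx$prior
  design <- fx$design
  mk <- function() posterior_evaluator(prior, NULL, design,
                                       function(th) example_media(1, th),
                                       model = "DE")
  chain <- two_level_sample(mk(), mk(), n_steps = 150, x0 = c(0.25, 6),
                            proposal_sd = c(0.02, 0.2), seed = 2)
  ct <- attr(chain, "counts")
  expect_equal(ct$n_accept, ct$n_preaccept)
})

test_that("hand-picked densities give the expected second-stage rate", {
  # mu_s = (1, 2), mu_t = (1, 1): moving 1 -> 2 pre-accepts with alpha = 1
  # and then beta = mu_s(1) mu_t(2) / (mu_s(2) mu_t(1)) = 1/2
  P2 <- two_level_kernel_oracle(c(1, 2) / 3, c(0.5, 0.5),
                                matrix(0.5, 2, 2))
  # off-diagonal transition 1 -> 2: q * alpha * beta = 0.5 * 1 * 0.5
  expect_equal(P2[1, 2], 0.25, tolerance = 1e-15)
})

test_that("target forward solves equal pre-acceptances plus initialisation", {
  g <- phase_grid(dx = 0.25, n_angles = 4, dim = 2)
  design <- experiment_design(g, epsilon = 0.5)
  prior <- prior_uniform(c(0, 0), c(0.5, 12), c("r", "h"))
  truth <- example_media(1, c(0.3, 5))
  data <- generate_data(truth, design, model = "RTE", seed = 1)
  sur <- posterior_evaluator(prior, data, design,
                             function(th) example_media(1, th), model = "DE")
  tar <- posterior_evaluator(prior, data, design,
                             function(th) example_media(1, th), model = "RTE")
  chain <- two_level_sample(sur, tar, n_steps = 60, x0 = c(0.3, 5),
                            proposal_sd = c(0.02, 0.2), seed = 9)
  ct <- attr(chain, "counts")
  expect_identical(ct$n_solves_target, ct$n_preaccept + 1L)
  expect_identical(ct$n_solves_surrogate, 60L + 1L)
  s <- acceptance_summary(chain)
  expect_equal(s$alpha_hat, ct$n_preaccept / 60)
  expect_equal(s$beta_hat, ct$n_accept / ct$n_preaccept)
})

test_that("chains are bitwise reproducible under a seed", {
  fx <- make_de_evaluator(data = NULL)
  c1 <- mh_sample(fx$ev, 50, x0 = c(0.25, 6), proposal_sd = 0.05, seed = 31)
  c2 <- mh_sample(make_de_evaluator(data = NULL)$ev, 50, x0 = c(0.25, 6),
                  proposal_sd = 0.05, seed = 31)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  mk <- function() make_de_evaluator(data = NULL)$ev
  t1 <- two_level_sample(mk(), mk(), 50, x0 = c(0.25, 6),
                         proposal_sd = 0.05, seed = 8)
  t2 <- two_level_sample(mk(), mk(), 50, x0 = c(0.25, 6),
                         proposal_sd = 0.05, seed = 8)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("acceptance summaries handle empty chains and zero pre-acceptance", {
  # no pre-accepted proposal: beta is undefined, not zero
  fake <- structure(tibble::tibble(r = 0.1),
                    counts = list(n_steps = 10, n_preaccept = 0L, n_accept = 0L,
                                  n_solves_target = 1L, n_solves_surrogate = 11L),
                    seed = 1, param_names = "r", level = "two-level")
  s <- acceptance_summary(fake)
  expect_true(is.na(s$beta_hat))
  expect_equal(s$alpha_hat, 0)
})

test_that("five-disk initial state follows the perturbation rule", {
  truth <- example2_truth()
  x0 <- initial_state_example2(truth, seed = 5)
  ratio <- x0 / truth
  expect_true(all(ratio >= 0.6 & ratio <= 1.0))
  expect_identical(x0, initial_state_example2(truth, seed = 5))
})
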