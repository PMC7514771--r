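#' Uniform box prior
#'
#' Independent uniform prior over a box; the log-density is 0 inside (up to
#' an additive constant, irrelevant for Metropolis ratios) and `-Inf`
#' outside.
#'
#' @param lower,upper Numeric vectors of equal length, `lower < upper`
#'   componentwise.
#' @param names Optional component names.
#' @return A `prior_uniform` object.
#' @export
prior_uniform <- function(lower, upper, names = NULL) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower < upper))
  if (is.null(names)) names <- paste0("theta", seq_along(lower))
  structure(list(lower = lower, upper = upper, names = names,
                 d = length(lower)),
            class = "prior_uniform")
}

#' @export
print.prior_uniform <- function(x, ...) {
  cat("<prior_uniform>\n")
  print(tibble(component = x$names, lower = x$lower, upper = x$upper))
  invisible(x)
}

# log prior density up to a constant; -Inf outside the box
log_prior <- function(prior, theta) {
  if (any(theta < prior$lower | theta > prior$upper)) -Inf else 0
}

#' Posterior evaluator binding prior, data and a forward model
#'
#' Represents the unnormalised log posterior
#' `log mu0(theta) - ||b - G(theta)||^2 / (2 gamma^2)`, where `G` is the
#' chosen forward map evaluated on the medium `builder(theta)`.  Forward
#' solves are counted (one per in-support evaluation); out-of-support
#' parameters return `-Inf` without touching the solver.  With `data = NULL`
#' the evaluator is the bare prior (useful for sampler checks against a flat
#' target).
#'
#' @param prior A [prior_uniform()].
#' @param data A `synthetic_dataset`, a measurement tibble, a numeric vector
#'   in detector-fastest order, or `NULL`.
#' @param design An [experiment_design()].
#' @param builder Function mapping a parameter vector to a `media` object,
#'   e.g. `function(th) example_media(1, th)`.
#' @param model `"DE"` or `"RTE"`.
#' @param noise_var Noise variance gamma^2 (default: the design's).
#' @return A `posterior_evaluator`.
#' @export
posterior_evaluator <- function(prior, data, design, builder,
                                model = c("DE", "RTE"), noise_var = NULL) {
  model <- match.arg(model)
  if (is.null(noise_var)) noise_var <- design$noise_var
  stopifnot(is.function(builder), noise_var > 0)
  b <- if (is.null(data)) NULL else measurement_vector(data)
  cache <- design_cache(design, model)
  env <- new.env(parent = emptyenv())
  env$n_solves <- 0L
  structure(
    list(prior = prior, data = b, design = design, builder = builder,
         model = model, noise_var = noise_var, cache = cache, env = env),
    class = "posterior_evaluator"
  )
}

#' @export
print.posterior_evaluator <- function(x, ...) {
  cat(sprintf("<posterior_evaluator> model %s | %s data | %d forward solve(s) so far\n",
              x$model, if (is.null(x$data)) "no" else length(x$data), x$env$n_solves))
  invisible(x)
}

#' Unnormalised log posterior density
#'
#' @param evaluator A [posterior_evaluator()].
#' @param theta Parameter vector.
#' @return Scalar log density (natural log, unnormalised); `-Inf` outside
#'   the prior support.
#' @export
log_posterior <- function(evaluator, theta) {
  lp <- log_prior(evaluator$prior, theta)
  if (!is.finite(lp)) return(-Inf)
  if (is.null(evaluator$data)) return(lp)
  g <- forward_vector(evaluator$builder(theta), evaluator$design,
                      evaluator$model, evaluator$cache)
  evaluator$env$n_solves <- evaluator$env$n_solves + 1L
  lp - sum((evaluator$data - g)^2) / (2 * evaluator$noise_var)
}

# number of forward-map evaluations performed so far
n_forward_solves <- function(evaluator) evaluator$env$n_solves

new_chain <- function(draws, extra, counts, seed, proposal_sd, level) {
  tbl <- as_tibble(draws)
  tbl <- dplyr::bind_cols(tbl, as_tibble(extra))
  structure(tbl,
            class = c("mcmc_chain", class(tbl)),
            counts = counts, seed = seed, param_names = colnames(draws),
            proposal_sd = proposal_sd, level = level)
}

#' One-level random-walk Metropolis-Hastings
#'
#' Symmetric componentwise Gaussian random walk targeting the (unnormalised)
#' posterior of `evaluator`; acceptance probability
#' `min(1, mu(y) / mu(x))`, computed in log space.  Out-of-support proposals
#' are rejected outright.
#'
#' @param evaluator A [posterior_evaluator()].
#' @param n_steps Number of proposals.
#' @param x0 Initial state (must have finite posterior density).
#' @param proposal_sd Componentwise proposal standard deviations.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return An `mcmc_chain` tibble: one row per step (step 0 is the initial
#'   state) with the parameter columns, `log_post` and an `accepted` flag;
#'   acceptance counts, seed and solver counts are attached as attributes
#'   and summarised by [acceptance_summary()] / [glance()].
#' @export
mh_sample <- function(evaluator, n_steps, x0, proposal_sd, seed = NULL) {
  d <- evaluator$prior$d
  stopifnot(length(x0) == d, length(proposal_sd) %in% c(1L, d),
            all(proposal_sd > 0), n_steps >= 0)
  if (length(proposal_sd) == 1L) proposal_sd <- rep(proposal_sd, d)
  if (!is.null(seed)) set.seed(seed)
  lt_x <- log_posterior(evaluator, x0)
  if (!is.finite(lt_x)) abort("x0 lies outside the prior support")
  draws <- matrix(NA_real_, n_steps + 1L, d,
                  dimnames = list(NULL, evaluator$prior$names))
  draws[1L, ] <- x0
  lp <- numeric(n_steps + 1L); lp[1L] <- lt_x
  acc <- logical(n_steps + 1L)
  x <- x0
  n_accept <- 0L
  for (s in seq_len(n_steps)) {
    y <- x + rnorm(d, 0, proposal_sd)
    lt_y <- log_posterior(evaluator, y)
    log_alpha <- min(0, lt_y - lt_x)
    if (is.finite(lt_y) && log(runif(1)) < log_alpha) {
      x <- y; lt_x <- lt_y; n_accept <- n_accept + 1L; acc[s + 1L] <- TRUE
    }
    draws[s + 1L, ] <- x
    lp[s + 1L] <- lt_x
  }
  new_chain(draws,
            list(log_post = lp, accepted = acc),
            counts = list(n_steps = n_steps, n_accept = n_accept,
                          n_solves_target = n_forward_solves(evaluator)),
            seed = seed, proposal_sd = proposal_sd, level = "one-level")
}

#' Delayed-acceptance two-level Metropolis-Hastings
#'
#' Level 1 runs the standard Metropolis accept test under the cheap surrogate
#' posterior (acceptance `alpha`); only pre-accepted proposals reach level 2,
#' where the second-stage probability uses the closed form
#' `beta = min(1, mu_sur(x) mu_tar(y) / (mu_sur(y) mu_tar(x)))`
#' (never the integral form of the effective proposal).  The expensive target
#' forward map is therefore evaluated once per pre-accepted proposal plus
#' once for the initial state.  Both densities of the current state are
#' cached, so no state is ever re-solved.
#'
#' @param surrogate,target [posterior_evaluator()]s sharing design and data
#'   (typically `model = "DE"` and `model = "RTE"`).
#' @param n_steps,x0,proposal_sd,seed As in [mh_sample()].
#' @return An `mcmc_chain` tibble with columns for the parameters,
#'   `log_post` (target), `log_post_surrogate`, and `pre_accepted` /
#'   `accepted` flags.
#' @export
two_level_sample <- function(surrogate, target, n_steps, x0, proposal_sd,
                             seed = NULL) {
  d <- surrogate$prior$d
  stopifnot(length(x0) == d, length(proposal_sd) %in% c(1L, d),
            all(proposal_sd > 0), n_steps >= 0)
  if (length(proposal_sd) == 1L) proposal_sd <- rep(proposal_sd, d)
  if (!is.null(seed)) set.seed(seed)
  ls_x <- log_posterior(surrogate, x0)
  lt_x <- log_posterior(target, x0)
  if (!is.finite(ls_x) || !is.finite(lt_x)) abort("x0 lies outside the prior support")
  draws <- matrix(NA_real_, n_steps + 1L, d,
                  dimnames = list(NULL, surrogate$prior$names))
  draws[1L, ] <- x0
  lt <- numeric(n_steps + 1L); lt[1L] <- lt_x
  ls <- numeric(n_steps + 1L); ls[1L] <- ls_x
  pre <- logical(n_steps + 1L); acc <- logical(n_steps + 1L)
  x <- x0
  n_pre <- 0L; n_accept <- 0L
  for (s in seq_len(n_steps)) {
    y <- x + rnorm(d, 0, proposal_sd)
    ls_y <- log_posterior(surrogate, y)
    log_alpha <- min(0, ls_y - ls_x)
    if (is.finite(ls_y) && log(runif(1)) < log_alpha) {
      pre[s + 1L] <- TRUE; n_pre <- n_pre + 1L
      lt_y <- log_posterior(target, y)
      log_beta <- min(0, (lt_y - lt_x) - (ls_y - ls_x))
      if (is.finite(lt_y) && log(runif(1)) < log_beta) {
        acc[s + 1L] <- TRUE; n_accept <- n_accept + 1L
        x <- y; ls_x <- ls_y; lt_x <- lt_y
      }
    }
    draws[s + 1L, ] <- x
    lt[s + 1L] <- lt_x
    ls[s + 1L] <- ls_x
  }
  new_chain(draws,
            list(log_post = lt, log_post_surrogate = ls,
                 pre_accepted = pre, accepted = acc),
            counts = list(n_steps = n_steps, n_preaccept = n_pre,
                          n_accept = n_accept,
                          n_solves_target = n_forward_solves(target),
                          n_solves_surrogate = n_forward_solves(surrogate)),
            seed = seed, proposal_sd = proposal_sd, level = "two-level")
}

#' Acceptance-rate summary of a chain
#'
#' For one-level chains, the acceptance rate `r1 = n_accept / n_steps`.  For
#' two-level chains, the pre-acceptance rate `alpha_hat =
#' n_preaccept / n_steps` and the second-level rate `beta_hat =
#' n_accept / n_preaccept` (reported as `NA` when nothing was pre-accepted),
#' plus forward-solve counts for both levels.
#'
#' @param chain An `mcmc_chain`.
#' @return A one-row tibble.
#' @export
acceptance_summary <- function(chain) {
  ct <- attr(chain, "counts")
  if (attr(chain, "level") == "one-level") {
    tibble(
      level = "one-level", n_steps = ct$n_steps, n_accept = ct$n_accept,
      r1 = if (ct$n_steps > 0) ct$n_accept / ct$n_steps else NA_real_,
      n_solves_target = ct$n_solves_target
    )
  } else {
    tibble(
      level = "two-level", n_steps = ct$n_steps,
      n_preaccept = ct$n_preaccept, n_accept = ct$n_accept,
      alpha_hat = if (ct$n_steps > 0) ct$n_preaccept / ct$n_steps else NA_real_,
      beta_hat = if (ct$n_preaccept > 0) ct$n_accept / ct$n_preaccept else NA_real_,
      n_solves_target = ct$n_solves_target,
      n_solves_surrogate = ct$n_solves_surrogate
    )
  }
}

#' Samplers on a finite state space
#'
#' Discrete adapters running the same Metropolis and delayed-acceptance
#' logic on a finite state space with an explicit proposal matrix `q`
#' (rows sum to 1).  These exist so the samplers can be checked exactly
#' against hand-built transition kernels: detailed balance, stationarity of
#' the target, and the closed-form second-stage rate.
#'
#' @param target Target probability vector (need not be normalised).
#' @param q Proposal matrix, `q[x, y]` the probability of proposing `y`
#'   from `x`.
#' @param n_steps Number of proposals.
#' @param x0 Initial state index.
#' @param seed Integer seed, or `NULL`.
#' @return Integer vector of visited states, length `n_steps + 1`; the
#'   two-level version attaches `n_preaccept` / `n_accept` attributes.
#' @export
mh_sample_discrete <- function(target, q, n_steps, x0 = 1L, seed = NULL) {
  stopifnot(all(target >= 0), nrow(q) == length(target),
            ncol(q) == length(target))
  if (!is.null(seed)) set.seed(seed)
  x <- as.integer(x0)
  out <- integer(n_steps + 1L); out[1L] <- x
  for (s in seq_len(n_steps)) {
    y <- sample.int(length(target), 1L, prob = q[x, ])
    alpha <- min(1, (q[y, x] * target[y]) / (q[x, y] * target[x]))
    if (runif(1) < alpha) x <- y
    out[s + 1L] <- x
  }
  out
}

#' @rdname mh_sample_discrete
#' @param surrogate Surrogate probability vector used at the first level.
#' @export
two_level_sample_discrete <- function(surrogate, target, q, n_steps,
                                      x0 = 1L, seed = NULL) {
  stopifnot(length(surrogate) == length(target))
  if (!is.null(seed)) set.seed(seed)
  x <- as.integer(x0)
  out <- integer(n_steps + 1L); out[1L] <- x
  n_pre <- 0L; n_acc <- 0L
  for (s in seq_len(n_steps)) {
    y <- sample.int(length(target), 1L, prob = q[x, ])
    alpha <- min(1, (q[y, x] * surrogate[y]) / (q[x, y] * surrogate[x]))
    if (runif(1) < alpha) {
      n_pre <- n_pre + 1L
      beta <- min(1, (surrogate[x] * target[y]) / (surrogate[y] * target[x]))
      if (runif(1) < beta) { x <- y; n_acc <- n_acc + 1L }
    }
    out[s + 1L] <- x
  }
  structure(out, n_preaccept = n_pre, n_accept = n_acc)
}

#' Perturbed initial state for the five-disk reconstruction
#'
#' Applies the rule `theta0_i = (0.6 + 0.4 * u_i) * truth_i`,
#' `u_i ~ U(0, 1)`, to every component: an initial guess up to 40% below the
#' truth.
#'
#' @param truth True parameter vector (default [example2_truth()]).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return Numeric vector like `truth`.
#' @export
initial_state_example2 <- function(truth = example2_truth(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  (0.6 + 0.4 * runif(length(truth))) * truth
}
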