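#' Run configuration for the reconstruction experiments
#'
#' Validated bag of settings shared by the runners: experiment id, grid,
#' Knudsen number, sampler settings and noise level.  Configurations
#' round-trip through JSON ([write_run_config()] / [read_run_config()]) and
#' carry a content hash that is recorded in every output.
#'
#' Defaults follow the reference configurations: `dx = 0.05`,
#' `dv = 2 pi / 16`, noise variance 1e-4, 1000 sampler steps, uniform priors
#' (`r` in `[0, 0.5]`, `h` in `[8, 12]` for the single-disk example; truth-
#' centred boxes `[0, 2 * truth_i]` per component for the five-disk example,
#' see the methods vignette), and componentwise Gaussian random-walk widths
#' calibrated per example so that one-level sampling of the transport
#' posterior reproduces the reference acceptance rate `r1` (the only reported
#' information about the proposal): `(0.08, 0.8)` for `(r, h)` in the
#' single-disk example, and 0.01 / 0.1 for radii / heights in the five-disk
#' example.
#'
#' @param example 1 (single disk, parameters `r, h`) or 2 (five disks,
#'   parameters `h1..h5, r1..r5`).
#' @param epsilon Knudsen number.
#' @param dx,n_angles Grid resolution.
#' @param n_steps Number of MCMC proposals.
#' @param seed Integer seed driving data generation, initialisation and the
#'   chain.
#' @param noise_var Measurement noise variance.
#' @param proposal_sd Optional override of the componentwise proposal widths.
#' @param prior_lower,prior_upper Optional override of the prior box.
#' @param burn_in Draws dropped from the front of the chain in summaries
#'   (default 0: raw chains are reported).
#' @param data_model Forward model generating the synthetic data
#'   (default `"RTE"`).
#' @return A `run_config` list.
#' @export
run_config <- function(example = 1, epsilon = 2^-6, dx = 0.05, n_angles = 16,
                       n_steps = 1000, seed = 1, noise_var = 1e-4,
                       proposal_sd = NULL, prior_lower = NULL,
                       prior_upper = NULL, burn_in = 0,
                       data_model = "RTE") {
  stopifnot(example %in% c(1, 2), epsilon > 0, n_steps >= 0, noise_var >= 0,
            burn_in >= 0, data_model %in% c("RTE", "DE"))
  if (example == 1) {
    names <- c("r", "h")
    if (is.null(prior_lower)) prior_lower <- c(0, 8)
    if (is.null(prior_upper)) prior_upper <- c(0.5, 12)
    # random-walk widths calibrated so the one-level transport chain
    # reproduces the reference acceptance rate r1 (~0.73 here); see vignette
    if (is.null(proposal_sd)) proposal_sd <- c(0.08, 0.8)
  } else {
    # five-disk prior: uniform boxes centred at the truth, [0, 2 * truth_i]
    # per component (the reference posterior moments sit at the truth with
    # prior-scale spread, which pins this centring; see the methods vignette)
    names <- names(example2_truth())
    if (is.null(prior_lower)) prior_lower <- rep(0, 10)
    if (is.null(prior_upper)) prior_upper <- 2 * unname(example2_truth())
    # widths calibrated to the reference one-level rate r1 (~0.78 here)
    if (is.null(proposal_sd)) proposal_sd <- c(rep(0.1, 5), rep(0.01, 5))
  }
  cfg <- list(
    example = example, epsilon = epsilon, dx = dx, n_angles = n_angles,
    n_steps = n_steps, seed = as.integer(seed), noise_var = noise_var,
    proposal_sd = proposal_sd, prior_lower = prior_lower,
    prior_upper = prior_upper, param_names = names,
    burn_in = burn_in, data_model = data_model
  )
  # hash the canonical JSON form so integer/double storage does not matter
  cfg$hash <- rlang::hash(as.character(jsonlite::toJSON(
    cfg[setdiff(names(cfg), "hash")], auto_unbox = TRUE, digits = NA)))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(config)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj[setdiff(names(obj), c("hash", "param_names"))])
}

config_builder <- function(config) {
  ex <- config$example
  function(theta) example_media(ex, theta)
}

config_truth <- function(config) {
  if (config$example == 1) c(r = 0.4, h = 10) else example2_truth()
}

#' Forward diffusion-limit convergence study
#'
#' Solves the transport equation across a ladder of Knudsen numbers and the
#' limiting diffusion equation once, and reports the L2(dx) distance between
#' the velocity-averaged transport density and the diffusion solution.  The
#' slab configuration (default) uses the three-bump medium with unit
#' isotropic inflow on the left boundary and vacuum (zero) inflow on the
#' right, and matching Dirichlet data 1 / 0; the 2-D configuration uses a
#' disk medium with the analogous left-edge data.
#'
#' @param epsilons Knudsen-number ladder (default the reference ladder
#'   `1, 1/2, 1/4, 1/16, 1/32, 1/64`).
#' @param media Medium (default [three_bump_medium()] for `dim = 1`,
#'   `example_media(1, c(0.4, 10))` for `dim = 2`).
#' @param dx,n_angles Grid resolution.
#' @param dim 1 (slab) or 2 (unit square).
#' @return A tibble with one row per epsilon: `epsilon`, `l2_error`.  The
#'   diffusion field and the per-epsilon transport densities are attached as
#'   attributes `rho_de` and `rho_rte`.
#' @export
run_forward_convergence <- function(epsilons = c(1, 1/2, 1/4, 1/16, 1/32, 1/64),
                                    media = NULL, dx = 0.05, n_angles = 16,
                                    dim = 1) {
  stopifnot(length(epsilons) >= 1, all(epsilons > 0))
  grid <- phase_grid(dx = dx, n_angles = n_angles, dim = dim)
  if (is.null(media)) {
    media <- if (dim == 1) three_bump_medium() else example_media(1, c(0.4, 10))
  }
  xi <- dirichlet_sides(grid, left = 1)
  de <- solve_de(grid, media, xi)
  phi <- inflow_sides(grid, left = 1)
  rho_list <- lapply(epsilons, function(eps) {
    sys <- assemble_rte(grid, media, eps, phi)
    sol <- solve_rte(sys)
    fluence_vec(sol$f, grid$weights)
  })
  errs <- vapply(rho_list, function(r) l2_error(r, de$rho, grid = grid), numeric(1))
  out <- tibble(epsilon = epsilons, l2_error = errs)
  attr(out, "rho_de") <- de$rho
  attr(out, "rho_rte") <- rho_list
  attr(out, "grid") <- grid
  out
}

#' Bayesian reconstruction runner
#'
#' End-to-end inversion for one configuration: generates seeded synthetic
#' data with the configured forward model, builds the diffusion and transport
#' posteriors, runs the requested sampler, and returns the chain plus an
#' acceptance summary.  With an output directory, the chain (CSV), the
#' summary and resolved configuration (JSON) are written alongside.
#'
#' All randomness derives from `config$seed`: the noise draw, the initial
#' state of the five-disk example (the `(0.6 + 0.4 u) * truth` rule) and the
#' chain itself.
#'
#' @param config A [run_config()].
#' @param method `"two-level"` (surrogate-filtered transport posterior) or
#'   `"one-level"`.
#' @param model For `method = "one-level"`, which posterior to sample
#'   (`"RTE"` or `"DE"`; two-level always filters the RTE target through the
#'   DE surrogate).
#' @param outdir Optional output directory.
#' @return A list with elements `chain` (an `mcmc_chain`), `summary`
#'   (one-row tibble), `data` (the `synthetic_dataset`) and `config`.
#' @export
run_inversion <- function(config, method = c("two-level", "one-level"),
                          model = "RTE", outdir = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(config, "run_config"))
  grid <- phase_grid(dx = config$dx, n_angles = config$n_angles, dim = 2)
  design <- experiment_design(grid, epsilon = config$epsilon,
                              noise_var = config$noise_var)
  builder <- config_builder(config)
  truth <- config_truth(config)
  set.seed(config$seed)
  dataset <- generate_data(builder(truth), design, model = config$data_model,
                           seed = config$seed)
  prior <- prior_uniform(config$prior_lower, config$prior_upper,
                         names = config$param_names)
  x0 <- if (config$example == 1) {
    (config$prior_lower + config$prior_upper) / 2
  } else {
    initial_state_example2(truth)
  }
  if (config$n_steps == 0) {
    chain <- NULL
    summary <- tibble(level = method, n_steps = 0L,
                      r1 = NA_real_, alpha_hat = NA_real_, beta_hat = NA_real_)
  } else if (method == "two-level") {
    sur <- posterior_evaluator(prior, dataset, design, builder, model = "DE")
    tar <- posterior_evaluator(prior, dataset, design, builder, model = "RTE")
    chain <- two_level_sample(sur, tar, n_steps = config$n_steps, x0 = x0,
                              proposal_sd = config$proposal_sd)
    summary <- acceptance_summary(chain)
  } else {
    ev <- posterior_evaluator(prior, dataset, design, builder, model = model)
    chain <- mh_sample(ev, n_steps = config$n_steps, x0 = x0,
                       proposal_sd = config$proposal_sd)
    summary <- acceptance_summary(chain)
  }
  summary$config_hash <- config$hash
  summary$seed <- config$seed
  res <- list(chain = chain, summary = summary, data = dataset,
              config = config, truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(chain)) {
      utils::write.csv(as.data.frame(chain),
                       file.path(outdir, "chain.csv"), row.names = FALSE)
    }
    jsonlite::write_json(as.list(summary), file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_run_config(config, file.path(outdir, "config.json"))
  }
  res
}

#' Compare two sampled posteriors
#'
#' Smooths both chains with a Gaussian-kernel density estimate on a shared
#' grid over the prior box and reports the Hellinger distance and the two
#' KL divergences.  For chains with more than two parameters, name the
#' `components` to compare (the joint marginal of those components is used),
#' e.g. `c("r1", "r4")` for the five-disk example.
#'
#' @param chain_a,chain_b `mcmc_chain` objects over the same parameter box.
#' @param lower,upper Box bounds for the compared components.
#' @param components Parameter column names to compare (default: all).
#' @param cells Grid cells per dimension.
#' @param bandwidth Optional KDE bandwidth override (per dimension).
#' @param burn_in Draws dropped from the front of each chain.
#' @return A one-row tibble: `hellinger`, `kl_ab`, `kl_ba`.
#' @export
run_compare <- function(chain_a, chain_b, lower, upper, components = NULL,
                        cells = 100, bandwidth = NULL, burn_in = 0) {
  sa <- chain_draws(chain_a, components, burn_in)
  sb <- chain_draws(chain_b, components, burn_in)
  if (!identical(colnames(sa), colnames(sb))) {
    abort("chains have different parameterisations")
  }
  pa <- kde_density(sa, lower, upper, cells = cells, bandwidth = bandwidth)
  pb <- kde_density(sb, lower, upper, cells = cells, bandwidth = bandwidth)
  tibble(
    hellinger = hellinger(pa, pb),
    kl_ab = kl_divergence(pa, pb),
    kl_ba = kl_divergence(pb, pa)
  )
}

# draw matrix of selected components
chain_draws <- function(chain, components = NULL, burn_in = 0) {
  pn <- attr(chain, "param_names")
  if (is.null(pn)) {
    pn <- setdiff(names(chain), c("log_post", "log_post_surrogate",
                                  "pre_accepted", "accepted"))
  }
  if (is.null(components)) components <- pn
  if (!all(components %in% pn)) abort("unknown component name(s)")
  m <- as.matrix(as.data.frame(chain)[, components, drop = FALSE])
  if (burn_in > 0) m <- m[-seq_len(min(burn_in, nrow(m) - 1L)), , drop = FALSE]
  m
}

#' Cost report for a two-level run
#'
#' Combines measured per-evaluation solve costs ([measure_costs()]) with the
#' empirical acceptance rates of a one-level and a two-level chain into the
#' cost model ([cost_model()]).
#'
#' @param one_level,two_level Results from [run_inversion()].
#' @param costs Optional one-row tibble with `c_d`, `c_r` (measured if
#'   omitted).
#' @return The [cost_model()] tibble.
#' @export
run_cost_report <- function(one_level, two_level, costs = NULL) {
  s1 <- one_level$summary; s2 <- two_level$summary
  if (is.null(costs)) {
    cfg <- two_level$config
    grid <- phase_grid(dx = cfg$dx, n_angles = cfg$n_angles, dim = 2)
    design <- experiment_design(grid, epsilon = cfg$epsilon,
                                noise_var = cfg$noise_var)
    costs <- measure_costs(config_builder(cfg)(config_truth(cfg)), design)
  }
  cost_model(r1 = s1$r1, beta = s2$beta_hat, c_d = costs$c_d,
             c_r = costs$c_r, alpha = s2$alpha_hat)
}
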