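#' Tidy summaries of MCMC chains
#'
#' `tidy()` returns one row per parameter with posterior mean, standard
#' deviation and central quantiles; `glance()` returns the one-row
#' acceptance summary (see [acceptance_summary()]).
#'
#' @param x An `mcmc_chain`.
#' @param burn_in Draws dropped from the front of the chain.
#' @param conf_level Width of the reported central interval.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mcmc_chain
#' @export
tidy.mcmc_chain <- function(x, burn_in = 0, conf_level = 0.95, ...) {
  m <- chain_draws(x, burn_in = burn_in)
  a <- (1 - conf_level) / 2
  tibble(
    term = colnames(m),
    mean = apply(m, 2, mean),
    sd = apply(m, 2, stats::sd),
    conf.low = apply(m, 2, stats::quantile, probs = a),
    conf.high = apply(m, 2, stats::quantile, probs = 1 - a)
  )
}

#' @rdname tidy.mcmc_chain
#' @method glance mcmc_chain
#' @export
glance.mcmc_chain <- function(x, ...) {
  acceptance_summary(x)
}

#' Trace plot of an MCMC chain
#'
#' @param object An `mcmc_chain`.
#' @param ... Unused.
#' @return A ggplot object, one facet per parameter.
#' @method autoplot mcmc_chain
#' @export
autoplot.mcmc_chain <- function(object, ...) {
  pn <- attr(object, "param_names")
  df <- as_tibble(as.data.frame(object))
  df$step <- seq_len(nrow(df)) - 1L
  long <- tidyr::pivot_longer(df[, c("step", pn)], cols = dplyr::all_of(pn),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "step", y = NULL)
}

#' Plot a grid density
#'
#' @param object A `grid_density` from [kde_density()].
#' @param ... Unused.
#' @return A ggplot object: a line in 1-D, a filled raster in 2-D.
#' @method autoplot grid_density
#' @export
autoplot.grid_density <- function(object, ...) {
  nm <- attr(object, "dim_names")
  if (!"x2" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$x1, y = .data$density)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = nm[1], y = "density")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$x1, y = .data$x2,
                                         fill = .data$density)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = nm[1], y = nm[2], fill = "density")
  }
}

#' Plot a phase-space transport solution
#'
#' @param object A `phase_solution`.
#' @param ... Unused.
#' @return A ggplot object: `f(x, theta)` as a raster for slab solutions,
#'   the fluence field for 2-D solutions.
#' @method autoplot phase_solution
#' @export
autoplot.phase_solution <- function(object, ...) {
  if (object$grid$dim == 1L) {
    df <- tidyr::expand_grid(theta = object$grid$theta, x = object$grid$xs)
    df <- df[order(df$theta, df$x), ]
    df$f <- as.numeric(object$f)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$theta,
                                     fill = .data$f)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "x", y = expression(theta), fill = "f")
  } else {
    df <- fluence(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$rho)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "x", y = "y", fill = expression(rho))
  }
}

#' Plot a forward-convergence error ladder
#'
#' @param errors Tibble from [run_forward_convergence()].
#' @return A log-log ggplot of the error against the Knudsen number.
#' @export
plot_convergence <- function(errors) {
  ggplot2::ggplot(errors, ggplot2::aes(x = .data$epsilon, y = .data$l2_error)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(epsilon), y = expression(L^2 ~ error))
}
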