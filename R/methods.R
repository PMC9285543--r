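#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
print.ppm_fit <- function(x, ...) {
  cat("Phylogenetic predictive model (Brownian-motion regression)\n")
  cat(sprintf("  observed tips: %d   posterior draws: %d (%d chain%s)\n",
              length(x$taxa), nrow(x$draws), x$config$chains,
              if (x$config$chains > 1) "s" else ""))
  cat(sprintf("  lambda: %s\n",
              if (x$lambda_mode == "fixed")
                sprintf("fixed at %g", x$lambda_value) else "estimated"))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy posterior parameter summaries of a PPM fit
#'
#' @param x A `ppm_fit` object.
#' @param level Central credible-interval level (default 0.95).
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term, estimate`
#'   (posterior mean), `std.error` (posterior SD), `conf.low`, `conf.high`.
#' @method tidy ppm_fit
#' @export
tidy.ppm_fit <- function(x, level = 0.95, ...) {
  a <- (1 - level) / 2
  terms <- c("alpha", "beta", "sigma2", "lambda")
  purrr::map_dfr(terms, function(tm) {
    v <- x$draws[[tm]]
    tibble::tibble(term = tm, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)))
  })
}

#' @method glance ppm_fit
#' @export
glance.ppm_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = length(x$taxa), n_draws = nrow(x$draws),
    chains = x$config$chains, lambda_mode = x$lambda_mode,
    seed = x$config$seed
  )
}

#' @method autoplot ppm_fit
#' @export
autoplot.ppm_fit <- function(object, n_lines = 50, ...) {
  obs <- object$data[is.finite(object$data$y), ]
  dr <- object$draws
  idx <- unique(round(seq(1, nrow(dr), length.out = min(n_lines, nrow(dr)))))
  lines <- dr[idx, c("alpha", "beta")]
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$alpha,
                                      slope = .data$beta),
                         alpha = 0.1, colour = "steelblue") +
    ggplot2::geom_abline(intercept = mean(dr$alpha), slope = mean(dr$beta),
                         colour = "steelblue4", linewidth = 0.8) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predictor (log10 skull width, mm)",
                  y = "response (log10 A_Phys, mm^2)",
                  title = "Phylogenetic regression: posterior of the line")
}

#' @export
print.ppm_prediction <- function(x, ...) {
  cat(sprintf(
    "Posterior predictive distributions for %d target tip%s (%d draws each)\n",
    ncol(x$draws), if (ncol(x$draws) > 1) "s" else "", nrow(x$draws)))
  print(x$summary, ...)
  invisible(x)
}

#' @method tidy ppm_prediction
#' @export
tidy.ppm_prediction <- function(x, ...) {
  x$summary
}

#' @method autoplot ppm_prediction
#' @export
autoplot.ppm_prediction <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$x, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo,
                                          ymax = .data$hi)) +
    ggplot2::labs(x = "predictor (log10 skull width, mm)",
                  y = "predicted response (log10 A_Phys, mm^2)",
                  title = sprintf("Posterior predictive medians with %g%% intervals",
                                  100 * object$level))
}

#' @export
print.ppm_loocv <- function(x, ...) {
  cat(sprintf(
    "Leave-one-out cross-validation: accuracy %.3f (%d/%d folds pass at p_mcmc >= %g)\n",
    x$accuracy, sum(x$folds$pass), nrow(x$folds), x$threshold))
  print(x$folds, ...)
  invisible(x)
}

#' @method tidy ppm_loocv
#' @export
tidy.ppm_loocv <- function(x, ...) {
  x$folds
}

#' @method glance ppm_loocv
#' @export
glance.ppm_loocv <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, n_folds = nrow(x$folds),
    n_pass = sum(x$folds$pass), threshold = x$threshold,
    seed = x$config$seed
  )
}

#' @method autoplot ppm_loocv
#' @export
autoplot.ppm_loocv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$observed, y = .data$median,
                               colour = .data$pass)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo,
                                          ymax = .data$hi)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue4",
                                            `FALSE` = "firebrick")) +
    ggplot2::labs(x = "observed response", y = "predictive median",
                  title = sprintf("LOOCV: accuracy %.2f", object$accuracy))
}

#' Bite force versus skull width scatter
#'
#' Convenience plot relating estimated bite forces to skull width on
#' log-log axes, optionally coloured by a `source` column (e.g. predicted
#' vs reconstructed areas).
#'
#' @param bite A tibble from [bite_force()] joined with a `w_sk_mm` column
#'   (skull width in mm) and optionally `source`.
#' @param which `"posterior"` (default, `F_BPost_N`) or `"anterior"`.
#' @return A ggplot object.
#' @export
plot_bite_force <- function(bite, which = c("posterior", "anterior")) {
  which <- match.arg(which)
  require_columns(bite, c("taxon", "w_sk_mm"), "bite-force table")
  ycol <- if (which == "posterior") "F_BPost_N" else "F_BAnt_N"
  p <- ggplot2::ggplot(bite,
                       ggplot2::aes(x = .data$w_sk_mm, y = .data[[ycol]]))
  if ("source" %in% names(bite)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$source))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "skull width (mm)",
                  y = sprintf("%s bite force (N)", which),
                  title = "Bite force vs skull width")
}

#' @importFrom stats sd predict
NULL
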