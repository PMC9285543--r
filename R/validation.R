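#' Posterior predictive p-value of an observed response
#'
#' Two-tailed by default: `p = 2 * min(#{draws <= obs}, #{draws >= obs}) /
#' #draws`, capped at 1, with ties counted inclusively on both sides. An
#' observed value beyond every draw gives p = 0; values near the predictive
#' median give p near 1. `tail = "one"` returns the smaller tail probability
#' without the factor 2. The statistic is rank-based and therefore invariant
#' under any strictly monotone transform applied jointly to draws and
#' observation.
#'
#' @param draws Numeric vector of posterior predictive draws (>= 100
#'   recommended for resolution at the 0.05 threshold).
#' @param observed The observed response value.
#' @param tail `"two"` (default) or `"one"`.
#' @return A probability in `[0, 1]`.
#' @examples
#' p_mcmc(1:1000, 975)  # 0.052
#' @export
p_mcmc <- function(draws, observed, tail = c("two", "one")) {
  tail <- match.arg(tail)
  draws <- as.numeric(draws)
  if (length(draws) == 0) stop_phybite("`draws` must be non-empty.")
  check_number(observed, "observed")
  if (length(draws) < 100) {
    rlang::warn("Fewer than 100 predictive draws; p_mcmc is coarse.")
  }
  lo <- sum(draws <= observed)
  hi <- sum(draws >= observed)
  p1 <- min(lo, hi) / length(draws)
  if (tail == "one") min(p1, 1) else min(2 * p1, 1)
}

#' Leave-one-out cross-validation of a phylogenetic predictive model
#'
#' For each taxon with an observed response: the model is refit on the
#' remaining N - 1 taxa, the left-out tip's posterior predictive
#' distribution is generated from its predictor value and phylogenetic
#' position, and the observed response is scored with [p_mcmc()]. A
#' prediction fails when the observation falls beyond 95% of the predictive
#' distribution (`p_mcmc < threshold`); overall accuracy is the passing
#' fraction of all folds. Each fold runs under a seed derived
#' deterministically from the master seed and the taxon name, so folds are
#' order-independent.
#'
#' Folds whose reduced covariance is singular are recorded as failed folds
#' (with the reason in `note`), not raised.
#'
#' @inheritParams fit_ppm
#' @param threshold Failure threshold on `p_mcmc` (default 0.05; a fold
#'   passes at `p_mcmc >= threshold`).
#' @param tail Tail convention for [p_mcmc()].
#' @param progress Print per-fold progress.
#' @return An object of class `ppm_loocv`: per-taxon tibble in `$folds`
#'   (`taxon, observed, median, lo, hi, p_mcmc, pass, note`) and `$accuracy`.
#' @export
loocv <- function(data, tree, config = ppm_config(),
                  lambda = c("fixed", "estimate"), lambda_value = 1,
                  threshold = 0.05, tail = c("two", "one"),
                  progress = FALSE) {
  lambda <- match.arg(lambda)
  tail <- match.arg(tail)
  check_number(threshold, "threshold", lower = 0, upper = 1)
  data <- validate_trait_table(data, require_y = TRUE)
  obs_idx <- which(is.finite(data$y))
  folds <- purrr::map_dfr(obs_idx, function(i) {
    taxon <- data$taxon[i]
    observed <- data$y[i]
    fold_seed <- derive_seed(config$seed, taxon)
    cfg <- config
    cfg$seed <- fold_seed
    res <- tryCatch({
      d <- data
      d$y[i] <- NA_real_
      fit <- fit_ppm(d, tree, cfg, lambda = lambda,
                     lambda_value = lambda_value)
      pred <- predict_tip(fit, taxon, seed = derive_seed(fold_seed, "pp"))
      p <- p_mcmc(pred$draws[, 1], observed, tail = tail)
      tibble::tibble(
        taxon = taxon, observed = observed,
        median = pred$summary$median, lo = pred$summary$lo,
        hi = pred$summary$hi, p_mcmc = p, pass = p >= threshold,
        note = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(taxon = taxon, observed = observed,
                     median = NA_real_, lo = NA_real_, hi = NA_real_,
                     p_mcmc = NA_real_, pass = FALSE,
                     note = conditionMessage(e))
    })
    if (progress) {
      message(sprintf("fold %s: p_mcmc = %s", taxon,
                      format(res$p_mcmc, digits = 3)))
    }
    res
  })
  structure(
    list(folds = folds, accuracy = mean(folds$pass),
         threshold = threshold, config = config, tail = tail),
    class = "ppm_loocv"
  )
}

#' Accuracy of externally supplied predictions against observations
#'
#' Applies the LOOCV pass rule (`p_mcmc >= threshold`) to a set of posterior
#' predictive distributions and matching observed responses, e.g. fossil
#' taxa whose reconstructed areas were withheld from the training set.
#'
#' @param predictions A `ppm_prediction` object (from [predict_batch()]).
#' @param observed A data frame with columns `taxon` and `y`, one row per
#'   prediction target.
#' @param threshold Failure threshold (default 0.05).
#' @param tail Tail convention for [p_mcmc()].
#' @return A list with `$scores` (tibble `taxon, observed, median, p_mcmc,
#'   pass`), `$accuracy`, and `$failed` (names of failing taxa).
#' @export
held_out_accuracy <- function(predictions, observed, threshold = 0.05,
                              tail = c("two", "one")) {
  stopifnot(inherits(predictions, "ppm_prediction"))
  tail <- match.arg(tail)
  require_columns(observed, c("taxon", "y"), "observed table")
  observed <- tibble::as_tibble(observed)
  observed$taxon <- norm_label(observed$taxon)
  pred_taxa <- colnames(predictions$draws)
  if (!setequal(pred_taxa, observed$taxon) ||
      length(pred_taxa) != nrow(observed)) {
    stop_phybite("Taxon mismatch between predictions and observations.")
  }
  idx <- match(pred_taxa, observed$taxon)
  scores <- purrr::map_dfr(seq_along(pred_taxa), function(j) {
    p <- p_mcmc(predictions$draws[, j], observed$y[idx[j]], tail = tail)
    tibble::tibble(taxon = pred_taxa[j], observed = observed$y[idx[j]],
                   median = predictions$summary$median[j],
                   p_mcmc = p, pass = p >= threshold)
  })
  list(scores = scores, accuracy = mean(scores$pass),
       failed = scores$taxon[!scores$pass])
}
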