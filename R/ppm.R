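#' MCMC configuration for phylogenetic predictive models
#'
#' Holds chain settings for [fit_ppm()]. Defaults give 1,000 pooled posterior
#' draws (500 retained per chain over two chains); the conjugate Gibbs
#' sampler mixes within a few sweeps, so long chains are only needed when the
#' phylogenetic-signal parameter lambda is estimated by Metropolis steps.
#'
#' @param iterations Total MCMC iterations per chain.
#' @param burnin Iterations discarded from the start of each chain
#'   (`burnin < iterations`).
#' @param thin Thinning interval (every `thin`-th post-burn-in iteration is
#'   retained; `>= 1`).
#' @param chains Number of independent chains (`>= 1`), pooled in the
#'   posterior sample.
#' @param seed Master seed; chain and prediction seeds are derived from it
#'   deterministically.
#' @return A list of class `ppm_config`.
#' @export
ppm_config <- function(iterations = 1000, burnin = 500, thin = 1,
                       chains = 2, seed = 1) {
  check_number(iterations, "iterations", lower = 1)
  check_number(burnin, "burnin", lower = 0)
  check_number(thin, "thin", lower = 1)
  check_number(chains, "chains", lower = 1)
  check_number(seed, "seed")
  if (burnin >= iterations) {
    stop_phybite("`burnin` must be smaller than `iterations`.")
  }
  structure(
    list(iterations = as.integer(iterations), burnin = as.integer(burnin),
         thin = as.integer(thin), chains = as.integer(chains),
         seed = as.integer(seed)),
    class = "ppm_config"
  )
}

validate_trait_table <- function(data, require_y = FALSE) {
  require_columns(data, c("taxon", "x"), "trait table")
  data <- tibble::as_tibble(data)
  data$taxon <- norm_label(data$taxon)
  if (anyDuplicated(data$taxon)) {
    stop_phybite(sprintf(
      "Duplicate taxa in trait table: %s",
      paste(unique(data$taxon[duplicated(data$taxon)]), collapse = ", ")))
  }
  check_number(data$x, "x")
  if (!"y" %in% names(data)) data$y <- NA_real_
  if (any(!is.na(data$y) & !is.finite(data$y))) {
    stop_phybite("`y` must be finite where present.")
  }
  if (require_y && sum(is.finite(data$y)) < 3) {
    stop_phybite("At least 3 taxa with observed `y` are required.")
  }
  data
}

# Lambda transform: off-diagonals of the Brownian covariance scaled by
# lambda, diagonal untouched.
lambda_cov <- function(C, lambda) {
  if (lambda == 1) return(C)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

# Cholesky with a single jitter retry (phylogenetically identical tips give
# a singular covariance).
safe_chol <- function(C, context = "covariance") {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(ch)) return(list(chol = ch, C = C))
  eps <- 1e-8 * max(diag(C))
  Cj <- C + diag(eps, nrow(C))
  ch <- tryCatch(chol(Cj), error = function(e) NULL)
  if (is.null(ch)) {
    stop_phybite(sprintf(
      "Singular %s matrix; resolve zero-length branches (see resolve_zero_branches_equal()) or drop phylogenetically identical tips.",
      context))
  }
  rlang::warn(sprintf(
    "Singular %s matrix: added jitter %.3g to the diagonal.", context, eps))
  list(chol = ch, C = Cj)
}

# Per-lambda sufficient statistics for the Gibbs sweep.
gls_workspace <- function(X, y, C, lambda) {
  sc <- safe_chol(lambda_cov(C, lambda))
  ch <- sc$chol
  Ci <- chol2inv(ch)
  CiX <- Ci %*% X
  XtCiX <- crossprod(X, CiX)
  XtCiy <- crossprod(CiX, y)
  ytCiy <- drop(crossprod(y, Ci %*% y))
  V <- solve(XtCiX)
  list(
    chol = ch, Ci = Ci, CiX = CiX, XtCiX = XtCiX, XtCiy = drop(XtCiy),
    ytCiy = ytCiy, bg = drop(V %*% XtCiy), V = V, cholV = chol(V),
    logdet = 2 * sum(log(diag(ch)))
  )
}

gls_ss <- function(ws, b) {
  max(ws$ytCiy - 2 * sum(b * ws$XtCiy) +
        sum(b * drop(ws$XtCiX %*% b)), 1e-300)
}

ppm_gibbs_chain <- function(X, y, C, config, lambda_mode, lambda_value,
                            chain_seed, log_s2_range = c(-30, 30),
                            lambda_step = 0.15) {
  set.seed(chain_seed)
  n <- length(y)
  estimate <- identical(lambda_mode, "estimate")
  lam <- if (estimate) 0.5 else lambda_value
  ws <- gls_workspace(X, y, C, lam)
  b <- ws$bg
  s2 <- gls_ss(ws, b) / max(n - 2, 1)
  keep <- seq.int(config$burnin + config$thin, config$iterations,
                  by = config$thin)
  nkeep <- length(keep)
  out <- matrix(NA_real_, nkeep, 4,
                dimnames = list(NULL, c("alpha", "beta", "sigma2", "lambda")))
  k <- 0L
  for (it in seq_len(config$iterations)) {
    if (estimate) {
      prop <- lam + runif(1, -lambda_step, lambda_step)
      # reflect into [0, 1]
      while (prop < 0 || prop > 1) {
        if (prop < 0) prop <- -prop
        if (prop > 1) prop <- 2 - prop
      }
      ws_prop <- gls_workspace(X, y, C, prop)
      r <- y - drop(X %*% b)
      ss_cur <- gls_ss(ws, b)
      v <- backsolve(ws_prop$chol, r, transpose = TRUE)
      ss_prop <- sum(v * v)
      log_ratio <- -0.5 * (ws_prop$logdet - ws$logdet) -
        (ss_prop - ss_cur) / (2 * s2)
      if (log(runif(1)) < log_ratio) {
        lam <- prop
        ws <- ws_prop
      }
    }
    # (alpha, beta) | sigma2, lambda ~ Normal(GLS estimate, s2 (X'Ci X)^-1)
    b <- ws$bg + sqrt(s2) * drop(t(ws$cholV) %*% rnorm(2))
    # sigma2 | (alpha, beta), lambda ~ scaled inverse-chi-square,
    # flat prior on log(sigma2) over log_s2_range
    ss <- gls_ss(ws, b)
    for (try in 1:50) {
      s2_new <- ss / rchisq(1, df = n)
      if (log(s2_new) >= log_s2_range[1] && log(s2_new) <= log_s2_range[2])
        break
    }
    s2 <- s2_new
    if (k < nkeep && it == keep[k + 1L]) {
      k <- k + 1L
      out[k, ] <- c(b[1], b[2], s2, lam)
    }
  }
  out
}

#' Fit a Bayesian phylogenetic predictive model
#'
#' Fits the regression `y ~ alpha + beta * x` with phylogenetically
#' structured residuals, `y ~ MVN(alpha + beta x, sigma2_bm * C_lambda)`,
#' where `C` is the Brownian-motion covariance of the tree ([phylo_vcv()])
#' and `C_lambda` scales its off-diagonals by Pagel's lambda. Sampling is by
#' MCMC: Gibbs draws from the exact conditional normal for `(alpha, beta)`
#' and the conditional inverse-gamma-form density for `sigma2_bm`, with a
#' reflected random-walk Metropolis step for lambda when it is estimated.
#' Priors are improper flat on `alpha` and `beta`, uniform on
#' `log(sigma2_bm)` over a wide range, and uniform(0, 1) on lambda.
#'
#' Only rows of `data` with a finite `y` enter the fit; rows with missing
#' `y` are retained as prediction targets for [predict_batch()].
#'
#' @param data A trait table: data frame with columns `taxon`, `x`
#'   (predictor, e.g. log10 skull width in mm), `y` (response, e.g. log10
#'   A_Phys in mm^2; `NA` for prediction targets) and optionally `status`.
#' @param tree A time-scaled `phylo` tree containing all `data` taxa as
#'   tips.
#' @param config An [ppm_config()] object.
#' @param lambda `"fixed"` (pure Brownian motion at `lambda_value`, the
#'   default) or `"estimate"`.
#' @param lambda_value Value of lambda when fixed (default 1).
#' @return An object of class `ppm_fit` with a `draws` tibble
#'   (`chain, iter, alpha, beta, sigma2, lambda`), the data, tree and
#'   configuration. Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and `predict()`.
#' @examples
#' tr <- simulate_tree(12, seed = 1)
#' d <- simulate_dataset(tr, seed = 1)
#' fit <- fit_ppm(d, tr, ppm_config(seed = 1))
#' generics::tidy(fit)
#' @export
fit_ppm <- function(data, tree, config = ppm_config(),
                    lambda = c("fixed", "estimate"), lambda_value = 1) {
  stopifnot(inherits(tree, "phylo"))
  lambda <- match.arg(lambda)
  check_number(lambda_value, "lambda_value", lower = 0, upper = 1)
  if (!inherits(config, "ppm_config")) {
    stop_phybite("`config` must be created with ppm_config().")
  }
  data <- validate_trait_table(data, require_y = TRUE)
  tips <- norm_label(tree$tip.label)
  if (!any(data$taxon %in% tips)) {
    stop_phybite("No overlap between trait-table taxa and tree tips.")
  }
  missing <- setdiff(data$taxon, tips)
  if (length(missing) > 0) {
    stop_phybite(sprintf("Trait-table taxa not in tree: %s",
                         paste(missing, collapse = ", ")))
  }
  obs <- data[is.finite(data$y), ]
  C <- phylo_vcv(tree, obs$taxon)
  X <- cbind(1, obs$x)
  draws <- purrr::map_dfr(seq_len(config$chains), function(k) {
    m <- ppm_gibbs_chain(X, obs$y, C, config, lambda, lambda_value,
                         chain_seed = derive_seed(config$seed,
                                                  paste0("chain", k)))
    tibble::tibble(chain = k, iter = seq_len(nrow(m)),
                   alpha = m[, "alpha"], beta = m[, "beta"],
                   sigma2 = m[, "sigma2"], lambda = m[, "lambda"])
  })
  structure(
    list(draws = draws, data = data, tree = tree, taxa = obs$taxon,
         config = config, lambda_mode = lambda, lambda_value = lambda_value),
    class = "ppm_fit"
  )
}

#' Log-likelihood of the phylogenetic regression
#'
#' Evaluates the multivariate-normal log density
#' `log MVN(y; alpha + beta x, sigma2 * C_lambda)` for the observed rows of a
#' trait table on a tree, via a Cholesky factorisation.
#'
#' @inheritParams fit_ppm
#' @param alpha,beta,sigma2 Parameter values.
#' @param lambda_value Pagel's lambda (default 1).
#' @return A single log-density value.
#' @export
ppm_loglik <- function(data, tree, alpha, beta, sigma2, lambda_value = 1) {
  data <- validate_trait_table(data, require_y = TRUE)
  obs <- data[is.finite(data$y), ]
  check_number(sigma2, "sigma2", lower = 0, strict_lower = TRUE)
  C <- lambda_cov(phylo_vcv(tree, obs$taxon), lambda_value)
  ch <- chol(sigma2 * C)
  r <- obs$y - (alpha + beta * obs$x)
  v <- backsolve(ch, r, transpose = TRUE)
  -0.5 * length(r) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(v * v)
}

# Shared predictive engine: draws from the conditional normal of each target
# given the observed tips, per posterior draw.
ppm_predict_core <- function(fit, targets, seed, level) {
  targets <- tibble::as_tibble(targets)
  require_columns(targets, c("taxon", "x"), "targets")
  targets$taxon <- norm_label(targets$taxon)
  if (nrow(targets) == 0) stop_phybite("Empty target set.")
  tips <- norm_label(fit$tree$tip.label)
  bad <- setdiff(targets$taxon, tips)
  if (length(bad) > 0) {
    stop_phybite(sprintf("Target taxa not in tree: %s",
                         paste(bad, collapse = ", ")))
  }
  infit <- intersect(targets$taxon, fit$taxa)
  if (length(infit) > 0) {
    stop_phybite(sprintf(
      "Target%s %s carried an observed response in the fit; use loocv() for in-sample assessment.",
      if (length(infit) > 1) "s" else "", paste(infit, collapse = ", ")))
  }
  obs <- fit$data[is.finite(fit$data$y), ]
  n <- nrow(obs)
  m <- nrow(targets)
  Call <- phylo_vcv(fit$tree, c(obs$taxon, targets$taxon))
  Coo <- Call[seq_len(n), seq_len(n), drop = FALSE]
  Cto <- Call[n + seq_len(m), seq_len(n), drop = FALSE]
  ctt <- diag(Call)[n + seq_len(m)]
  X <- cbind(1, obs$x)
  dr <- fit$draws
  nd <- nrow(dr)
  set.seed(seed)
  draws <- matrix(NA_real_, nd, m, dimnames = list(NULL, targets$taxon))
  lam_const <- length(unique(dr$lambda)) == 1L
  lam_values <- if (lam_const) dr$lambda[1] else dr$lambda
  compute_for_lambda <- function(lam) {
    sc <- safe_chol(lambda_cov(Coo, lam))
    Ci <- chol2inv(sc$chol)
    list(Ciy = drop(Ci %*% obs$y), CiX = Ci %*% X, Ci = Ci)
  }
  if (lam_const) {
    wk <- compute_for_lambda(lam_values)
    for (j in seq_len(m)) {
      cstar <- lam_values * Cto[j, ]
      q1 <- sum(cstar * wk$Ciy)
      qA <- drop(crossprod(wk$CiX, cstar))
      qv <- sum(cstar * drop(wk$Ci %*% cstar))
      mu <- dr$alpha + dr$beta * targets$x[j] + q1 -
        (qA[1] * dr$alpha + qA[2] * dr$beta)
      v <- pmax(dr$sigma2 * (ctt[j] - qv), 0)
      draws[, j] <- rnorm(nd, mu, sqrt(v))
    }
  } else {
    for (d in seq_len(nd)) {
      wk <- compute_for_lambda(dr$lambda[d])
      for (j in seq_len(m)) {
        cstar <- dr$lambda[d] * Cto[j, ]
        q1 <- sum(cstar * wk$Ciy)
        qA <- drop(crossprod(wk$CiX, cstar))
        qv <- sum(cstar * drop(wk$Ci %*% cstar))
        mu <- dr$alpha[d] + dr$beta[d] * targets$x[j] + q1 -
          (qA[1] * dr$alpha[d] + qA[2] * dr$beta[d])
        v <- max(dr$sigma2[d] * (ctt[j] - qv), 0)
        draws[d, j] <- rnorm(1, mu, sqrt(v))
      }
    }
  }
  a <- (1 - level) / 2
  summary <- tibble::tibble(
    taxon = targets$taxon,
    x = targets$x,
    median = apply(draws, 2, median),
    lo = apply(draws, 2, quantile, probs = a),
    hi = apply(draws, 2, quantile, probs = 1 - a)
  )
  structure(
    list(summary = summary, draws = draws, level = level, seed = seed),
    class = "ppm_prediction"
  )
}

#' Posterior predictive distribution for one unobserved tip
#'
#' For each retained posterior draw, the target's response is sampled from
#' its conditional normal given the observed tips under that draw's
#' parameters: mean `alpha + beta x* + c*' C^-1 (y - alpha - beta x)` and
#' variance `sigma2 (c** - c*' C^-1 c*)`, where `c*` is the target-observed
#' covariance vector and `c**` the target's diagonal entry (lambda applied
#' to off-diagonals). The predictive draws therefore carry both parameter
#' and sampling uncertainty.
#'
#' @param fit A [fit_ppm()] object.
#' @param target Taxon name of a tip whose `y` is absent, or a one-row data
#'   frame with `taxon` and `x`.
#' @param seed Seed for the predictive sampling (default derived from the
#'   fit's master seed).
#' @param level Central-interval level for the summary (default 0.95).
#' @return A `ppm_prediction` object; `tidy()` gives the summary row and
#'   `$draws` the predictive draws.
#' @export
predict_tip <- function(fit, target, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "ppm_fit"))
  if (is.character(target)) {
    target <- lookup_targets(fit, target)
  }
  if (nrow(tibble::as_tibble(target)) != 1) {
    stop_phybite("`target` must identify exactly one taxon; use predict_batch() for several.")
  }
  if (is.null(seed)) seed <- derive_seed(fit$config$seed, "predict")
  ppm_predict_core(fit, target, seed = seed, level = level)
}

lookup_targets <- function(fit, taxa) {
  taxa <- norm_label(taxa)
  idx <- match(taxa, fit$data$taxon)
  if (anyNA(idx)) {
    stop_phybite(sprintf("Taxa absent from the fit's trait table: %s",
                         paste(taxa[is.na(idx)], collapse = ", ")))
  }
  fit$data[idx, c("taxon", "x")]
}

#' Posterior predictive distributions for a batch of unobserved tips
#'
#' Equivalent to [predict_tip()] run per target on a tree containing all
#' targets: each target conditions only on the observed (response-bearing)
#' tips, never on other targets.
#'
#' @param fit A [fit_ppm()] object.
#' @param targets Character vector of taxa, a data frame with `taxon` and
#'   `x`, or `NULL` (default) for every trait-table row with missing `y`.
#' @inheritParams predict_tip
#' @return A `ppm_prediction` object covering all targets.
#' @export
predict_batch <- function(fit, targets = NULL, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "ppm_fit"))
  if (is.null(targets)) {
    targets <- fit$data[!is.finite(fit$data$y), c("taxon", "x")]
  } else if (is.character(targets)) {
    targets <- lookup_targets(fit, targets)
  }
  if (nrow(tibble::as_tibble(targets)) == 0) {
    stop_phybite("Empty target set.")
  }
  if (is.null(seed)) seed <- derive_seed(fit$config$seed, "predict")
  ppm_predict_core(fit, targets, seed = seed, level = level)
}

#' @export
predict.ppm_fit <- function(object, newdata = NULL, ...) {
  predict_batch(object, targets = newdata, ...)
}
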