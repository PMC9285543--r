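test_that("posterior means match OLS on a star tree", {
  set.seed(42)
  n <- 10
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", seq_len(n))
  d <- tibble::tibble(taxon = star$tip.label, x = rnorm(n, 2, 0.5))
  d$y <- -1.5 + 2 * d$x + rnorm(n, 0, 0.2)
  fit <- fit_ppm(d, star, ppm_config(iterations = 4500, burnin = 500,
                                     chains = 2, seed = 9))
  ols <- coef(lm(y ~ x, data = d))
  dr <- fit$draws
  for (k in 1:2) {
    v <- if (k == 1) dr$alpha else dr$beta
    mc_se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - ols[k]), 3 * sqrt(mc_se^2 + (0.02 * sd(v))^2))
  }
})

test_that("posterior means match the GLS closed form on a fixed tree", {
  tr <- simulate_tree(20, style = "fossil", seed = 4)
  d <- simulate_dataset(tr, seed = 4)
  fit <- fit_ppm(d, tr, ppm_config(iterations = 8500, burnin = 500,
                                   chains = 2, seed = 2))
  C <- phylo_vcv(tr, d$taxon)
  bg <- gls_oracle(d$x, d$y, C)
  dr <- fit$draws
  for (k in 1:2) {
    v <- if (k == 1) dr$alpha else dr$beta
    mc_se <- sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - bg[k]), 3 * sqrt(mc_se^2 + (0.02 * sd(v))^2))
  }
})

test_that("identical seed and config give identical draws", {
  tr <- simulate_tree(12, seed = 3)
  d <- simulate_dataset(tr, seed = 3)
  cfg <- ppm_config(iterations = 300, burnin = 100, chains = 2, seed = 77)
  f1 <- fit_ppm(d, tr, cfg)
  f2 <- fit_ppm(d, tr, cfg)
  expect_identical(f1$draws, f2$draws)
  p1 <- predict_tip(fit_ppm(within(d, y[1] <- NA), tr, cfg), d$taxon[1])
  p2 <- predict_tip(fit_ppm(within(d, y[1] <- NA), tr, cfg), d$taxon[1])
  expect_identical(p1$draws, p2$draws)
})

test_that("log-likelihood matches brute-force MVN density on small trees", {
  for (s in 1:3) {
    tr <- simulate_tree(6, style = "fossil", seed = s)
    d <- simulate_dataset(tr, seed = s)
    for (lam in c(1, 0.6)) {
      ll <- ppm_loglik(d, tr, alpha = -1.2, beta = 1.8, sigma2 = 3e-4,
                       lambda_value = lam)
      C <- phylo_vcv(tr, d$taxon)
      Cl <- lam * C
      diag(Cl) <- diag(C)
      ll_brute <- mvn_logdens_brute(d$y, -1.2 + 1.8 * d$x, 3e-4 * Cl)
      expect_equal(ll, ll_brute, tolerance = 1e-8)
    }
  }
})

test_that("a target duplicating an observed tip is predicted exactly", {
  tr <- parse_newick("(((A:0,T:0):5,(B:3,C:3):2):1,D:6);")
  d <- tibble::tibble(taxon = c("A", "B", "C", "D", "T"),
                      x = c(1.0, 1.5, 2.0, 2.5, 1.0),
                      y = c(0.5, 1.2, 2.1, 2.8, NA))
  fit <- fit_ppm(d, tr, fast_config(seed = 5))
  pred <- predict_tip(fit, "T")
  expect_equal(unname(pred$draws[, 1]), rep(0.5, nrow(fit$draws)),
               tolerance = 1e-6)
})

test_that("with lambda = 0 the prediction reduces to the regression line", {
  tr <- simulate_tree(15, seed = 6)
  d <- simulate_dataset(tr, seed = 6)
  d$y[1] <- NA
  fit <- fit_ppm(d, tr, ppm_config(iterations = 2500, burnin = 500,
                                   chains = 1, seed = 8),
                 lambda = "fixed", lambda_value = 0)
  pred <- predict_tip(fit, d$taxon[1])
  dr <- fit$draws
  line_mean <- mean(dr$alpha + dr$beta * d$x[1])
  css <- phylo_vcv(tr)[d$taxon[1], d$taxon[1]]
  pred_sd <- sqrt(mean(dr$sigma2) * css +
                    var(dr$alpha + dr$beta * d$x[1]))
  expect_lt(abs(mean(pred$draws[, 1]) - line_mean),
            4 * pred_sd / sqrt(nrow(dr)) + 0.05 * pred_sd)
})

test_that("conditioning never inflates the predictive variance", {
  # c** - c*' C^-1 c* must lie in [0, c**] for every target/tree
  for (s in 1:4) {
    tr <- simulate_tree(12, style = "fossil", seed = s)
    V <- phylo_vcv(tr)
    for (j in c(1, 5, 12)) {
      cstar <- V[j, -j]
      css <- V[j, j]
      qv <- drop(t(cstar) %*% solve(V[-j, -j]) %*% cstar)
      expect_gte(qv, -1e-8)
      expect_lte(qv, css + 1e-8)
    }
  }
})

test_that("batch prediction agrees with single-tip prediction", {
  tr <- simulate_tree(20, seed = 12)
  d <- simulate_dataset(tr, seed = 12)
  d$y[c(1, 10)] <- NA
  fit <- fit_ppm(d, tr, ppm_config(seed = 21))
  both <- predict_batch(fit)
  expect_equal(ncol(both$draws), 2)
  expect_equal(nrow(both$draws), nrow(fit$draws))
  # single target through either entry point: identical draws, same seed
  one <- predict_batch(fit, d$taxon[1])
  tip <- predict_tip(fit, d$taxon[1])
  expect_identical(one$draws, tip$draws)
  # each batch target matches its own single-tip run within Monte-Carlo error
  for (tx in c(d$taxon[1], d$taxon[10])) {
    single <- predict_tip(fit, tx, seed = 999)
    sd_p <- sd(both$draws[, tx])
    expect_lt(abs(median(both$draws[, tx]) - single$summary$median),
              4 * sd_p / sqrt(nrow(both$draws)) * 3)
  }
})

test_that("prediction targets must be unobserved tips of the tree", {
  tr <- simulate_tree(10, seed = 1)
  d <- simulate_dataset(tr, seed = 1)
  fit <- fit_ppm(d, tr, fast_config())
  expect_error(predict_tip(fit, d$taxon[2]), "loocv")
  expect_error(predict_batch(fit, data.frame(taxon = "missing", x = 1)),
               "missing")
  expect_error(predict_batch(fit), "Empty target")
})

test_that("simulated data recover the generating parameters", {
  truth <- list(alpha = -1.5, beta = 2)
  hits <- c(alpha = 0, beta = 0)
  n_rep <- 30
  for (s in seq_len(n_rep)) {
    tr <- simulate_tree(25, style = "fossil", seed = 100 + s)
    d <- simulate_dataset(tr, seed = 200 + s)
    fit <- fit_ppm(d, tr, fast_config(seed = s))
    td <- tidy(fit)
    for (term in c("alpha", "beta")) {
      row <- td[td$term == term, ]
      if (abs(row$estimate - truth[[term]]) < 3 * row$std.error) {
        hits[term] <- hits[term] + 1
      }
    }
  }
  # 3-SD band: expect nearly all replicates inside
  expect_gte(hits["alpha"] / n_rep, 0.9)
  expect_gte(hits["beta"] / n_rep, 0.9)
})

test_that("lambda posterior concentrates above 0.5 when data are Brownian", {
  tr <- simulate_tree(60, seed = 31)
  d <- simulate_dataset(tr, lambda = 1, seed = 31)
  fit <- fit_ppm(d, tr, ppm_config(iterations = 3000, burnin = 1000,
                                   chains = 1, seed = 13),
                 lambda = "estimate")
  expect_gt(mean(fit$draws$lambda > 0.5), 0.9)
})

test_that("central predictive intervals have close to nominal coverage", {
  n_rep <- 200
  hit <- 0
  for (s in seq_len(n_rep)) {
    tr <- simulate_tree(12, style = "fossil", seed = 5000 + s)
    d <- simulate_dataset(tr, seed = 6000 + s)
    truth_y <- d$y[1]
    d$y[1] <- NA
    fit <- fit_ppm(d, tr, fast_config(seed = s))
    pred <- predict_tip(fit, d$taxon[1])
    if (truth_y >= pred$summary$lo && truth_y <= pred$summary$hi) {
      hit <- hit + 1
    }
  }
  expect_gt(hit / n_rep, 0.89)
  expect_lt(hit / n_rep, 1.0)
})

test_that("fit validates inputs and flags singular covariances", {
  tr <- simulate_tree(10, seed = 1)
  d <- simulate_dataset(tr, seed = 1)
  expect_error(fit_ppm(d[1:2, ], tr, ppm_config()), "At least 3")
  d_bad <- d
  d_bad$taxon[1] <- "not_a_tip"
  expect_error(fit_ppm(d_bad, tr, ppm_config()), "not_a_tip")
  d_none <- d
  d_none$taxon <- paste0("z", seq_len(nrow(d)))
  expect_error(fit_ppm(d_none, tr, ppm_config()), "No overlap")
  # two phylogenetically identical observed tips: jitter warning, no crash
  tr2 <- parse_newick("((A:0,B:0):5,(C:3,D:3):2);")
  d2 <- tibble::tibble(taxon = c("A", "B", "C", "D"),
                       x = c(1, 1.1, 2, 2.2), y = c(0.9, 1.0, 2.1, 2.4))
  expect_warning(fit_ppm(d2, tr2, fast_config()), "jitter")
})

test_that("tidy and glance summarise a fit", {
  tr <- simulate_tree(10, seed = 2)
  d <- simulate_dataset(tr, seed = 2)
  fit <- fit_ppm(d, tr, fast_config(seed = 3))
  td <- tidy(fit)
  expect_setequal(td$term, c("alpha", "beta", "sigma2", "lambda"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 10)
  expect_equal(gl$n_draws, nrow(fit$draws))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
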