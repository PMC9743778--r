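# Maximum-likelihood fitting: closed forms, nesting, exposure equivariance,
# oracle comparisons, honest convergence reporting.

test_that("intercept-only fits match the closed forms for the mean component", {
  d <- make_taxon_data(seed = 2, zero_prob = 0.01)
  X1 <- matrix(1, length(d$y), dimnames = list(NULL, "(Intercept)"))
  rate <- sum(d$y) / sum(d$s)
  f_pois <- fit_ml("Poisson", d$y, X1, s = d$s)
  expect_equal(unname(f_pois$alpha), log(rate), tolerance = 1e-8)
  f_bin <- fit_ml("Binomial", d$y, X1, s = d$s)
  expect_equal(unname(f_bin$alpha), qlogis(rate), tolerance = 1e-8)
  # overdispersed families share the same mean closed form at the optimum
  f_nb <- fit_ml("NegativeBinomial", d$y, X1, s = d$s)
  expect_equal(unname(f_nb$alpha), log(mean(d$y / d$s)), tolerance = 1e-3)
})

test_that("nested families never lose log-likelihood", {
  for (seed in c(5, 9)) {
    d <- make_taxon_data(seed = seed, beta_x = 0.3)
    ll <- sapply(all_family_names, function(nm) {
      fam <- prr_families(nm)[[1]]
      fit_ml(fam, d$y, d$X, if (fam$zero_inflated) d$Z, d$s)$loglik
    })
    # zero-inflated extends plain; overdispersed extends plain
    expect_gte(ll[["ZIPoisson"]], ll[["Poisson"]] - 1e-6)
    expect_gte(ll[["ZINegativeBinomial"]], ll[["NegativeBinomial"]] - 1e-6)
    expect_gte(ll[["ZIBinomial"]], ll[["Binomial"]] - 1e-6)
    expect_gte(ll[["ZIBetaBinomial"]], ll[["BetaBinomial"]] - 1e-6)
    expect_gte(ll[["NegativeBinomial"]], ll[["Poisson"]] - 1e-6)
    expect_gte(ll[["BetaBinomial"]], ll[["Binomial"]] - 1e-6)
    expect_gte(ll[["ZINegativeBinomial"]], ll[["ZIPoisson"]] - 1e-6)
    expect_gte(ll[["ZIBetaBinomial"]], ll[["ZIBinomial"]] - 1e-6)
  }
})

test_that("doubling library sizes shifts only the Poisson-type intercept by -log 2", {
  d <- make_taxon_data(seed = 4, beta_x = 0.5)
  for (nm in c("Poisson", "NegativeBinomial")) {
    f1 <- fit_ml(nm, d$y, d$X, s = d$s)
    f2 <- fit_ml(nm, d$y, d$X, s = 2 * d$s)
    expect_equal(unname(f2$alpha[1]), unname(f1$alpha[1]) - log(2),
                 tolerance = 1e-6, label = paste(nm, "intercept"))
    expect_equal(unname(f2$alpha[2]), unname(f1$alpha[2]),
                 tolerance = 1e-6, label = paste(nm, "slope"))
  }
})

test_that("negative binomial fit attains the oracle maximum on simulated data", {
  withr::local_seed(21)
  n <- 200
  x <- rnorm(n)
  s <- rpois(n, 1000) + 200
  mu <- s * 0.01 * exp(0.8 * x)
  y <- rnbinom(n, size = 1.5, mu = mu)
  X <- cbind(1, x)
  fit <- fit_ml("NegativeBinomial", y, X, s = s)
  expect_true(fit$converged)
  # independent oracle: coarse grid over parameters refined by Nelder-Mead
  # (gradient-free, different algorithm from the BFGS path under test)
  obj <- function(p) -log_likelihood("NegativeBinomial", p, y, X, s = s)
  grid <- expand.grid(a0 = c(-5.5, -4.5), a1 = c(0.5, 1), lt = c(0, 0.7))
  oracle <- min(apply(grid, 1, function(g)
    stats::optim(as.numeric(g), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))$value))
  expect_gte(fit$loglik, -oracle - 1e-4)
  expect_equal(fit$loglik, -oracle, tolerance = 1e-4)
})

test_that("fitted maxima reach a gradient-free oracle across random instances", {
  # 20 random small instances per family; the oracle is Nelder-Mead from
  # three deterministic starts, sharing nothing with the BFGS fit path
  for (nm in all_family_names) {
    fam <- prr_families(nm)[[1]]
    for (r in 1:20) {
      d <- make_taxon_data(n = 50, seed = 100 * r + 7,
                           beta_x = 0.4 * (r %% 3 - 1), theta = 0.8,
                           zero_prob = 0.2)
      Z1 <- matrix(1, 50, dimnames = list(NULL, "(Intercept)"))
      fit <- fit_ml(fam, d$y, d$X, if (fam$zero_inflated) Z1, d$s)
      obj <- function(p) {
        v <- log_likelihood(fam, p, d$y, d$X, if (fam$zero_inflated) Z1, d$s)
        if (is.finite(v)) -v else 1e10
      }
      np <- 2 + fam$zero_inflated + fam$overdispersed
      starts <- list(rep(0.1, np),
                     c(-4, rep(0.2, np - 1)),
                     c(-5, 0, rep(-0.5, np - 2)))
      oracle <- suppressWarnings(min(vapply(starts, function(st)
        stats::optim(st, obj, method = "Nelder-Mead",
                     control = list(maxit = 3000, reltol = 1e-10))$value,
        numeric(1))))
      expect_gte(fit$loglik, -oracle - 1e-3)
    }
  }
})

test_that("convergence reporting is honest under an iteration cap", {
  d <- make_taxon_data(seed = 13, beta_x = 0.6)
  f <- fit_ml("ZINegativeBinomial", d$y, d$X, d$Z, d$s,
              control = list(maxit = 1))
  expect_false(f$converged)
  expect_true(length(f$messages) > 0)
  expect_true(is.finite(f$loglik))
})

test_that("auxiliary parameter at its internal boundary flags non-convergence", {
  d <- make_taxon_data(seed = 6)
  f <- fit_ml("NegativeBinomial", d$y, d$X, s = d$s,
              control = list(aux_boundary = 0.01))
  expect_false(f$converged)
  expect_true(any(grepl("boundary", f$messages)))
})

test_that("degenerate designs and data are rejected or reported, never silent", {
  d <- make_taxon_data(seed = 8)
  Xbad <- cbind(d$X, d$X[, 2])
  expect_error(fit_ml("Poisson", d$y, Xbad, s = d$s), "rank deficient")
  expect_error(fit_ml("ZINegativeBinomial", d$y[1:3], d$X[1:3, ],
                      d$Z[1:3, ], d$s[1:3]),
               "fewer observations")
  # all-zero taxon under a binomial model: reported, not crashed
  y0 <- rep(0, length(d$y))
  f <- fit_ml("Binomial", y0, d$X, s = d$s)
  expect_s3_class(f, "prr_fit")
  expect_true(is.finite(f$loglik))
})

test_that("fits are deterministic given data and init", {
  d <- make_taxon_data(seed = 10, beta_x = 0.2)
  f1 <- fit_ml("ZIBetaBinomial", d$y, d$X, d$Z, d$s)
  f2 <- fit_ml("ZIBetaBinomial", d$y, d$X, d$Z, d$s)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("negative binomial agrees with an independent package implementation", {
  skip_if_not_installed("MASS")
  withr::local_seed(31)
  n <- 150
  x <- rnorm(n)
  s <- rpois(n, 800) + 100
  y <- rnbinom(n, size = 2, mu = s * 0.02 * exp(0.5 * x))
  X <- cbind(1, x)
  fit <- fit_ml("NegativeBinomial", y, X, s = s)
  m <- MASS::glm.nb(y ~ x + offset(log(s)))
  expect_equal(fit$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-5)
  expect_equal(unname(fit$alpha), unname(coef(m)), tolerance = 1e-4)
  expect_equal(unname(fit$aux_natural), m$theta, tolerance = 1e-3)
})
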