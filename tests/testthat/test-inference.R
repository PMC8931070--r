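# Simulated-data checks of the three estimators and of the dyadic table
# construction.

test_that("dyadic table: distance regimes, transforms and cardinality", {
  ch <- fixture("chain3")
  g <- suppressWarnings(run_grid(ch, 0.3, c(0, 1)))
  f <- node_features(ch)
  d <- build_dyadic_table(g, f, ch)
  expect_equal(nrow(d), 2 * 9)
  row <- function(o, j, a) d[d$origin == o & d$dest == j & d$alpha == a, ]
  # A -> C: directed distance 2 -> indirect
  expect_equal(row("A", "C", 1)$indirect, 1)
  expect_equal(row("A", "C", 1)$no_direct_link, 0)
  # C -> A: no directed path
  expect_equal(row("C", "A", 1)$no_direct_link, 1)
  expect_equal(row("C", "A", 1)$indirect, 0)
  # A -> B: direct link is the omitted baseline; domestic only on diagonal
  expect_equal(row("A", "B", 1)$indirect + row("A", "B", 1)$no_direct_link, 0)
  expect_equal(row("A", "A", 1)$domestic, 1)
  # regimes are mutually exclusive
  reg <- d$domestic + (1 - d$domestic) *
    pmax(d$indirect, d$no_direct_link)
  expect_true(all(d$domestic + d$indirect + d$no_direct_link <= 1))
  # display transforms
  expect_equal(d$dest_clustering, 1000 * f$clustering[match(d$dest, f$id)])
  expect_equal(d$orig_log_betweenness,
               log1p(f$betweenness[match(d$origin, f$id)]))
  # hash guard
  other <- fixture("star5")
  expect_error(build_dyadic_table(g, f, other), "hash")
})

test_that("tobit equals least squares when nothing is censored", {
  set.seed(21)
  n <- 400
  x1 <- rnorm(n); x2 <- runif(n)
  y <- 50 + 2 * x1 - 3 * x2 + rnorm(n)   # strictly positive
  expect_true(all(y > 0))
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  tf <- tobit_fit(y ~ x1 + x2, d)
  lf <- stats::lm(y ~ x1 + x2, d)
  expect_lt(max(abs(coef(tf) - coef(lf))), 1e-6)
  expect_equal(tf$n_censored, 0L)
})

test_that("tobit recovers known parameters under heavy censoring", {
  set.seed(7)
  n <- 2000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  ystar <- 0.3 + 1.5 * x1 - 1 * x2 + rnorm(n, sd = 2)
  y <- pmax(ystar, 0)
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  tf <- tobit_fit(y ~ x1 + x2, d)
  expect_gt(tf$n_censored / n, 0.25)
  truth <- c(0.3, 1.5, -1)
  expect_true(all(abs(coef(tf) - truth) < 3 * tf$se))
  expect_equal(tf$sigma, 2, tolerance = 0.15)
  expect_gt(tf$pseudo_r2, 0)
  # degenerate input refused
  expect_error(tobit_fit(y ~ x1, data.frame(y = rep(0, 10), x1 = 1:10)),
               "censored")
})

test_that("negative binomial recovery and Poisson boundary", {
  set.seed(31)
  n <- 516
  x <- rnorm(n)
  mu <- exp(1 + 0.5 * x)
  y <- stats::rnbinom(n, mu = mu, size = 2)   # kappa = 0.5
  nf <- negbin_fit(y ~ x, data.frame(y = y, x = x))
  expect_true(all(abs(coef(nf) - c(1, 0.5)) < 3 * nf$se))
  expect_equal(nf$kappa, 0.5, tolerance = 0.5)
  # intercept-only fit recovers the mean
  cf <- suppressWarnings(negbin_fit(y ~ 1, data.frame(y = rep(2L, 60))))
  expect_equal(unname(exp(coef(cf)[1])), 2, tolerance = 1e-6)
  # Poisson data: dispersion pinned at the boundary
  yp <- stats::rpois(n, mu)
  pf <- suppressWarnings(negbin_fit(y ~ x, data.frame(y = yp, x = x)))
  expect_lt(pf$kappa, 0.05)
  expect_true(all(abs(coef(pf) - c(1, 0.5)) < 3 * pf$se))
  expect_error(negbin_fit(y ~ x, data.frame(y = rep(0L, 20), x = 1:20)),
               "zero")
})

test_that("OLS: exact fit, recovery and singularity reporting", {
  x <- 1:30
  d0 <- data.frame(y = 2 + 3 * x, x = x)
  of <- suppressWarnings(ols_fit(y ~ x, d0))  # lm warns on a perfect fit
  expect_equal(of$r_squared, 1)
  set.seed(5)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(y = 1 - 2 * x1 + 0.5 * x2 + rnorm(n), x1 = x1, x2 = x2)
  of2 <- ols_fit(y ~ x1 + x2, d)
  expect_true(all(abs(coef(of2) - c(1, -2, 0.5)) < 3 * of2$se))
  d$x3 <- d$x1   # duplicated covariate
  expect_error(ols_fit(y ~ x1 + x2 + x3, d), "x3")
})

test_that("robust SEs agree with classical SEs under homoskedasticity", {
  set.seed(12)
  n <- 4000
  x <- rnorm(n)
  d <- data.frame(y = 1 + x + rnorm(n), x = x)
  of <- ols_fit(y ~ x, d)
  classical <- sqrt(diag(stats::vcov(of$fit)))
  expect_equal(unname(of$se), unname(classical), tolerance = 0.1)
})

test_that("standardized coefficients rescale slopes and keep t-stats", {
  set.seed(9)
  n <- 300
  x <- rnorm(n, sd = 2); ind <- rbinom(n, 1, 0.5)
  d <- data.frame(y = 1 + 3 * x + ind + rnorm(n), x = x, ind = ind)
  of <- ols_fit(y ~ x + ind, d)
  st <- standardize_coefficients(of)
  i <- st$term == "x"
  expect_equal(st$std_estimate[i], st$estimate[i] * sd(d$x))
  # indicators pass through unscaled
  j <- st$term == "ind"
  expect_equal(st$std_estimate[j], st$estimate[j])
  # t statistics unchanged by standardization
  expect_equal(st$std_estimate / st$std_se, st$estimate / st$se)
  # zero-variance covariates are dropped with a note (no-intercept fit,
  # where a constant column is not collinear)
  d$z <- 5
  of2 <- ols_fit(y ~ 0 + x + z, d)
  expect_message(st2 <- standardize_coefficients(of2), "z")
  expect_false("z" %in% st2$term)
  # prune_formula removes the constant before an intercept fit
  pf <- suppressMessages(prune_formula(y ~ x + z, d))
  expect_false("z" %in% all.vars(pf))
})

test_that("tobit optimum is stable across optimizer starts", {
  # refitting on jittered subsamples of one censored dataset lands on
  # the same optimum when refit on the full data (concave likelihood)
  set.seed(17)
  n <- 800
  x <- rnorm(n)
  y <- pmax(0.5 + x + rnorm(n), 0)
  d <- data.frame(y = y, x = x)
  f1 <- tobit_fit(y ~ x, d)
  f2 <- tobit_fit(y ~ x, d[sample(n), ])   # permuted rows
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})
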