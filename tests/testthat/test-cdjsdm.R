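test_that("loadings evaluate linearly in the context vector", {
  lam <- array(0, c(2, 2, 2))
  lam[1, , ] <- diag(2)                      # intercept block = I
  lam[2, , ] <- rbind(c(1, 1), c(1, -1))
  expect_equal(loadings_at(lam, c(1, 0)), diag(2), ignore_attr = TRUE)
  expect_equal(loadings_at(lam, c(1, 0.5)),
               rbind(c(1.5, 0.5), c(0.5, 0.5)), ignore_attr = TRUE)
  expect_equal(loadings_at(array(0, c(2, 3, 2)), c(1, 2)),
               matrix(0, 3, 2), ignore_attr = TRUE)
  expect_error(loadings_at(lam, c(1, 0, 0)), "length")
  expect_error(loadings_at(lam, c(2, 0)), "intercept")
})

test_that("association matrices reproduce hand-computed correlations", {
  expect_equal(association_matrix(rbind(c(1, 0), c(1, 0)))[1, 2], 1)
  expect_equal(association_matrix(rbind(c(1, 1), c(1, -1)))[1, 2], 0)
  expect_equal(association_matrix(rbind(c(2, 0), c(1, 1)))[1, 2],
               2 / sqrt(8), tolerance = 1e-10)
  L <- rbind(c(0.3, -1.2), c(0.8, 0.4), c(-0.5, 0.9))
  expect_equal(association_matrix(L), brute_R(L), tolerance = 1e-12)
})

test_that("all-zero loading rows are reported as undefined correlations", {
  L <- rbind(sp_a = c(1, 0), sp_b = c(0, 0))
  expect_error(association_matrix(L), "sp_b")
})

test_that("associations are invariant to factor rotation", {
  set.seed(101)
  lam <- array(rnorm(3 * 5 * 3), c(3, 5, 3))
  x_star <- c(1, 0.7, -0.3)
  R0 <- association_matrix(loadings_at(lam, x_star))
  for (i in 1:100) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))     # random orthogonal
    rot <- lam
    for (k in 1:3) rot[k, , ] <- matrix(lam[k, , ], 5, 3) %*% Q
    expect_equal(association_matrix(loadings_at(rot, x_star)), R0,
                 tolerance = 1e-10)
  }
})

test_that("the probit log likelihood matches an elementwise oracle", {
  # all parameters zero, one cell: log(0.5)
  ll0 <- jsdm_loglik(matrix(0, 2, 1), array(0, c(1, 2, 1)),
                     matrix(0, 1, 1), matrix(1, 1, 1), matrix(1, 1, 1),
                     matrix(c(1, 0), 1, 2))
  expect_equal(ll0, 2 * log(0.5), tolerance = 1e-12)

  # 2 stations x 2 species toy, brute-force elementwise sum
  x <- rbind(c(1, 0.5), c(1, -1))
  xs <- rbind(c(1, 2), c(1, 0))
  beta <- rbind(c(0.2, -0.4), c(-0.1, 0.3))
  lam <- array(c(0.5, -0.2, 0.3, 0.1), c(2, 2, 1))
  z <- matrix(c(0.7, -1.2), 2, 1)
  y <- rbind(c(1, 0), c(0, 1))
  oracle <- 0
  for (i in 1:2) for (j in 1:2) {
    eta <- sum(x[i, ] * beta[j, ]) +
      z[i, 1] * sum(xs[i, ] * lam[, j, 1])
    p <- pnorm(eta)
    oracle <- oracle + if (y[i, j] == 1) log(p) else log(1 - p)
  }
  expect_equal(jsdm_loglik(beta, lam, z, x, xs, y), oracle,
               tolerance = 1e-10)

  # y = 1 with eta -> +Inf contributes ~0 from below
  llbig <- jsdm_loglik(matrix(50, 1, 1), array(0, c(1, 1, 1)),
                       matrix(0, 1, 1), matrix(1, 1, 1),
                       matrix(1, 1, 1), matrix(1, 1, 1))
  expect_gt(llbig, -1e-8)
  expect_lte(llbig, 0)
})

test_that("an intercept-only single-species fit recovers occupancy", {
  # 70% occupancy at n = 500; add a dummy second species (the model
  # needs >= 2) and check the probit intercept of the first
  set.seed(9)
  n <- 500
  y <- cbind(a = rbinom(n, 1, 0.7), b = rbinom(n, 1, 0.5))
  cv <- data.frame(intercept = rep(1, n))
  fit <- suppressWarnings(cdjsdm(y, cv, context = character(0), nf = 1,
                n_chains = 2, n_burn = 300, n_samples = 600, seed = 2))
  draws <- pnorm(fit$draws$beta[, 1, 1])
  expect_lt(abs(mean(draws) - 0.7), 3 * sd(draws))
})

test_that("fits are bitwise reproducible under a fixed seed", {
  cfg <- sim_config(n_stations = 60, n_species = 3, n_factors = 1,
                    seed = 31)
  truth <- sim_community(cfg, sim_covariates(60, seed = 31))
  f1 <- suppressWarnings(
    cdjsdm(truth$occupancy, truth$covariates, nf = 1, n_chains = 1,
           n_burn = 50, n_samples = 80, seed = 5))
  f2 <- suppressWarnings(
    cdjsdm(truth$occupancy, truth$covariates, nf = 1, n_chains = 1,
           n_burn = 50, n_samples = 80, seed = 5))
  expect_identical(f1$draws, f2$draws)
})

test_that("binary input is enforced", {
  cv <- data.frame(intercept = rep(1, 10))
  expect_error(cdjsdm(matrix(2, 10, 2), cv), "binary")
  expect_error(cdjsdm(matrix(0:1, 10, 1), cv), "two species")
})

test_that("per-draw residual covariance is low-rank positive semidefinite", {
  cfg <- sim_config(n_stations = 80, n_species = 5, n_factors = 2,
                    seed = 41)
  truth <- sim_community(cfg, sim_covariates(80, seed = 41))
  fit <- suppressWarnings(
    cdjsdm(truth$occupancy, truth$covariates, nf = 2, n_chains = 1,
           n_burn = 50, n_samples = 60, seed = 3))
  set.seed(2)
  for (d in sample(60, 10)) {
    lam <- array(fit$draws$lambda[d, , , ], c(3, 5, 2))
    L <- loadings_at(lam, c(1, 0.4, -0.2))
    omega <- tcrossprod(L)
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_lte(sum(ev > 1e-8), 2)   # rank <= nf
  }
})

test_that("prediction context levels follow the observed gradient", {
  cfg <- sim_config(n_stations = 100, n_species = 4, n_factors = 2,
                    seed = 51)
  truth <- sim_community(cfg, sim_covariates(100, seed = 51))
  fit <- suppressWarnings(
    cdjsdm(truth$occupancy, truth$covariates, nf = 2, n_chains = 1,
           n_burn = 100, n_samples = 150, seed = 4))
  est <- predict(fit, "human_modification", "max")
  expect_equal(unname(est$context["human_modification_z"]),
               max(fit$x_star[, "human_modification_z"]))
  expect_equal(unname(est$context["human_presence_logz"]),
               mean(fit$x_star[, "human_presence_logz"]), tolerance = 1e-12)
  expect_true(all(est$R_lower <= est$R_mean + 1e-12))
  expect_true(all(est$R_mean <= est$R_upper + 1e-12))
  expect_equal(diag(est$R_mean), rep(1, 4), ignore_attr = TRUE)
  expect_error(predict(fit, "elevation"), "unknown context")
})

test_that("pair classification counts match a hand tally", {
  R <- diag(1, 3)
  R[1, 2] <- R[2, 1] <- 0.5
  R[1, 3] <- R[3, 1] <- -0.2
  R[2, 3] <- R[3, 2] <- 0.1
  lo <- R - 0.15; hi <- R + 0.15
  diag(lo) <- diag(hi) <- 1
  counts <- classify_pairs(list(R_mean = R, R_lower = lo, R_upper = hi))
  expect_equal(counts$n_pairs, 3)
  expect_equal(counts$positive, 2)
  expect_equal(counts$negative, 1)
  expect_equal(counts$significant_positive, 1)  # only the 0.5 pair
  expect_equal(counts$significant_negative, 1)  # the -0.2 pair
  # strict positivity: exact zeros count as neither
  R0 <- diag(1, 3)
  c0 <- classify_pairs(list(R_mean = R0, R_lower = R0 - 1, R_upper = R0 + 1))
  expect_equal(c0$positive, 0)
  expect_equal(c0$negative, 0)
})

test_that("DIC is deterministic given a posterior and orders model fit", {
  cfg <- sim_config(n_stations = 150, n_species = 4, n_factors = 1,
                    seed = 61)
  truth <- sim_community(cfg, sim_covariates(150, seed = 61))
  fit <- suppressWarnings(
    cdjsdm(truth$occupancy, truth$covariates, nf = 1, n_chains = 1,
           n_burn = 100, n_samples = 200, seed = 6))
  d1 <- dic(fit); d2 <- dic(fit)
  expect_identical(d1, d2)
  expect_true(is.finite(d1$dic))
})

test_that("DIC prefers a structured fit over a null fit on clean data", {
  # strong shared-factor community; intercept-only null comparator
  lam <- array(0, c(3, 4, 1)); lam[1, , 1] <- c(1.5, 1.5, -1.5, -1.5)
  cfg <- sim_config(n_stations = 250, n_species = 4, n_factors = 1,
                    beta_true = matrix(0, 4, 5), lambda_true = lam,
                    seed = 71)
  truth <- sim_community(cfg, sim_covariates(250, seed = 71))
  fit_full <- suppressWarnings(
    cdjsdm(truth$occupancy, truth$covariates, nf = 1,
           n_chains = 1, n_burn = 200, n_samples = 300, seed = 7))
  cv0 <- data.frame(intercept = rep(1, 250))
  fit_null <- suppressWarnings(
    cdjsdm(truth$occupancy, cv0, context = character(0),
           nf = 1, n_chains = 1, n_burn = 200,
           n_samples = 300, seed = 7,
           prior_sd_lambda = 1e-3))   # loadings pinned near zero
  expect_lt(dic(fit_full)$dic, dic(fit_null)$dic)
})

test_that("summary and accessors expose the posterior coherently", {
  cfg <- sim_config(n_stations = 80, n_species = 3, n_factors = 1,
                    seed = 81)
  truth <- sim_community(cfg, sim_covariates(80, seed = 81))
  fit <- suppressWarnings(
    cdjsdm(truth$occupancy, truth$covariates, nf = 1, n_chains = 2,
           n_burn = 80, n_samples = 120, seed = 8))
  s <- summary(fit)
  expect_equal(nrow(s), 3 * 5)
  expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  expect_equal(dim(coef(fit)), c(3L, 5L))
  psi <- fitted(fit, thin = 20)
  expect_true(all(psi >= 0 & psi <= 1))
  expect_equal(dim(residuals(fit, thin = 20)), dim(truth$occupancy))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] %in% 0:1))
})
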