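test_that("selection benchmark scenario matches its published design", {
  sc <- caseIScenario()
  expect_equal(dim(sc$coeffs), c(2, 10))
  # null covariates have all-zero coefficient columns (1, 5, 7, 8, 9)
  nullCols <- c(1, 5, 7, 8, 9) + 1
  expect_true(all(sc$coeffs[, nullCols] == 0))
  # covariates 2, 4, 6 act on both equations; 3 mainly on the first
  expect_true(all(sc$coeffs[, c(3, 5, 7)] != 0))
  expect_equal(sc$coeffs[, 4], c(-3, 0.5))
  expect_equal(sc$alphaPlus, 50)
  expect_equal(sc$p, c(0.25, 0.25, 0.5))
  expect_equal(sc$wtilde, c(0.6, 0.8, 0.7))
  sim <- simulateScenario(sc, seed = 1)
  Y <- countMatrix(sim$data)
  expect_equal(dim(Y), c(750, 3))
  expect_true(all(rowSums(Y) >= 1))
  # mean total reads close to the Poisson mean
  expect_lt(abs(mean(rowSums(Y)) - 50), 3 * sqrt(50 / 750))
})

test_that("recovery benchmark scenario carries the documented truth", {
  sc <- caseIVScenario()
  expect_equal(sc$coeffs[, 1], c(-0.5, 1.5, 2, 3))
  expect_equal(sc$coeffs[, 2], c(1.8, -2.5, -1, -2))
  tr <- EFDMreg:::.truthVector(sc)
  expect_equal(unname(tr["alphaPlus"]), 50)
  expect_equal(unname(tr["p[2]"]), 0.3)
  expect_equal(unname(tr["wtilde[2]"]), 0.3)
  # dm variant drops the mixture truth
  trdm <- EFDMreg:::.truthVector(caseIVScenario("dm"))
  expect_false(any(grepl("wtilde", names(trdm))))
  # fixed seed reproduces the dataset bitwise
  s1 <- simulateScenario(sc, seed = 9, N = 40)
  s2 <- simulateScenario(sc, seed = 9, N = 40)
  expect_identical(countMatrix(s1$data), countMatrix(s2$data))
  expect_identical(covariateMatrix(s1$data), covariateMatrix(s2$data))
})

test_that("generated counts match the model moments at fixed covariates", {
  # intercept-only scenario: mu is constant, so empirical moments must match
  # the distribution-level formulas
  mu <- c(0.1, 0.35, 0.25, 0.12, 0.18)
  sc <- efdmScenario("m", "efdm", coeffs = matrix(log(mu[-5] / mu[5]), 4, 1),
                     alphaPlus = 50, p = c(0.25, 0.3, 0.2, 0.1, 0.15),
                     wtilde = c(0.6, 0.3, 0.9, 0.4, 0.35),
                     N = 30000, readsMean = 60)
  sim <- simulateScenario(sc, seed = 17)
  Y <- countMatrix(sim$data)
  mp <- efdmMeanParams(mu, 50, sc$p, sc$wtilde)
  # totals vary by sample; compare proportions against mu and the count
  # covariance at the realized totals via the law of total variance
  prop <- Y / rowSums(Y)
  se <- sqrt(diag(efdMoments(asStandardParams(mp))$cov) / nrow(Y)) + 1e-3
  expect_true(all(abs(colMeans(prop) - mu) < 3.5 * se))
})

test_that("logistic-normal generator spans multinomial and correlated regimes", {
  co <- matrix(c(0.3, -0.2, 0.1), 3, 1)
  # zero latent covariance: plain multinomial at fixed mu
  s0 <- simulateLogisticNormal(co, matrix(0, 3, 3), N = 20000,
                               readsMean = 50, seed = 3)
  Y <- countMatrix(s0$data)
  mu <- as.numeric(logitLinkMean(co, 1))
  prop <- Y / rowSums(Y)
  expect_lt(max(abs(colMeans(prop) - mu)), 0.01)
  # normalized variance stays at the multinomial benchmark 1/n
  nv <- apply(Y, 2, var) / (colMeans(Y) * (mean(rowSums(Y)) - colMeans(Y)))
  expect_lt(max(nv), 0.035) # 1/n plus Poisson-total slack at n ~ 50
  # a strongly correlated latent pair produces positive count correlation
  Sig <- diag(c(4, 4, 0.2)); Sig[1, 2] <- Sig[2, 1] <- 0.95 * 4
  s1 <- simulateLogisticNormal(co, Sig, N = 20000, readsMean = 50, seed = 4)
  Y1 <- countMatrix(s1$data)
  cc <- cor(Y1 / rowSums(Y1))
  expect_gt(max(cc[upper.tri(cc)]), 0.2)
  # mean proportions match an independent softmax-normal Monte Carlo oracle
  set.seed(5)
  Z <- matrix(rnorm(2e5 * 3), ncol = 3) %*% chol(Sig)
  eta <- sweep(Z, 2, as.numeric(co), "+")
  ex <- cbind(exp(eta), 1)
  oracle <- colMeans(ex / rowSums(ex))
  expect_lt(max(abs(colMeans(Y1 / rowSums(Y1)) - oracle)), 0.01)
  expect_error(simulateLogisticNormal(co, matrix(-1, 3, 3), N = 10),
               "positive semidefinite")
})

test_that("excess-zero generator inflates zeros beyond the DM baseline", {
  sc <- caseIVScenario("dm")
  plain <- simulateScenario(sc, seed = 31, N = 400)
  inflated <- simulateExcessZeros(sc, zeroProb = 0.4, seed = 31, N = 400)
  z0 <- mean(countMatrix(plain$data) == 0)
  z1 <- mean(countMatrix(inflated$data) == 0)
  expect_gt(z1, z0 + 0.2)
  expect_true(all(rowSums(countMatrix(inflated$data)) >= 1))
})

test_that("replication harness aggregates metrics deterministically", {
  sc <- caseIVScenario("dm")
  mc <- mcmcConfig(chains = 1, warmup = 600, iter = 400, thin = 4)
  r1 <- replicationStudy(sc, fitFamilies = "dm", B = 2, mcmc = mc,
                         seed = 5, N = 60, readsMean = 30)
  r2 <- replicationStudy(sc, fitFamilies = "dm", B = 2, mcmc = mc,
                         seed = 5, N = 60, readsMean = 30)
  expect_identical(r1$summary, r2$summary)
  expect_equal(r1$failed, 0L)
  expect_equal(nrow(r1$waic), 2)
  expect_true(all(c("postMean", "rMSE", "coverage") %in% names(r1$summary)))
  # every truth parameter of the dm family is summarized
  expect_setequal(r1$summary$parameter,
                  names(EFDMreg:::.truthVector(sc)))
})
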