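test_that("WAIC formula on degenerate and hand-computed inputs", {
  # identical draws: no effective parameters, waic = -2 sum ll
  ll <- matrix(rep(c(log(0.2), log(0.6)), each = 3), 3, 2)
  w <- waic(ll)
  expect_equal(w$pWaic, 0)
  expect_equal(w$waic, -2 * (log(0.2) + log(0.6)))
  # two-draw toy matrix, computed by hand from the definition
  llm <- matrix(c(log(.5), log(.25), log(.5), log(.75)), 2, 2)
  lppd <- log(mean(c(.5, .25))) + log(mean(c(.5, .75)))
  pw <- var(c(log(.5), log(.25))) + var(c(log(.5), log(.75)))
  w2 <- waic(llm)
  expect_equal(w2$lppd, lppd, tolerance = 1e-12)
  expect_equal(w2$pWaic, pw, tolerance = 1e-12)
  expect_equal(w2$waic, -2 * (lppd - pw), tolerance = 1e-12)
  expect_error(waic(matrix(c(1, NaN), 2, 1)), "non-finite")
  expect_error(waic(matrix(1, 1, 3)), "two posterior draws")
})

test_that("posterior summary: degenerate, Gaussian and coverage cases", {
  const <- matrix(2.5, 100, 1, dimnames = list(NULL, "a"))
  s <- posteriorSummary(const)
  expect_equal(s$lower, 2.5)
  expect_equal(s$upper, 2.5)
  set.seed(2)
  z <- matrix(rnorm(2e5), ncol = 1, dimnames = list(NULL, "z"))
  s2 <- posteriorSummary(z, level = 0.95)
  expect_equal(s2$lower, -1.96, tolerance = 0.02)
  expect_equal(s2$upper, 1.96, tolerance = 0.02)
  s3 <- posteriorSummary(const, truth = c(a = 2.5))
  expect_true(s3$covered)
  expect_equal(s3$sqErr, 0)
  expect_error(posteriorSummary(const, level = 1.2), "level")
})

test_that("fitting machinery produces coherent posterior objects", {
  res <- tinyFit()
  fit <- res$fit
  draws <- posteriorDraws(fit)
  expect_equal(nrow(draws), 200)
  expect_true(all(c("beta[1,0]", "beta[1,1]", "alphaPlus") %in%
                    colnames(draws)))
  expect_true(all(draws[, "alphaPlus"] > 0))
  expect_equal(dim(logLikMatrix(fit)), c(200, 80))
  expect_true(all(is.finite(logLikMatrix(fit))))
  d <- diagnostics(fit)
  expect_true(all(d$acceptRate > 0.05 & d$acceptRate < 0.6))
  expect_equal(d$seed, 7)
  # efdm fit: simplex and unit-interval draws stay in their domains
  fit2 <- fitEFDMReg(res$sim$data, "efdm",
                     mcmc = mcmcConfig(chains = 1, warmup = 600, iter = 400,
                                       thin = 4, seed = 3))
  dr <- posteriorDraws(fit2)
  pcols <- paste0("p[", 1:5, "]")
  expect_equal(unname(rowSums(dr[, pcols])), rep(1, nrow(dr)),
               tolerance = 1e-12)
  wcols <- paste0("wtilde[", 1:5, "]")
  expect_true(all(dr[, wcols] > 0 & dr[, wcols] < 1))
})

test_that("two seeds give compatible posterior means", {
  sim <- simulateScenario(caseIVScenario(), seed = 55, N = 120,
                          readsMean = 50)
  m1 <- fitEFDMReg(sim$data, "dm",
                   mcmc = mcmcConfig(chains = 1, warmup = 1500, iter = 1500,
                                     thin = 3, seed = 1))
  m2 <- fitEFDMReg(sim$data, "dm",
                   mcmc = mcmcConfig(chains = 1, warmup = 1500, iter = 1500,
                                     thin = 3, seed = 99))
  s1 <- posteriorSummary(m1); s2 <- posteriorSummary(m2)
  ess1 <- diagnostics(m1)$ess; ess2 <- diagnostics(m2)$ess
  mcse <- sqrt(s1$sd^2 / pmax(ess1, 5) + s2$sd^2 / pmax(ess2, 5))
  expect_true(all(abs(s1$mean - s2$mean) < 4 * mcse + 1e-3))
})

test_that("with the likelihood disabled the sampler recovers the priors", {
  y <- matrix(5L, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  d <- efdmExperiment(y)
  fit <- fitEFDMReg(d, "efdm", priors = priorConfig(),
                    mcmc = mcmcConfig(chains = 1, warmup = 4000, iter = 8000,
                                      thin = 4, seed = 11),
                    likelihoodWeight = 0)
  dr <- posteriorDraws(fit)
  # alpha+ ~ Gamma(k g, g) with k = 50, g = 0.01
  ks1 <- suppressWarnings(stats::ks.test(dr[, "alphaPlus"], stats::pgamma,
                                         shape = 0.5, rate = 0.01))
  expect_gt(ks1$p.value, 0.01)
  # wtilde_r ~ Beta(1, 1) = uniform
  ks2 <- suppressWarnings(stats::ks.test(dr[, "wtilde[2]"], stats::punif))
  expect_gt(ks2$p.value, 0.01)
  # p_1 ~ Beta(1, D - 1) under the uniform Dirichlet
  ks3 <- suppressWarnings(stats::ks.test(dr[, "p[1]"], stats::pbeta,
                                         shape1 = 1, shape2 = 2))
  expect_gt(ks3$p.value, 0.01)
  # coefficients ~ N(0, 10^2)
  ks4 <- suppressWarnings(stats::ks.test(dr[, "beta[1,0]"] / 10,
                                         stats::pnorm))
  expect_gt(ks4$p.value, 0.01)
})

test_that("posterior draws can be persisted and reloaded", {
  fit <- tinyFit()$fit
  dir <- tempfile("post")
  paths <- writePosterior(fit, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  expect_equal(as.matrix(back), posteriorDraws(fit), tolerance = 1e-12,
               ignore_attr = TRUE)
  side <- jsonlite::read_json(file.path(dir, "diagnostics.json"))
  expect_equal(side$seed, 7)
  expect_equal(side$family, "dm")
  expect_true(!is.null(side$configDigest))
  summ <- utils::read.csv(file.path(dir, "summary.csv"))
  expect_equal(summ$mean, unname(colMeans(posteriorDraws(fit))),
               tolerance = 1e-10)
})
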