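test_that("posterior-predictive draws respect totals and the fitted mean", {
  res <- tinyFit()
  pp <- posteriorPredictive(res$fit, res$sim$data, nRep = 60, seed = 3)
  Y <- countMatrix(res$sim$data)
  expect_equal(dim(pp), c(60, 80, 5))
  for (s in c(1, 30, 60))
    expect_equal(unname(rowSums(pp[s, , ])), unname(rowSums(Y)))
  # tower property: predictive mean proportions track the posterior mean mu
  draws <- posteriorDraws(res$fit)
  bcols <- grep("^beta\\[", colnames(draws))
  co <- matrix(colMeans(draws)[bcols], 4, 2, byrow = TRUE)
  muHat <- logitLinkMean(co, covariateMatrix(res$sim$data), 5)
  predProp <- apply(pp, c(2, 3), mean) / rowSums(Y)
  expect_lt(mean(abs(predProp - muHat)), 0.02)
})

test_that("zero metrics follow their confusion-count definitions", {
  obs <- rbind(c(0L, 3L, 2L), c(1L, 0L, 4L))
  perfect <- array(rep(obs, each = 2), c(2, 2, 3))
  zm <- zeroMetrics(obs, perfect)
  expect_equal(zm$accuracy, 1)
  expect_equal(zm$sensitivity, 1)
  expect_equal(zm$specificity, 1)
  expect_equal(zm$ppv, 1)
  expect_equal(zm$npv, 1)
  expect_equal(sum(zm$counts), length(obs))
  # an all-positive prediction finds no zeros but keeps specificity
  nonzero <- array(1L, c(2, 2, 3))
  zm2 <- zeroMetrics(obs, nonzero)
  expect_equal(zm2$sensitivity, 0)
  expect_equal(zm2$specificity, 1)
  expect_true(is.na(zm2$ppv))
  # accuracy is recomputable from the cells
  expect_equal(zm2$accuracy,
               (zm2$counts[["tp"]] + zm2$counts[["tn"]]) / sum(zm2$counts))
})

test_that("KL divergence is zero at equality and positive otherwise", {
  obs <- rbind(c(5L, 5L, 10L), c(8L, 2L, 10L))
  same <- array(rep(obs, each = 3), c(3, 2, 3))
  expect_lt(klDivergence(obs, same), 1e-12)
  set.seed(4)
  other <- array(rpois(3 * 2 * 3, 5) + 1L, c(3, 2, 3))
  expect_gt(klDivergence(obs, other), 0)
})

test_that("correlation networks keep the sign structure of the moments", {
  # DM moments: all interclass correlations negative, so no positive edges
  mu <- c(0.3, 0.25, 0.45)
  dm <- efdmParams(5 * mu, rep(1, 3), mu)
  net <- correlationNetwork(efdmMoments(dm, 30), negThreshold = -0.01)
  expect_true(all(net$sign == "negative"))
  expect_false(any(net$source == net$target))
  # a strong negative threshold can suppress everything
  netNone <- correlationNetwork(efdmMoments(dm, 30), negThreshold = -2)
  expect_equal(nrow(netNone), 0)
  # the positive-dependence parameter set produces a positive edge
  pos <- correlationNetwork(efdmMoments(positiveDependenceParams(), 30),
                            labels = c("A", "B", "C", "D"))
  expect_true(any(pos$sign == "positive"))
  expect_true(all(pos$weight[pos$sign == "positive"] > 0))
  # deterministic ordering
  pos2 <- correlationNetwork(efdmMoments(positiveDependenceParams(), 30),
                             labels = c("A", "B", "C", "D"))
  expect_identical(pos, pos2)
})

test_that("class-correlation tables expose the model hierarchy", {
  mu <- c(0.3, 0.25, 0.45)
  # DM: constant intraclass column 1 / (alpha+ + 1)
  tabDM <- classCorrelationTable(efdmMoments(efdmParams(5 * mu, rep(1, 3), mu),
                                             40))
  expect_equal(tabDM$perTaxon$intraclass, rep(1 / 6, 3), tolerance = 1e-10)
  # near-multinomial limit: intraclass vanishes
  tabM <- classCorrelationTable(
    efdmMoments(efdmParams(1e8 * mu, rep(1, 3), mu), 40))
  expect_lt(max(tabM$perTaxon$intraclass), 1e-6)
  # heterogeneous tau: intraclass varies across taxa
  sp <- efdmParams(c(1, 2, 3), c(8, 1, 3), c(0.2, 0.3, 0.5))
  tabE <- classCorrelationTable(efdmMoments(sp, 40), labels = c("x", "y", "z"))
  expect_gt(diff(range(tabE$perTaxon$intraclass)), 0.01)
  expect_equal(rownames(tabE$interclass), c("x", "y", "z"))
})

test_that("posterior-averaged moments reflect the fitted dependence", {
  fit <- tinyFit()$fit
  mom <- fittedMoments(fit, size = 40, nDraws = 50)
  expect_s4_class(mom, "EFDMMoments")
  # a dm fit keeps the constant-intraclass signature of the family
  expect_lt(diff(range(mom@intraclass)), 1e-8)
  expect_lt(max(abs(rowSums(mom@cov))), 1e-8)
})
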