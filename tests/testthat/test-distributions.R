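test_that("DM pmf: single-draw reduction, normalization, multinomial limit", {
  # n = 1 reduces to the multinomial mean
  expect_equal(ddm(c(1, 0), mu = c(0.3, 0.7), alphaPlus = 3.7, log = TRUE),
               log(0.3))
  # brute-force normalization over the 3-part simplex at n = 4
  g <- simplexGrid(3, 4)
  expect_equal(sum(ddm(g, mu = c(0.2, 0.3, 0.5), alphaPlus = 2)), 1,
               tolerance = 1e-12)
  # large precision approaches the multinomial pmf
  y <- c(3, 1, 2)
  mult <- lgamma(7) - sum(lgamma(y + 1)) + sum(y * log(c(0.2, 0.3, 0.5)))
  expect_equal(ddm(y, c(0.2, 0.3, 0.5), 1e8, log = TRUE), mult,
               tolerance = 1e-4)
  # no overflow at large totals
  yy <- c(60000, 40000)
  expect_true(is.finite(ddm(yy, c(0.6, 0.4), 5, log = TRUE)))
  # argument validation
  expect_error(ddm(c(1, 2), mu = c(0.7, 0.7), alphaPlus = 1), "sum to 1")
  expect_error(ddm(c(1, 2), mu = c(0.5, 0.5), alphaPlus = -1), "positive")
  expect_error(ddm(c(-1, 2), mu = c(0.5, 0.5), alphaPlus = 1), "nonnegative")
})

test_that("EFDM pmf agrees with the rising-factorial form and normalizes", {
  sp <- efdmParams(c(1, 2, 3), c(2, 1, 4), c(0.2, 0.3, 0.5))
  g <- simplexGrid(3, 5)
  expect_equal(sum(defdm(g, sp)), 1, tolerance = 1e-12)
  direct <- apply(g, 1, efdmDirectLogPmf, alpha = sp@alpha, tau = sp@tau,
                  p = sp@p)
  expect_equal(defdm(g, sp, log = TRUE), direct, tolerance = 1e-10)
  # symmetric two-part case at n = 1
  sym <- efdmParams(c(1, 1), c(1, 1), c(0.5, 0.5))
  expect_equal(defdm(c(1, 0), sym, log = TRUE), log(0.5))
})

test_that("EFDM pmf normalizes across dimensions and random parameters", {
  set.seed(101)
  shapes <- list(c(2, 6), c(3, 5), c(4, 4))
  for (i in 1:25) {
    for (sh in shapes) {
      sp <- randomParams(sh[1], allowZeroWeight = (i %% 5 == 0))
      tot <- sum(defdm(simplexGrid(sh[1], sh[2]), sp))
      expect_equal(tot, 1, tolerance = 1e-8)
    }
  }
})

test_that("EFDM reduces to DM at tau = 1, p = alpha / alpha+", {
  mu <- c(0.15, 0.35, 0.5); ap <- 6
  sp <- efdmParams(ap * mu, rep(1, 3), mu)
  g <- simplexGrid(3, 6)
  expect_equal(defdm(g, sp, log = TRUE), ddm(g, mu, ap, log = TRUE),
               tolerance = 1e-12)
  # and the DM moments follow: cov = n M(mu) (1 + (n-1)/(ap+1)),
  # constant intraclass 1 / (ap + 1)
  m <- efdmMoments(sp, 12)
  Mmu <- diag(mu) - tcrossprod(mu)
  expect_equal(m@cov, 12 * Mmu * (1 + 11 / (ap + 1)), tolerance = 1e-10)
  expect_equal(m@intraclass, rep(1 / (ap + 1), 3), tolerance = 1e-12)
  expect_equal(m@nvar, rep(1 / 12 + (11 / 12) / (ap + 1), 3),
               tolerance = 1e-12)
})

test_that("EFDM moments match brute-force enumeration at (D, n) = (3, 6)", {
  set.seed(7)
  for (i in 1:5) {
    sp <- randomParams(3)
    em <- enumMoments(sp, 6)
    m <- efdmMoments(sp, 6)
    expect_equal(m@mean, em$mean, tolerance = 1e-8)
    expect_equal(m@cov, em$cov, tolerance = 1e-8)
  }
})

test_that("covariance matrices have zero row sums and are PSD", {
  set.seed(11)
  for (i in 1:20) {
    sp <- randomParams(sample(2:6, 1))
    m <- efdmMoments(sp, sample(2:80, 1))
    expect_lt(max(abs(rowSums(m@cov))), 1e-8)
    expect_gt(min(eigen(m@cov, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
    expect_true(all(m@intraclass > 0 & m@intraclass < 1))
    off <- m@interclass[upper.tri(m@interclass)]
    expect_true(all(off >= -1 & off <= 1))
    expect_true(all(m@nvar >= 1 / m@size - 1e-12 & m@nvar <= 1 + 1e-12))
  }
})

test_that("class correlations match the n = 2 enumeration decomposition", {
  set.seed(19)
  for (i in 1:5) {
    sp <- randomParams(3)
    cc <- enumClassCorr(sp)
    m <- efdmMoments(sp, 2)
    expect_equal(m@intraclass, cc$intra, tolerance = 1e-8)
    off <- upper.tri(cc$inter)
    expect_equal(m@interclass[off], cc$inter[off], tolerance = 1e-8)
  }
})

test_that("latent-composition moments are n-free and tie to class correlations", {
  sp <- efdmParams(c(1, 2, 3), c(2, 1, 4), c(0.2, 0.3, 0.5))
  em <- efdMoments(sp)
  # inverting the total-variance law at any n recovers the same Pi-covariance
  for (n in c(2, 100)) {
    m <- efdmMoments(sp, n)
    mu <- m@mean / n
    Mmu <- diag(mu) - tcrossprod(mu)
    VPi <- (m@cov / n - Mmu) / (n - 1)
    expect_equal(VPi, em$cov, tolerance = 1e-9)
  }
  # intraclass equals the normalized variance of Pi, interclass the product
  # form Corr(Pi) * sqrt(nvar_r nvar_s)
  m <- efdmMoments(sp, 10)
  denom <- em$mean * (1 - em$mean)
  expect_equal(m@intraclass, diag(em$cov) / denom, tolerance = 1e-10)
  corrPi <- stats::cov2cor(em$cov)
  prod <- corrPi * tcrossprod(sqrt(diag(em$cov) / denom))
  off <- upper.tri(prod)
  expect_equal(m@interclass[off], prod[off], tolerance = 1e-10)
})

test_that("FDM closed forms agree with the general mixture route", {
  sp <- efdmParams(c(2, 2, 2), c(3, 3, 3), c(1/3, 1/3, 1/3))
  m1 <- efdmMoments(sp, 20); m2 <- fdmMoments(sp, 20)
  expect_equal(m1@cov, m2@cov, tolerance = 1e-10)
  expect_equal(m1@intraclass, m2@intraclass, tolerance = 1e-10)
  off <- upper.tri(m1@interclass)
  expect_equal(m1@interclass[off], m2@interclass[off], tolerance = 1e-10)
  # asymmetric equal-tau case
  sp2 <- efdmParams(c(1, 4, 2, 3), rep(2.5, 4), c(0.4, 0.1, 0.2, 0.3))
  m1 <- efdmMoments(sp2, 35); m2 <- fdmMoments(sp2, 35)
  expect_equal(m1@cov, m2@cov, tolerance = 1e-10)
  expect_equal(m1@intraclass, m2@intraclass, tolerance = 1e-10)
  # FDM interclass correlations are all negative
  expect_true(all(m2@interclass[upper.tri(m2@interclass)] < 0))
  # DM reduction: tau = 1 and p = alpha / alpha+
  mu <- c(0.3, 0.45, 0.25)
  spdm <- efdmParams(8 * mu, rep(1, 3), mu)
  mdm <- fdmMoments(spdm, 15)
  expect_equal(mdm@intraclass, rep(1 / 9, 3), tolerance = 1e-12)
  expect_error(fdmMoments(efdmParams(c(1, 1, 1), c(1, 2, 3),
                                     c(0.3, 0.3, 0.4)), 10), "common tau")
})

test_that("positive interclass correlation is attainable (and never for DM)", {
  sp <- positiveDependenceParams()
  ic <- efdmMoments(sp, 10)@interclass
  expect_gt(max(ic, na.rm = TRUE), 0.1)
  # verified independently by enumeration
  cc <- enumClassCorr(sp)
  expect_equal(max(ic, na.rm = TRUE),
               max(cc$inter[upper.tri(cc$inter)]), tolerance = 1e-8)
})

test_that("count correlations converge to composition correlations (n large)", {
  sp <- efdmParams(c(1, 2, 3), c(2, 1, 4), c(0.2, 0.3, 0.5))
  m <- efdmMoments(sp, 1e4)
  corrY <- stats::cov2cor(m@cov)
  corrPi <- stats::cov2cor(efdMoments(sp)$cov)
  expect_lt(max(abs(corrY - corrPi)), 1e-2)
})

test_that("distinct parameters give distinct pmfs (identifiability spot check)", {
  set.seed(23)
  g <- simplexGrid(3, 4)
  for (i in 1:20) {
    a <- randomParams(3); b <- randomParams(3)
    expect_gt(max(abs(defdm(g, a) - defdm(g, b))), 1e-6)
  }
})

test_that("EFDM sampler is reproducible and matches the moment formulas", {
  sp <- efdmParams(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4),
                   c(0.1, 0.2, 0.3, 0.2, 0.2))
  y1 <- refdm(rep(50, 10), sp, seed = 5)
  y2 <- refdm(rep(50, 10), sp, seed = 5)
  expect_identical(y1, y2)
  expect_true(all(rowSums(y1) == 50))
  n <- 4e4
  y <- refdm(rep(50, n), sp, seed = 6)
  th <- efdmMoments(sp, 50)
  se <- sqrt(diag(th@cov) / n)
  expect_true(all(abs(colMeans(y) - th@mean) < 3.5 * se))
  # intraclass recovered from sampled compositions
  set.seed(8)
  comp <- sample.int(5, n, TRUE, sp@p)
  conc <- matrix(sp@alpha, n, 5, byrow = TRUE)
  conc[cbind(1:n, comp)] <- conc[cbind(1:n, comp)] + sp@tau[comp]
  gmat <- matrix(rgamma(n * 5, conc), n, 5)
  pis <- gmat / rowSums(gmat)
  empIntra <- apply(pis, 2, var) / (colMeans(pis) * (1 - colMeans(pis)))
  expect_lt(max(abs(empIntra - th@intraclass)), 0.02)
})

test_that("normalized variance benchmarks", {
  expect_equal(normalizedVariance(0.3 * 0.7, 0.3, 1), 1)
  # multinomial component: n pi (1 - pi) normalized by n pi (n - n pi)
  n <- 40; pi <- 0.23
  expect_equal(normalizedVariance(n * pi * (1 - pi), n * pi, n), 1 / n)
  expect_error(normalizedVariance(1, 0, 1), "strictly inside")
})

test_that("zero-weight components follow the pinned-tau convention", {
  sp <- efdmParams(c(1, 2, 3), c(9, 9, 9), c(0, 0.4, 0.6))
  expect_equal(sp@tau[1], 1)
  g <- simplexGrid(3, 4)
  expect_equal(sum(defdm(g, sp)), 1, tolerance = 1e-10)
  mp <- asMeanParams(sp)
  expect_equal(mp@wtilde[1], 0.5)
})
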