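test_that("inverse normal transform hits the closed-form quantiles and is rank-invariant", {
  expect_equal(inverseNormalTransform(c(3, 1, 2)),
               qnorm(c(5 / 6, 1 / 6, 3 / 6)), tolerance = 1e-12)
  set.seed(1)
  y <- rlnorm(500)
  expect_equal(inverseNormalTransform(y), inverseNormalTransform(log(y) * 7 - 2))
  z <- inverseNormalTransform(y)
  expect_lt(abs(mean(z)), 0.01)
  expect_equal(var(z), 1, tolerance = 0.02)
  skw <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(abs(skw), 0.05)
  expect_error(inverseNormalTransform(rep(1, 5)), "distinct")
  expect_equal(inverseNormalTransform(c(1, NA, 2))[2], NA_real_)
})

test_that("linear engine is exact on noiseless data and flags collinearity", {
  g <- c(0, 1, 2, 0, 1, 2)
  r <- suppressWarnings(fitLinear(2 * g, g))  # noiseless fit warns in summary.lm
  expect_equal(r$contrasts$beta, 2, tolerance = 1e-12)
  expect_equal(unname(r$intercepts), 0, tolerance = 1e-12)
  X <- data.frame(a = g * 3)   # collinear with dosage
  expect_error(fitLinear(rnorm(6), g, X), "collinear")
})

test_that("binary logistic matches the balanced-table zero and a numeric likelihood oracle", {
  y <- rep(c(0, 1, 0, 1), each = 10)
  g <- rep(c(0, 0, 1, 1), each = 10)
  r <- fitBinaryLogistic(y, g)
  expect_equal(r$contrasts$beta, 0, tolerance = 1e-10)

  set.seed(7)
  g <- rbinom(40, 2, 0.4); x1 <- rnorm(40)
  y <- rbinom(40, 1, plogis(-0.3 + 0.6 * g + 0.4 * x1))
  fit <- fitBinaryLogistic(y, g, data.frame(x1 = x1))
  par <- oracleLogistic(y, g, cbind(x1))
  expect_equal(fit$contrasts$beta, par[2], tolerance = 1e-4)
  expect_equal(unname(fit$intercepts), par[1], tolerance = 1e-4)
})

test_that("perfect separation is flagged as non-converged", {
  y <- c(0, 0, 0, 1, 1, 1)
  g <- c(0, 0, 0, 2, 2, 2)
  r <- fitBinaryLogistic(y, g)
  expect_false(r$converged)
})

test_that("proportional-odds engine matches the likelihood oracle with increasing cutpoints", {
  y <- c(1, 1, 2, 2, 3, 3); g <- c(0, 0, 1, 1, 2, 2)
  ## jitter to avoid the degenerate perfectly-separated toy
  set.seed(3)
  yy <- c(y, sample(1:3, 30, TRUE)); gg <- c(g, rbinom(30, 2, 0.5))
  fit <- fitOrdinalLogistic(factor(yy, ordered = TRUE), gg)
  orc <- oracleOrdinal(yy, gg)
  expect_equal(fit$contrasts$beta, orc$beta[1], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(unname(fit$cutpoints), orc$theta, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_true(!is.unsorted(fit$cutpoints, strictly = TRUE))
})

test_that("ordinal on two occupied categories collapses to binary logistic", {
  set.seed(5)
  g <- rbinom(120, 2, 0.3)
  y <- factor(ifelse(runif(120) < plogis(-0.2 + 0.5 * g), "B2", "B1"),
              levels = c("B1", "B2", "B3"), ordered = TRUE)
  fo <- fitOrdinalLogistic(y, g)
  fb <- fitBinaryLogistic(as.integer(y == "B2"), g)
  expect_equal(fo$contrasts$beta, fb$contrasts$beta, tolerance = 1e-6)
  expect_equal(fo$model, "ordinal")
})

test_that("multinomial engine matches the likelihood oracle and collapses to binary", {
  set.seed(11)
  n <- 60
  g <- rbinom(n, 2, 0.4)
  eta1 <- 0.5 * g - 0.2; eta2 <- -0.4 * g + 0.1
  pr <- cbind(1, exp(eta1), exp(eta2)); pr <- pr / rowSums(pr)
  y <- apply(pr, 1, function(p) sample(c("L2", "L1", "L3"), 1, prob = p))
  fit <- fitMultinomialLogistic(y, g, reference = "L2")
  orc <- oracleMultinomial(relevel(factor(y), "L2"), g)
  ## oracle columns follow factor level order after releveling: L1, L3
  expect_equal(sort(fit$contrasts$beta), sort(orc$B[2, ]), tolerance = 1e-4)
  expect_equal(-fit$fit$deviance / 2, orc$logLik, tolerance = 1e-6)

  y2 <- ifelse(y == "L3", "L1", y)
  fm <- fitMultinomialLogistic(y2, g, reference = "L2")
  fb <- fitBinaryLogistic(as.integer(y2 == "L1"), g)
  expect_equal(fm$contrasts$beta, fb$contrasts$beta, tolerance = 1e-6)
  expect_error(fitMultinomialLogistic(y, g, reference = "L9"), "reference")
})

test_that("Weibull AFT matches the likelihood oracle and its own score equation", {
  set.seed(13)
  n <- 200
  g <- rbinom(n, 2, 0.3); x1 <- rnorm(n)
  t0 <- rweibull(n, shape = 1.3, scale = 10 * exp(0.3 * g + 0.2 * x1))
  cens <- runif(n, 2, 25)
  time <- pmin(t0, cens); event <- as.integer(t0 <= cens)
  expect_gt(mean(1 - event), 0.15)  # genuinely right-censored instance
  fit <- fitWeibullAFT(time, event, g, data.frame(x1 = x1))
  orc <- oracleWeibullAFT(time, event, g, cbind(x1))
  expect_equal(fit$contrasts$beta[1], orc$beta[1], tolerance = 1e-4)
  expect_equal(1 / fit$shape, orc$sigma, tolerance = 1e-4)
  expect_equal(fit$contrasts$beta[2], -orc$beta[1] / orc$sigma, tolerance = 1e-3)

  ## the likelihood oracle itself reproduces the exponential closed form
  ## (shape fixed at 1: rate MLE = n_events / sum(time))
  nll_mu <- function(mu) nllWeibullAFT(c(mu, 0, 0), time, event,
                                       X = matrix(0, n, 1))
  opt <- optimize(nll_mu, c(-5, 10), tol = 1e-10)
  expect_equal(opt$minimum, log(sum(time) / sum(event)), tolerance = 1e-6)
  expect_error(fitWeibullAFT(time, rep(0, n), g), "censored")
  expect_error(fitWeibullAFT(c(-1, time[-1]), event, g), "positive")
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  m <- metaFixed(data.frame(beta = c(0.1, 0.1), se = c(0.1, 0.1)))
  expect_equal(m$beta, 0.1)
  expect_equal(m$se, 0.1 / sqrt(2), tolerance = 1e-12)
  m2 <- metaFixed(data.frame(beta = c(0.3, -0.3), se = c(0.05, 0.05)))
  expect_equal(m2$beta, 0)
  ## age-at-diagnosis scale pooling: CD + UC study pair
  m3 <- metaFixed(data.frame(beta = c(-0.07, -0.06), se = c(0.01, 0.01)))
  expect_equal(m3$beta, -0.065)
  expect_equal(m3$se, 0.01 / sqrt(2), tolerance = 1e-12)
  expect_lt(m3$p, 2 * pnorm(-abs(-0.07 / 0.01)))
  expect_lt(m3$se, 0.01)   # pooled SE below the smallest input SE
  ## cross-check against an established meta-analysis implementation
  if (requireNamespace("metafor", quietly = TRUE)) {
    rma <- metafor::rma(yi = c(-0.07, -0.06), sei = c(0.01, 0.01), method = "FE")
    expect_equal(m3$beta, as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(m3$se, rma$se, tolerance = 1e-10)
  }
  r1 <- fitLinear(rnorm(30), rbinom(30, 2, .3)); r1$variant <- "a"
  r2 <- fitLinear(rnorm(30), rbinom(30, 2, .3)); r2$variant <- "b"
  expect_error(metaFixed(list(r1, r2)), "mismatched variant ids")
})

test_that("Wald and LRT p-values agree within a factor 1.5 for moderate effects", {
  set.seed(17)
  n <- 5000
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + 0.12 * g))
  pw <- fitBinaryLogistic(y, g, p_method = "wald")$p
  pl <- fitBinaryLogistic(y, g, p_method = "lrt")$p
  expect_lt(max(pw / pl, pl / pw), 1.5)
})
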