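## small cohorts with targeted effect structure for scan behaviour
spikeEffectTable <- function(spike_id = "NOD2_like", spike_beta = log(2.5),
                             n_null = 30, background = 0.12) {
  ## weak polygenic background on the location axis keeps the location bands
  ## from degenerating onto any single locus
  data.frame(
    id = c(spike_id, sprintf("nul%02d", seq_len(n_null))),
    maf = c(0.2, runif(n_null, 0.1, 0.5)),
    beta_ileal = c(spike_beta,
                   runif(n_null, -background, background)),
    beta_colonic = 0, beta_UC = 0,
    age_shift = 0, surgery_loghr = 0, extent_logor = 0,
    locus_group = c("NOD2", rep("OTHER", n_null)), is_hla = FALSE,
    stringsAsFactors = FALSE
  )
}

cleanSim <- function(eff, n = 4000, seed = 1, ...) {
  simulateCohort(simulationConfig(
    n_samples = n, effect_table = eff, pc_class_effect = 0,
    ibdu_margin = 0, n_null_variants = 0,
    missing_rates = list(location = 0, behaviour = 0, extent = 0, age = 0,
                         smoking = 0, family_history = 0, sex = 0, surgery = 0),
    seed = seed, ...))
}

test_that("a scan restricted to one variant equals the direct engine call", {
  set.seed(2)
  sim <- cleanSim(spikeEffectTable(), n = 1500, seed = 3)
  x <- sim$cohort
  P <- phenotypes(x)
  res <- runScan(x, scanConfig("age", model = "linear", k_pcs = 0),
                 variants = "NOD2_like")
  keep <- P$diagnosis %in% c("CD", "UC")
  direct <- fitLinear(inverseNormalTransform(P$age_at_diagnosis[keep]),
                      dosages(x, samplesInRows = TRUE)[keep, "NOD2_like"])
  expect_equal(res$beta, direct$contrasts$beta, tolerance = 1e-12)
  expect_equal(res$p, direct$p, tolerance = 1e-12)
  expect_equal(res$n, direct$n)
})

test_that("significance tiers use strict thresholds", {
  df <- data.frame(p = c(1.01e-35, 2.5e-6, 5e-8, 0.2, NA))
  out <- flagSignificance(df)
  expect_equal(out$tier,
               c("genome_wide", "suggestive", "suggestive", "null", "null"))
  expect_error(scanConfig("location", genome_wide = 1e-5, suggestive = 5e-8),
               "must exceed")
})

test_that("null cohorts are calibrated and spiked variants top the scan", {
  eff <- spikeEffectTable(n_null = 99)
  eff$beta_ileal[1] <- 0                      # null for the scanned trait
  sim <- cleanSim(eff, n = 1500, seed = 9)
  res <- runScan(sim$cohort, scanConfig("age", model = "linear", k_pcs = 2))
  expect_gte(mean(res$p > 0.01, na.rm = TRUE), 0.95)

  sim2 <- cleanSim(spikeEffectTable(spike_beta = log(3)), n = 4000, seed = 10)
  res2 <- runScan(sim2$cohort, scanConfig("location", k_pcs = 0))
  overall <- aggregate(p ~ variant, res2, min)
  expect_equal(overall$variant[which.min(overall$p)], "NOD2_like")
})

test_that("scans on permuted phenotypes yield no genome-wide hits", {
  sim <- cleanSim(spikeEffectTable(n_null = 50), n = 1500, seed = 12)
  x <- sim$cohort
  P <- phenotypes(x)
  set.seed(1)
  P$age_at_diagnosis <- sample(P$age_at_diagnosis)
  phenotypes(x) <- P
  res <- runScan(x, scanConfig("age", model = "linear", k_pcs = 0))
  expect_equal(sum(res$tier == "genome_wide"), 0)
})

test_that("location-mediated behaviour association attenuates under conditioning", {
  sim <- cleanSim(spikeEffectTable(spike_beta = log(2.5)), n = 8000, seed = 14)
  x <- sim$cohort
  unadj <- runScan(x, scanConfig("behaviour", k_pcs = 0),
                   variants = "NOD2_like")
  adj <- runScan(x, scanConfig("behaviour", k_pcs = 0, condition = "location"),
                 variants = "NOD2_like")
  expect_lt(unadj$p, 0.01)   # induced purely via location
  expect_gt(adj$p, 0.01)
})

test_that("model selection picks the generating model family", {
  ## distinct unordered category effects -> multinomial
  set.seed(31)
  n <- 3000
  G <- sapply(1:12, function(j) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("v", 1:12)
  rownames(G) <- paste0("s", 1:n)
  b1 <- runif(12, 0.3, 0.5) * sample(c(-1, 1), 12, TRUE)
  b3 <- runif(12, 0.3, 0.5) * sample(c(-1, 1), 12, TRUE)
  eta1 <- G %*% b1; eta3 <- G %*% b3
  pr <- cbind(exp(eta1), 1, exp(eta3)); pr <- pr / rowSums(pr)
  loc <- apply(pr, 1, function(p) sample(c("L1", "L2", "L3"), 1, prob = p))
  P <- data.frame(sample_id = paste0("s", 1:n), diagnosis = "CD",
                  location = loc, stringsAsFactors = FALSE)
  x <- IBDCohort(t(G), phenotypes = P)
  msel <- selectGeneticModel(x, "location", panel = colnames(G))
  expect_equal(msel$model, "multinomial")

  ## proportional odds -> ordinal
  set.seed(32)
  bo <- runif(12, 0.3, 0.5) * sample(c(-1, 1), 12, TRUE)
  eta <- drop(G %*% bo)
  u <- runif(n)
  p1 <- plogis(0.5 - eta); p12 <- plogis(1.8 - eta)
  beh <- ifelse(u < p1, "B1", ifelse(u < p12, "B2", "B3"))
  P2 <- data.frame(sample_id = paste0("s", 1:n), diagnosis = "CD",
                   behaviour = beh, stringsAsFactors = FALSE)
  x2 <- IBDCohort(t(G), phenotypes = P2)
  msel2 <- selectGeneticModel(x2, "behaviour", panel = colnames(G))
  expect_equal(msel2$model, "ordinal")

  ## two-category phenotype -> binary, always
  P3 <- data.frame(sample_id = paste0("s", 1:n), diagnosis = "UC",
                   extent = sample(c("E2", "E3"), n, TRUE),
                   stringsAsFactors = FALSE)
  x3 <- IBDCohort(t(G), phenotypes = P3)
  msel3 <- selectGeneticModel(x3, "extent", panel = colnames(G)[1:10])
  expect_equal(msel3$model, "binary")
})

test_that("replication combination promotes concordant signals only", {
  disc <- data.frame(variant = c("a", "b", "c"),
                     beta = c(0.5, 0.4, 0.3), se = c(0.08, 0.09, 0.1),
                     p = c(2e-6, 1e-5, 6e-4), stringsAsFactors = FALSE)
  repl <- data.frame(variant = c("a", "b"),
                     beta = c(0.45, -0.4), se = c(0.1, 0.09),
                     p = c(1e-4, 1e-5), stringsAsFactors = FALSE)
  expect_warning(out <- combineReplication(disc, repl), "no replication")
  a <- out[out$variant == "a", ]
  expect_lt(a$p_combined, min(2e-6, 1e-4))     # concordant: combined p smaller
  b <- out[out$variant == "b", ]
  expect_equal(b$beta_combined, 0, tolerance = 1e-10)
  expect_false(b$promoted)
  ## threshold mode requires concordant direction
  out2 <- suppressWarnings(
    combineReplication(disc, repl, mode = "threshold"))
  expect_true(out2$promoted[out2$variant == "a"])
  expect_false(out2$promoted[out2$variant == "b"])
})

test_that("two-stage promotion rate matches a direct two-stage simulation oracle", {
  ## one true signal; discovery n1, replication n2; promotion = combined
  ## p < 5e-8. The oracle replays the same two-stage rule on normal draws.
  set.seed(41)
  beta <- 0.28; maf <- 0.3; n1 <- 3000; n2 <- 2000
  se1 <- sqrt((1 / (2 * maf * (1 - maf))) * (2 / n1) * 2)
  se2 <- sqrt((1 / (2 * maf * (1 - maf))) * (2 / n2) * 2)
  nrep <- 400
  promoted <- logical(nrep)
  for (i in seq_len(nrep)) {
    b1 <- rnorm(1, beta, se1); b2 <- rnorm(1, beta, se2)
    p1 <- 2 * pnorm(-abs(b1 / se1))
    if (p1 >= 1e-5) { promoted[i] <- FALSE; next }
    disc <- data.frame(variant = "v", beta = b1, se = se1, p = p1)
    repl <- data.frame(variant = "v", beta = b2, se = se2,
                       p = 2 * pnorm(-abs(b2 / se2)))
    promoted[i] <- combineReplication(disc, repl)$promoted
  }
  oracle <- mean(replicate(4000, {
    b1 <- rnorm(1, beta, se1); b2 <- rnorm(1, beta, se2)
    if (2 * pnorm(-abs(b1 / se1)) >= 1e-5) return(FALSE)
    w <- c(1 / se1^2, 1 / se2^2)
    bc <- sum(w * c(b1, b2)) / sum(w)
    2 * pnorm(-abs(bc * sqrt(sum(w)))) < 5e-8
  }))
  se_diff <- sqrt(oracle * (1 - oracle) * (1 / nrep + 1 / 4000))
  expect_lt(abs(mean(promoted) - oracle), 4 * se_diff + 0.02)
})
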