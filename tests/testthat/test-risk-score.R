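toyPanel <- function(n = 163) {
  grp <- c("NOD2", "MHC", "MST1", rep("OTHER", n - 3))
  structure(data.frame(
    id = paste0("loc", seq_len(n)),
    w_CD = seq(0.1, 0.5, length.out = n),
    w_UC = seq(-0.1, 0.2, length.out = n),
    is_hla = grp == "MHC", locus_group = grp,
    stringsAsFactors = FALSE
  ), class = c("EffectPanel", "data.frame"))
}

test_that("contrast weights are differences of class log odds ratios", {
  p <- data.frame(id = c("a", "b", "c"), w_CD = c(0.3, 0.7, 0.2),
                  w_UC = c(0.1, -0.1, 0.2), is_hla = FALSE,
                  locus_group = "OTHER")
  w <- buildScoreWeights(p, "CD_vs_UC")
  expect_equal(unname(w), c(0.2, 0.8, 0.0))
  expect_equal(unname(buildScoreWeights(p, "UC")), c(0.1, -0.1, 0.2))
  expect_equal(unname(buildScoreWeights(p, "CD")), c(0.3, 0.7, 0.2))
})

test_that("locus-group exclusion removes exactly the tagged loci", {
  p <- toyPanel(163)
  p2 <- excludeLoci(p, c("NOD2", "MHC", "MST1"))
  expect_equal(nrow(p2), 160)
  expect_identical(excludeLoci(p, character(0)), p)
  expect_error(excludeLoci(p, "HLA"), "unknown locus group")
})

test_that("scores are weighted dosage sums with mean imputation and standardization", {
  d <- rbind(v1 = c(2, 0, 1), v2 = c(1, 1, NA))
  colnames(d) <- paste0("s", 1:3)
  x <- IBDCohort(d)
  s <- scoreSamples(x, c(v1 = 0.5, v2 = -0.2))
  expect_equal(s$score[1], 2 * 0.5 + 1 * -0.2)
  ## missing dosage imputed by the variant mean (1)
  expect_equal(s$score[3], 1 * 0.5 + 1 * -0.2)
  expect_equal(mean(s$score_std), 0, tolerance = 1e-12)
  expect_equal(sd(s$score_std), 1, tolerance = 1e-12)
  ## zero weights and zero-weight loci are inert
  s0 <- scoreSamples(x, c(v1 = 0, v2 = 0))
  expect_true(all(s0$score == 0))
  s1 <- scoreSamples(x, c(v1 = 0.5))
  s2 <- scoreSamples(x, c(v1 = 0.5, v2 = 0))
  expect_equal(s1$score, s2$score)
  expect_error(scoreSamples(x, c(v1 = 1, a = 1, b = 1)), "weighted loci")
})

test_that("scores are affine-equivariant: scaling weights scales raw scores only", {
  x <- makeToyCohort(n = 60, nv = 8)
  w <- setNames(runif(8, -0.3, 0.3), variantInfo(x)$id)
  s1 <- scoreSamples(x, w)
  s3 <- scoreSamples(x, 3 * w)
  expect_equal(s3$score, 3 * s1$score, tolerance = 1e-12)
  expect_equal(s3$score_std, s1$score_std, tolerance = 1e-12)
  lab <- rep(c(0, 1), 30)
  expect_equal(rankAUC(s1$score, lab), rankAUC(s3$score, lab))
})

test_that("rank AUC matches hand-counted concordance", {
  expect_equal(rankAUC(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(rankAUC(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_error(rankAUC(1:4, c(0, 0, 0, 0)), "both classes")
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(2)
    sc <- rnorm(80); lb <- rbinom(80, 1, 0.5)
    expect_equal(rankAUC(sc, lb),
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                                levels = c(0, 1),
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("score association applies the 15-combination Bonferroni threshold", {
  set.seed(4)
  s <- rnorm(400)
  y <- rnorm(400)                       # independent phenotype
  a <- associateScore(s, y, model = "linear")
  expect_equal(a$threshold, 0.05 / 15)
  expect_equal(round(a$threshold, 3), 0.003)
  expect_lt(abs(a$effect), 3 * a$se)    # null effect within 3 SE of zero
})

test_that("case-only panel estimation is antisymmetric under label swap", {
  x <- makeToyCohort(n = 200, nv = 5, seed = 10)
  lab <- phenotypes(x)$diagnosis
  p1 <- suppressWarnings(estimateEffectPanel(x, lab))
  lab2 <- ifelse(lab == "CD", "UC", "CD")
  p2 <- suppressWarnings(estimateEffectPanel(x, lab2))
  expect_equal(p1$w_CD, p2$w_UC, tolerance = 1e-8)
  expect_equal(p1$w_UC, p2$w_CD, tolerance = 1e-8)
  expect_equal(buildScoreWeights(p1, "CD_vs_UC"),
               -buildScoreWeights(p2, "CD_vs_UC"), tolerance = 1e-8)
})

test_that("an external weights TSV loads and bypasses estimation", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(id = c("v1", "v2"), w_CD = c(0.3, -0.2),
                         w_UC = c(0.1, 0.1), is_hla = c(FALSE, TRUE),
                         locus_group = c("OTHER", "MHC")),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- readEffectPanel(f)
  expect_s3_class(p, "EffectPanel")
  expect_equal(unname(buildScoreWeights(p, "CD_vs_UC")), c(0.2, -0.3))
  bad <- data.frame(id = "v1", w_CD = Inf, w_UC = 0)
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readEffectPanel(f), "finite")
})

test_that("outlier flags are one-sided per diagnosis on the raw score", {
  P <- data.frame(sample_id = paste0("s", 1:8),
                  diagnosis = c("CD", "CD", "CD", "UC", "UC", "UC", "CD", "UC"),
                  site = "A", stringsAsFactors = FALSE)
  sc <- data.frame(sample_id = P$sample_id,
                   score = c(-2.5, 2.5, 0, 2.5, -2.5, 0, -2, 2),
                   score_std = 0, contrast = "CD_vs_UC",
                   stringsAsFactors = FALSE)
  arms <- flagOutliers(sc, P, seed = 1)
  out <- arms$sample_id[arms$arm == "outlier"]
  expect_setequal(out, c("s1", "s4", "s7", "s8"))  # thresholds inclusive
  expect_false("s2" %in% out)                      # CD with high score: wrong tail
  expect_false("s3" %in% out)                      # zero score is never an outlier
  ## comparators are site-matched non-outliers, one per outlier when available
  ctrl <- arms[arms$arm == "non_outlier", ]
  expect_true(all(ctrl$site == "A"))
  expect_lte(nrow(ctrl), sum(arms$arm == "outlier"))
})

test_that("enrichment test recovers the published-scale revision imbalance", {
  ## 26/97 revised outliers vs 8/95 revised non-outliers
  arms <- data.frame(
    sample_id = paste0("s", 1:192),
    diagnosis = "CD", site = "A", score = 0,
    arm = rep(c("outlier", "non_outlier"), c(97, 95)),
    stringsAsFactors = FALSE
  )
  P <- data.frame(
    sample_id = arms$sample_id,
    diagnosis_revised = c(rep(c(TRUE, FALSE), c(26, 71)),
                          rep(c(TRUE, FALSE), c(8, 87))),
    location = sample(c("L1", "L2", "L3"), 192, TRUE),
    stringsAsFactors = FALSE
  )
  en <- enrichmentTest(arms, P)
  expect_lt(en$p, 0.01)
  expect_gt(en$effect, 0)
  expect_equal(unname(en$rates["outlier"]), 26 / 97, tolerance = 1e-12)
  ## independent exact-test oracle on the same 2x2 table
  ft <- fisher.test(matrix(c(26, 71, 8, 87), 2, byrow = TRUE))
  expect_lt(ft$p.value, 0.01)
  ## degenerate all-same flags
  P$diagnosis_revised <- FALSE
  expect_equal(enrichmentTest(arms, P)$p, 1)
})

test_that("enrichment p-values are calibrated under label permutation", {
  set.seed(6)
  arms <- data.frame(sample_id = paste0("s", 1:160), diagnosis = "CD",
                     site = "A", score = 0,
                     arm = rep(c("outlier", "non_outlier"), each = 80),
                     stringsAsFactors = FALSE)
  rev0 <- rep(c(TRUE, FALSE), c(24, 136))
  ps <- replicate(400, {
    P <- data.frame(sample_id = arms$sample_id,
                    diagnosis_revised = sample(rev0),
                    stringsAsFactors = FALSE)
    enrichmentTest(arms, P)$p
  })
  expect_lt(abs(mean(ps < 0.1) - 0.1), 0.06)   # roughly uniform under the null
})

test_that("grouping evidence distinguishes shared from subtype-specific effects", {
  expect_equal(compareGroupings(makeToyCohort(60),
                                rep(c("ilealCD", "colonicCD", "UC"), 20),
                                panel = character(0))$delta_bic, 0)
  set.seed(8)
  n <- 3000
  cls <- sample(c("ilealCD", "colonicCD", "UC"), n, TRUE)
  pdist <- c(ilealCD = 0.45, colonicCD = 0.3, UC = 0.3)   # distinct i vs c
  pshared <- c(ilealCD = 0.4, colonicCD = 0.4, UC = 0.25) # CD shared
  G <- rbind(dst = rbinom(n, 2, pdist[cls]),
             shr = rbinom(n, 2, pshared[cls]))
  colnames(G) <- paste0("s", 1:n)
  x <- IBDCohort(G)
  expect_equal(compareGroupings(x, cls, "dst")$favours, 3L)
  expect_equal(compareGroupings(x, cls, "shr")$favours, 2L)
  ## closed-form allele BIC matches a glm-based computation
  cg <- compareGroupings(x, cls, "dst")
  g <- dosages(x, samplesInRows = TRUE)[, "dst"]
  grp3 <- factor(cls); grp2 <- factor(cls == "UC")
  b2 <- BIC(glm(cbind(g, 2 - g) ~ grp2, family = binomial()))
  b3 <- BIC(glm(cbind(g, 2 - g) ~ grp3, family = binomial()))
  expect_equal(cg$delta_bic, b2 - b3, tolerance = 1e-6)
})

test_that("continuum summary orders groups by mean with valid CIs", {
  set.seed(9)
  sc <- c(rnorm(300, 0), rnorm(300, 0.5), rnorm(300, 1))
  grp <- rep(c("UC", "colonicCD", "ilealCD"), each = 300)
  cs <- continuumSummary(sc, grp)
  expect_equal(cs$group, c("UC", "colonicCD", "ilealCD"))
  expect_true(all(cs$ci_low < cs$mean & cs$mean < cs$ci_high))
  one <- continuumSummary(rnorm(50), rep("UC", 50))
  expect_equal(nrow(one), 1)
})

test_that("cross-validated AUC matches the analytic normal-separation oracle", {
  ## two classes with scores N(0,1) and N(delta,1): AUC = Phi(delta/sqrt(2))
  set.seed(10)
  delta <- 0.8
  sc <- c(rnorm(1500), rnorm(1500, delta))
  lab <- rep(0:1, each = 1500)
  auc <- rankAUC(sc, lab)
  expect_lt(abs(auc - pnorm(delta / sqrt(2))), 0.025)
})

test_that("training AUC is optimistically biased relative to held-out AUC", {
  set.seed(20)
  reps <- 8
  gaps <- replicate(reps, {
    seed <- sample.int(1e6, 1)
    sim <- simulateCohort(simulationConfig(n_samples = 1200, seed = seed))
    x <- sim$cohort; P <- phenotypes(x)
    lab <- ifelse(P$diagnosis == "CD", 1L, ifelse(P$diagnosis == "UC", 0L, NA))
    train <- P$country != "UK"
    cv <- crossvalAUC(x, lab, train, n_boot = 20, seed = 1)
    ptr <- suppressWarnings(estimateEffectPanel(
      x[, train], ifelse(P$diagnosis[train] %in% c("CD", "UC"),
                         P$diagnosis[train], NA)))
    str_ <- scoreSamples(x[, train], buildScoreWeights(ptr, "CD_vs_UC"))
    auc_tr <- rankAUC(str_$score, lab[train])
    auc_tr - cv$auc
  })
  expect_gt(mean(gaps), 0)
})
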