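## Genetic risk scores: effect panel estimation, score construction and
## application (continuum placement, cross-validated classification,
## outlier-based misclassification detection, grouping model comparison).

#' Estimate a per-locus effect panel
#'
#' Per-locus univariate logistic log odds ratios with PC adjustment; HLA
#' dosage columns are treated identically to SNPs. With three label classes
#' (CD, UC, control) the CD and UC weights are case-control log-ORs against
#' the control class; in case-only mode (CD/UC labels only) the CD-vs-UC
#' case-case log-OR is split symmetrically (`w_CD = c/2, w_UC = -c/2`) so
#' that the difference weight equals the case-case effect.
#'
#' @param x an [IBDCohort-class] (training samples only).
#' @param labels per-sample labels: `"CD"`, `"UC"` and optionally
#'   `"control"`; NA samples are dropped.
#' @param pcs optional PC data.frame for adjustment (rows matching samples
#'   of `x`).
#' @param loci variant ids to estimate (default: all non-null effect loci,
#'   i.e. every variant).
#' @return data.frame of class `EffectPanel`: `id, w_CD, w_UC, se_CD, se_UC,
#'   is_hla, locus_group`. Monomorphic loci get weight 0 with a warning.
#' @export
estimateEffectPanel <- function(x, labels, pcs = NULL, loci = NULL) {
  vi <- variantInfo(x)
  if (is.null(loci)) loci <- vi$id
  labels <- as.character(labels)
  classes <- setdiff(unique(na.omit(labels)), character(0))
  if (length(classes) < 2) stop("need at least two label classes")
  case_only <- !"control" %in% classes
  D <- dosages(x, samplesInRows = TRUE)
  X <- if (is.null(pcs)) NULL else as.data.frame(pcs)

  w_CD <- w_UC <- se_CD <- se_UC <- rep(NA_real_, length(loci))
  mono <- character(0)
  uniOR <- function(sel1, sel0, g) {
    keep <- (sel1 | sel0) & !is.na(g)
    gg <- g[keep]
    if (length(unique(gg)) < 2) return(NULL)
    Xk <- if (is.null(X)) NULL else X[keep, , drop = FALSE]
    fit <- fitBinaryLogistic(as.integer(sel1[keep]), gg, Xk)
    c(fit$contrasts$beta, fit$contrasts$se)
  }
  isCD <- !is.na(labels) & labels == "CD"
  isUC <- !is.na(labels) & labels == "UC"
  isCtl <- !is.na(labels) & labels == "control"
  for (i in seq_along(loci)) {
    g <- D[, loci[i]]
    if (case_only) {
      r <- uniOR(isCD, isUC, g)
      if (is.null(r)) { mono <- c(mono, loci[i]); w_CD[i] <- w_UC[i] <- 0; next }
      w_CD[i] <- r[1] / 2; w_UC[i] <- -r[1] / 2
      se_CD[i] <- se_UC[i] <- r[2] / 2
    } else {
      r1 <- uniOR(isCD, isCtl, g)
      r2 <- uniOR(isUC, isCtl, g)
      if (is.null(r1) || is.null(r2)) { mono <- c(mono, loci[i]); w_CD[i] <- w_UC[i] <- 0; next }
      w_CD[i] <- r1[1]; se_CD[i] <- r1[2]
      w_UC[i] <- r2[1]; se_UC[i] <- r2[2]
    }
  }
  if (length(mono))
    warning("monomorphic locus given weight 0: ", paste(mono, collapse = ", "))
  idx <- match(loci, vi$id)
  structure(data.frame(id = loci, w_CD = w_CD, w_UC = w_UC,
                       se_CD = se_CD, se_UC = se_UC,
                       is_hla = vi$is_hla[idx],
                       locus_group = vi$locus_group[idx],
                       stringsAsFactors = FALSE),
            class = c("EffectPanel", "data.frame"))
}

#' Load an effect panel from a weights TSV
#'
#' Columns: `id, w_CD, w_UC, is_hla, locus_group`. Bypasses estimation.
#'
#' @param path path to the TSV.
#' @return an `EffectPanel` data.frame.
#' @export
readEffectPanel <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "w_CD", "w_UC")
  if (!all(need %in% colnames(p)))
    stop("weights TSV must contain columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(p$w_CD)) || any(!is.finite(p$w_UC)))
    stop("weights must be finite")
  if (anyDuplicated(p$id)) stop("duplicate locus ids in panel")
  if (is.null(p$is_hla)) p$is_hla <- FALSE
  if (is.null(p$locus_group)) p$locus_group <- "OTHER"
  structure(p, class = c("EffectPanel", "data.frame"))
}

#' Contrast weights from an effect panel
#'
#' `CD_vs_UC` weights are `w_CD - w_UC` (the difference score); `CD` and `UC`
#' return the corresponding log-OR columns; `ileal_vs_colonic` requires the
#' panel to carry `w_ileal`/`w_colonic` columns (case-only location panel).
#'
#' @param panel an `EffectPanel`.
#' @param contrast one of `"CD_vs_UC", "CD", "UC", "ileal_vs_colonic"`.
#' @return named numeric weight vector (natural-log odds units).
#' @export
buildScoreWeights <- function(panel, contrast = c("CD_vs_UC", "CD", "UC",
                                                  "ileal_vs_colonic")) {
  contrast <- match.arg(contrast)
  w <- switch(contrast,
    CD_vs_UC = panel$w_CD - panel$w_UC,
    CD = panel$w_CD,
    UC = panel$w_UC,
    ileal_vs_colonic = {
      if (!all(c("w_ileal", "w_colonic") %in% colnames(panel)))
        stop("panel lacks w_ileal/w_colonic columns")
      panel$w_ileal - panel$w_colonic
    })
  setNames(w, panel$id)
}

#' Remove locus groups from a panel
#'
#' @param panel an `EffectPanel`.
#' @param tags locus-group tags to drop (subset of NOD2, MHC, MST1, OTHER).
#' @return the reduced panel.
#' @export
excludeLoci <- function(panel, tags) {
  bad <- setdiff(tags, .LOCUS_GROUPS)
  if (length(bad)) stop("unknown locus group tag: ", paste(bad, collapse = ", "))
  out <- panel[!panel$locus_group %in% tags, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score samples with locus weights
#'
#' `S_i = sum_j w_j d_ij` in natural-log odds units; missing dosages are
#' replaced by the per-variant mean. A standardized copy (mean 0, SD 1 over
#' the scored cohort) is included.
#'
#' @param x an [IBDCohort-class] (or samples x variants dosage matrix).
#' @param weights named weight vector (names = variant ids); loci absent from
#'   `x` are dropped, but fewer than 50% present is an error.
#' @param contrast tag recorded on the output.
#' @return data.frame of class `ScoreSet`: `sample_id, score, score_std,
#'   contrast`.
#' @export
scoreSamples <- function(x, weights, contrast = "CD_vs_UC") {
  D <- if (is(x, "IBDCohort")) dosages(x, samplesInRows = TRUE) else as.matrix(x)
  present <- names(weights)[names(weights) %in% colnames(D)]
  if (length(present) < 0.5 * length(weights))
    stop(sprintf("only %d of %d weighted loci present in genotypes",
                 length(present), length(weights)))
  Dm <- D[, present, drop = FALSE]
  cm <- colMeans(Dm, na.rm = TRUE)
  for (j in seq_along(present)) {
    nas <- is.na(Dm[, j])
    if (any(nas)) Dm[nas, j] <- cm[j]
  }
  s <- drop(Dm %*% weights[present])
  sdv <- sd(s)
  std <- if (is.na(sdv) || sdv == 0) rep(0, length(s)) else (s - mean(s)) / sdv
  structure(data.frame(sample_id = rownames(D), score = s, score_std = std,
                       contrast = contrast, stringsAsFactors = FALSE),
            class = c("ScoreSet", "data.frame"))
}

#' Score-phenotype association
#'
#' Regresses a phenotype on the standardized score (with covariates) using
#' the phenotype-appropriate engine, so effects are in SD units. Flags
#' significance at the Bonferroni level for `n_tests` phenotype-score
#' combinations (default 15, threshold 0.05/15 = 0.0033).
#'
#' @param scores a `ScoreSet` (or numeric vector).
#' @param y phenotype response (numeric, 0/1, ordered factor, or factor).
#' @param model engine: `linear, binary, ordinal, multinomial`.
#' @param X optional covariates.
#' @param n_tests Bonferroni correction count.
#' @return list: `effect, se, p, n, significant, threshold, fit`.
#' @export
associateScore <- function(scores, y, model = c("linear", "binary", "ordinal",
                                                "multinomial"),
                           X = NULL, n_tests = 15) {
  model <- match.arg(model)
  s <- if (is.data.frame(scores)) scores$score_std else as.numeric(scale(scores))
  res <- switch(model,
    linear = fitLinear(y, s, X),
    binary = fitBinaryLogistic(y, s, X),
    ordinal = fitOrdinalLogistic(y, s, X),
    multinomial = fitMultinomialLogistic(y, s, X)
  )
  thr <- 0.05 / n_tests
  list(effect = res$contrasts$beta[1], se = res$contrasts$se[1], p = res$p,
       n = res$n, significant = res$p < thr, threshold = thr, result = res)
}

## ----------------------------------------------------------------------------

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance of
#' scores between classes.
#'
#' @param score numeric scores.
#' @param label 0/1 class labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
rankAUC <- function(score, label) {
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]; label <- as.integer(label[ok])
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated classification AUC
#'
#' Estimates score weights on training samples only (e.g. non-UK sites),
#' scores the held-out samples, and reports the rank-statistic AUC with a
#' stratified bootstrap CI.
#'
#' @param x an [IBDCohort-class].
#' @param label per-sample 0/1 (or logical) class label; NA = not classified.
#' @param train logical vector: TRUE = training sample. Test samples are the
#'   non-training samples with non-missing labels.
#' @param train_labels labels used to fit the panel on the training split
#'   (default: CD/UC diagnosis, case-only mode).
#' @param contrast score contrast (see [buildScoreWeights()]).
#' @param pcs optional PCs for panel estimation.
#' @param n_boot bootstrap draws for the 95% CI (stratified by class).
#' @param seed RNG seed for the bootstrap.
#' @return list: `auc, ci, n_test, n_train, scores`.
#' @export
crossvalAUC <- function(x, label, train, train_labels = NULL,
                        contrast = "CD_vs_UC", pcs = NULL, n_boot = 2000,
                        seed = 1L) {
  label <- as.integer(label)
  test <- !train & !is.na(label)
  if (length(unique(label[test])) < 2)
    stop("held-out set must contain both classes")
  xtr <- x[, train]
  if (is.null(train_labels)) train_labels <- phenotypes(xtr)$diagnosis
  train_labels[!train_labels %in% c("CD", "UC", "control")] <- NA
  panel <- suppressWarnings(
    estimateEffectPanel(xtr, train_labels,
                        pcs = if (is.null(pcs)) NULL else pcs[train, , drop = FALSE])
  )
  w <- buildScoreWeights(panel, contrast)
  sc <- scoreSamples(x[, test], w, contrast = contrast)
  auc <- rankAUC(sc$score, label[test])
  set.seed(seed)
  i1 <- which(label[test] == 1); i0 <- which(label[test] == 0)
  boots <- replicate(n_boot, {
    bi <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    rankAUC(sc$score[bi], label[test][bi])
  })
  list(auc = auc, ci = unname(quantile(boots, c(0.025, 0.975))),
       n_test = sum(test), n_train = sum(train), scores = sc)
}

## ----------------------------------------------------------------------------

#' Flag risk-score outliers (candidate misdiagnoses)
#'
#' A Crohn's disease case is an outlier when its natural-log CD-vs-UC score
#' is at or below `lo`; an ulcerative colitis case when at or above `hi`
#' (one-sided per diagnosis: the tail of the opposite phenotype). A
#' site-matched random non-outlier comparator is drawn per outlier.
#'
#' A score built as a weighted dosage sum carries an arbitrary additive
#' constant (it is a log odds only up to an intercept), so by default the
#' scores are centered at the scored-cohort mean before thresholding; pass
#' `center = FALSE` to threshold the raw sums directly.
#'
#' @param scores a `ScoreSet` with raw scores (natural-log odds units).
#' @param P phenotype data.frame (diagnosis, site).
#' @param lo,hi outlier thresholds on the (centered) raw score
#'   (defaults -2 / +2).
#' @param center center scores at their mean before thresholding (default
#'   TRUE).
#' @param seed RNG seed for comparator sampling.
#' @return data.frame: sample_id, diagnosis, site, score, arm
#'   (`"outlier"`/`"non_outlier"`).
#' @export
flagOutliers <- function(scores, P, lo = -2, hi = 2, center = TRUE, seed = 1L) {
  m <- merge(scores, P[, intersect(c("sample_id", "diagnosis", "site"),
                                   colnames(P))], by = "sample_id")
  sc <- if (center) m$score - mean(m$score) else m$score
  out <- (!is.na(m$diagnosis) & m$diagnosis == "CD" & sc <= lo) |
         (!is.na(m$diagnosis) & m$diagnosis == "UC" & sc >= hi)
  outliers <- m[out, , drop = FALSE]
  pool <- m[!out & !is.na(m$diagnosis) & m$diagnosis %in% c("CD", "UC"), ,
            drop = FALSE]
  set.seed(seed)
  picks <- character(0)
  if ("site" %in% colnames(m)) {
    for (s in unique(outliers$site)) {
      need <- sum(outliers$site == s)
      cand <- setdiff(pool$sample_id[pool$site == s], picks)
      picks <- c(picks, sample(cand, min(need, length(cand))))
    }
  } else {
    picks <- sample(pool$sample_id, min(nrow(outliers), nrow(pool)))
  }
  ctrl <- pool[pool$sample_id %in% picks, , drop = FALSE]
  res <- rbind(
    cbind(outliers, arm = "outlier", stringsAsFactors = FALSE),
    cbind(ctrl, arm = "non_outlier", stringsAsFactors = FALSE)
  )
  rownames(res) <- NULL
  res
}

#' Outlier revision-rate enrichment test
#'
#' Tests whether masked re-phenotyping raised doubts (diagnosis revised) more
#' often among score outliers than among site-matched non-outliers: logistic
#' regression of the revision flag on outlier status with a disease-location
#' covariate, falling back to Fisher's exact test when any 2x2 cell is
#' below 5.
#'
#' @param arms output of [flagOutliers()].
#' @param P phenotype data.frame carrying `diagnosis_revised` (and
#'   `location` for the covariate).
#' @return list: `p, effect` (log-OR of revision for outliers), `rates`
#'   (per-arm revision rates), `method`, `table`.
#' @export
enrichmentTest <- function(arms, P) {
  m <- merge(arms, P[, intersect(c("sample_id", "diagnosis_revised", "location"),
                                 colnames(P))], by = "sample_id")
  m <- m[!is.na(m$diagnosis_revised), , drop = FALSE]
  if (!nrow(m) || length(unique(m$arm)) < 2) stop("both arms must be non-empty")
  tab <- table(arm = m$arm, revised = factor(m$diagnosis_revised,
                                             levels = c(FALSE, TRUE)))
  rates <- tab[, "TRUE"] / rowSums(tab)
  if (length(unique(m$diagnosis_revised)) < 2)
    return(list(p = 1, effect = 0, rates = rates, method = "degenerate",
                table = tab))
  if (any(tab < 5)) {
    ft <- fisher.test(tab)
    return(list(p = ft$p.value, effect = log(ft$estimate), rates = rates,
                method = "fisher", table = tab))
  }
  df <- data.frame(rev = as.integer(m$diagnosis_revised),
                   outlier = as.integer(m$arm == "outlier"))
  form <- "rev ~ outlier"
  if ("location" %in% colnames(m) && length(unique(na.omit(m$location))) > 1) {
    df$location <- ifelse(is.na(m$location), "missing", m$location)
    form <- "rev ~ outlier + location"
  }
  fit <- suppressWarnings(glm(as.formula(form), family = binomial(), data = df))
  sm <- summary(fit)$coefficients
  list(p = sm["outlier", 4], effect = sm["outlier", 1], rates = rates,
       method = "logistic", table = tab)
}

## ----------------------------------------------------------------------------

## Closed-form binomial log-likelihood of allele counts under per-group
## allele frequencies (binomial constants cancel in model comparisons).
.alleleLL <- function(g, grp) {
  ll <- 0
  for (lev in unique(grp)) {
    gg <- g[grp == lev]
    x <- sum(gg); m <- 2 * length(gg)
    p <- x / m
    if (p > 0 && p < 1) ll <- ll + x * log(p) + (m - x) * log(1 - p)
  }
  ll
}

#' Two-group vs three-group model comparison
#'
#' For each panel locus, compares the BIC of an allele-frequency model with
#' two groups (Crohn's disease grouped: {CD, UC}) against three groups
#' ({ileal CD, colonic CD, UC}). `delta_bic = BIC2 - BIC3` summed over loci;
#' positive values favour the three-group model.
#'
#' @param x an [IBDCohort-class].
#' @param labels per-sample labels in `{ilealCD, colonicCD, UC}` (others NA).
#' @param panel variant ids to aggregate over.
#' @return list of class `GroupingEvidence`: `delta_bic`, `per_locus`
#'   data.frame, `favours` (2 or 3).
#' @export
compareGroupings <- function(x, labels, panel) {
  labels <- as.character(labels)
  keep <- !is.na(labels) & labels %in% c("ilealCD", "colonicCD", "UC")
  if (length(unique(labels[keep])) < 3)
    stop("all three label classes (ilealCD, colonicCD, UC) are required")
  D <- dosages(x, samplesInRows = TRUE)
  grp3 <- labels[keep]
  grp2 <- ifelse(grp3 == "UC", "UC", "CD")
  per <- vapply(panel, function(v) {
    g <- D[keep, v]
    ok <- !is.na(g)
    n <- sum(ok)
    ll2 <- .alleleLL(g[ok], grp2[ok])
    ll3 <- .alleleLL(g[ok], grp3[ok])
    bic2 <- -2 * ll2 + 2 * log(n)
    bic3 <- -2 * ll3 + 3 * log(n)
    bic2 - bic3
  }, 0)
  total <- sum(per)
  structure(list(delta_bic = total,
                 per_locus = data.frame(id = panel, delta_bic = unname(per),
                                        stringsAsFactors = FALSE),
                 favours = if (total > 0) 3L else 2L),
            class = "GroupingEvidence")
}

#' @export
print.GroupingEvidence <- function(x, ...) {
  cat(sprintf("grouping evidence: sum dBIC(2-group minus 3-group) = %.2f -> favours %d groups\n",
              x$delta_bic, x$favours))
  invisible(x)
}

#' Continuum summary of risk scores by group
#'
#' Group means of the (raw) score with 95% CIs, ordered by mean: the data
#' product behind the violin/continuum display of subphenotype placement.
#'
#' @param scores a `ScoreSet` or numeric vector.
#' @param groups per-sample group labels (e.g. ilealCD / colonicCD / UC /
#'   L3 / IBDU); NA dropped.
#' @return data.frame: group, n, mean, se, ci_low, ci_high (ordered by mean).
#' @export
continuumSummary <- function(scores, groups) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  ok <- !is.na(s) & !is.na(groups)
  s <- s[ok]; groups <- as.character(groups)[ok]
  if (!length(s)) stop("no scored samples with group labels")
  rows <- lapply(unique(groups), function(gr) {
    v <- s[groups == gr]
    se <- sd(v) / sqrt(length(v))
    data.frame(group = gr, n = length(v), mean = mean(v), se = se,
               ci_low = mean(v) - 1.96 * se, ci_high = mean(v) + 1.96 * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$mean), , drop = FALSE]
}
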