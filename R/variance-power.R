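## McKelvey-Zavoina pseudo-R2 variance decomposition and analytic power for
## per-allele association tests.

#' McKelvey-Zavoina pseudo-R2
#'
#' Latent-scale variance explained for logit models:
#' `R2 = Var(eta_hat) / (Var(eta_hat) + pi^2/3)`. Accepts a fitted binary
#' logistic `glm`, a `MASS::polr` fit (the same logistic latent variance
#' applies), or the fitted latent predictor directly.
#'
#' @param fit fitted logit model or numeric vector of fitted latent values.
#' @return R-squared fraction in \[0, 1\].
#' @export
mckelveyZavoinaR2 <- function(fit) {
  eta <- if (is.numeric(fit)) fit
  else if (inherits(fit, "glm")) {
    if (!isTRUE(fit$converged) && !is.null(fit$converged))
      stop("model did not converge")
    predict(fit, type = "link")
  } else if (inherits(fit, "polr")) fit$lp
  else stop("unfitted or unsupported model")
  v <- var(eta)
  if (is.na(v)) stop("cannot compute latent variance")
  v / (v + pi^2 / 3)
}

#' Variance decomposition for a binary subphenotype
#'
#' Per-predictor McKelvey-Zavoina pseudo-R2 from single-predictor logistic
#' models plus block rows from joint models (genetics only, genetics +
#' smoking, all predictors). Cohort filters follow the adult-onset design:
#' only patients born within `birth_years` are included, and recruitment
#' centres with more than `max_smoking_missing` missing smoking status are
#' removed. A `NOD2` predictor is the summed risk-allele count across the
#' variants tagged NOD2.
#'
#' @param x an [IBDCohort-class].
#' @param outcome 0/1 response vector over samples of `x` (NA = excluded),
#'   e.g. ileal vs colonic location or extensive vs non-extensive extent.
#' @param genetic_ids variant ids entered individually.
#' @param score optional `ScoreSet` entered as "risk_score".
#' @param birth_years inclusive year-of-birth window (default 1955-1985).
#' @param max_smoking_missing centre-level missingness cutoff (default 0.6).
#' @return data.frame of class `VarianceTable`: predictor, beta, se, p,
#'   r2_pct, block.
#' @export
varianceDecomposition <- function(x, outcome, genetic_ids = character(),
                                  score = NULL,
                                  birth_years = c(1955, 1985),
                                  max_smoking_missing = 0.6) {
  P <- phenotypes(x)
  D <- dosages(x, samplesInRows = TRUE)
  keep <- !is.na(outcome)
  if (!is.null(birth_years) && "year_of_birth" %in% colnames(P))
    keep <- keep & !is.na(P$year_of_birth) &
      P$year_of_birth >= birth_years[1] & P$year_of_birth <= birth_years[2]
  if ("smoking" %in% colnames(P) && "site" %in% colnames(P)) {
    miss_by_site <- tapply(is.na(P$smoking), P$site, mean)
    bad_sites <- names(miss_by_site)[miss_by_site > max_smoking_missing]
    keep <- keep & !P$site %in% bad_sites
  }
  if (!any(keep)) stop("no samples remain after filters")

  preds <- list()
  if ("smoking" %in% colnames(P)) {
    preds$ever_smoker <- as.numeric(P$smoking %in% c("smoker", "ex"))
    preds$ever_smoker[is.na(P$smoking)] <- NA
    preds$smoker_at_diagnosis <- as.numeric(P$smoking == "smoker")
    preds$smoker_at_diagnosis[is.na(P$smoking)] <- NA
  }
  if ("age_at_diagnosis" %in% colnames(P)) preds$age_at_diagnosis <- P$age_at_diagnosis
  if ("year_of_birth" %in% colnames(P)) preds$year_of_birth <- P$year_of_birth
  vi <- variantInfo(x)
  nod2 <- vi$id[vi$locus_group == "NOD2"]
  for (v in genetic_ids) preds[[v]] <- D[, v]
  if (length(nod2)) preds$NOD2 <- rowSums(D[, nod2, drop = FALSE])
  if (!is.null(score))
    preds$risk_score <- score$score_std[match(P$sample_id, score$sample_id)]

  gen_names <- c(genetic_ids, if (length(nod2)) "NOD2",
                 if (!is.null(score)) "risk_score")
  smoking_names <- intersect(c("ever_smoker", "smoker_at_diagnosis"), names(preds))

  y <- outcome[keep]
  pd <- as.data.frame(preds)[keep, , drop = FALSE]
  ## one analysis set: complete cases across every predictor, so that
  ## single-predictor R2 is nested within (and bounded by) the block R2
  cc <- complete.cases(pd) & !is.na(y)
  y <- y[cc]; pd <- pd[cc, , drop = FALSE]
  if (!length(y)) stop("no samples remain after filters")

  single <- lapply(names(pd), function(nm) {
    df <- data.frame(y = y, p1 = pd[[nm]])
    fit <- glm(y ~ p1, family = binomial(), data = df)
    sm <- summary(fit)$coefficients
    data.frame(predictor = nm, beta = sm["p1", 1], se = sm["p1", 2],
               p = sm["p1", 4], r2_pct = 100 * mckelveyZavoinaR2(fit),
               block = "single", stringsAsFactors = FALSE)
  })
  blockR2 <- function(nms, label) {
    df <- cbind(data.frame(y = y), pd[, nms, drop = FALSE])
    fit <- suppressWarnings(glm(y ~ ., family = binomial(), data = df))
    data.frame(predictor = label, beta = NA_real_, se = NA_real_, p = NA_real_,
               r2_pct = 100 * mckelveyZavoinaR2(fit), block = label,
               stringsAsFactors = FALSE)
  }
  blocks <- list()
  if (length(gen_names))
    blocks$gen <- blockR2(gen_names, "genetics_only")
  if (length(gen_names) && length(smoking_names))
    blocks$gensmoke <- blockR2(c(gen_names, smoking_names), "genetics_and_smoking")
  blocks$all <- blockR2(names(pd), "all_parameters")
  out <- do.call(rbind, c(single, unname(blocks)))
  rownames(out) <- NULL
  structure(out, class = c("VarianceTable", "data.frame"))
}

#' Analytic power for a per-allele association test
#'
#' Two-sided normal approximation for the allele-count (trend) test of a
#' log odds ratio between two groups:
#' `SE^2 = (2p(1-p))^-1 (1/n1 + 1/n2)`,
#' `power = Phi(|ln OR|/SE - z) + Phi(-|ln OR|/SE - z)` with
#' `z = qnorm(1 - alpha/2)`.
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @param or per-allele odds ratio (> 0).
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level (default genome-wide 5e-8).
#' @return power fraction.
#' @export
analyticPower <- function(maf, or, n1, n2, alpha = 5e-8) {
  stopifnot(maf > 0, maf <= 0.5, or > 0, alpha > 0, alpha < 1)
  se <- sqrt((1 / (2 * maf * (1 - maf))) * (1 / n1 + 1 / n2))
  z <- qnorm(1 - alpha / 2)
  d <- abs(log(or)) / se
  pnorm(d - z) + pnorm(-d - z)
}
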