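## Per-variant scans across phenotypes, genetic-model selection, significance
## tiers, and discovery + replication combination.

.GENOME_WIDE <- 5e-8
.SUGGESTIVE <- 1e-5

.PHENO_MODELS <- c(location = "multinomial", behaviour = "ordinal",
                   extent = "binary", age = "linear", surgery = "weibull",
                   colectomy = "weibull", upper_gi = "binary",
                   perianal = "binary")

## Build the response and default sample subset for a named phenotype target.
.scanResponse <- function(P, phenotype) {
  switch(phenotype,
    location = {
      keep <- !is.na(P$diagnosis) & P$diagnosis == "CD"
      y <- factor(ifelse(P$location %in% c("L1", "L2", "L3"), P$location, NA),
                  levels = c("L1", "L2", "L3"))
      list(y = y, keep = keep)
    },
    behaviour = {
      keep <- !is.na(P$diagnosis) & P$diagnosis == "CD"
      list(y = factor(P$behaviour, levels = .BEHAVIOUR, ordered = TRUE), keep = keep)
    },
    extent = {
      keep <- !is.na(P$diagnosis) & P$diagnosis == "UC"
      y <- ifelse(P$extent == "E3", 1L,
                  ifelse(P$extent %in% c("E1", "E2"), 0L, NA))
      list(y = y, keep = keep)
    },
    age = {
      keep <- !is.na(P$diagnosis) & P$diagnosis %in% c("CD", "UC")
      list(y = P$age_at_diagnosis, keep = keep)
    },
    surgery = {
      keep <- !is.na(P$diagnosis) & P$diagnosis == "CD"
      list(time = P$surgery_time_years, event = as.integer(P$surgery_event),
           keep = keep)
    },
    colectomy = {
      keep <- !is.na(P$diagnosis) & P$diagnosis == "UC"
      list(time = P$surgery_time_years, event = as.integer(P$surgery_event),
           keep = keep)
    },
    upper_gi = {
      keep <- !is.na(P$diagnosis) & P$diagnosis == "CD"
      list(y = as.integer(P$upper_gi_L4), keep = keep)
    },
    perianal = {
      keep <- !is.na(P$diagnosis) & P$diagnosis == "CD"
      list(y = as.integer(P$perianal), keep = keep)
    },
    stop("unknown phenotype target: ", phenotype)
  )
}

## Conditioning covariates: location as two dummies (L1, L3 vs L2), behaviour
## ordinal-coded, age as inverse-normal score, extent as E3 dummy.
.conditionCovariates <- function(P, condition) {
  out <- list()
  for (cv in condition) {
    if (cv == "location") {
      out$loc_L1 <- as.numeric(P$location == "L1")
      out$loc_L3 <- as.numeric(P$location == "L3")
      out$loc_L1[!P$location %in% c("L1", "L2", "L3")] <- NA
      out$loc_L3[!P$location %in% c("L1", "L2", "L3")] <- NA
    } else if (cv == "behaviour") {
      out$behaviour_ord <- as.numeric(factor(P$behaviour, levels = .BEHAVIOUR))
    } else if (cv == "age") {
      out$age_int <- inverseNormalTransform(P$age_at_diagnosis)
    } else if (cv == "extent") {
      out$extent_E3 <- ifelse(P$extent == "E3", 1,
                              ifelse(P$extent %in% c("E1", "E2"), 0, NA))
    } else stop("unknown conditioning phenotype: ", cv)
  }
  if (length(out)) as.data.frame(out) else NULL
}

#' Scan configuration
#'
#' @param phenotype one of `location, behaviour, extent, age, surgery,
#'   colectomy, upper_gi, perianal`.
#' @param model `"auto"` (phenotype-appropriate engine) or one of
#'   `linear, binary, ordinal, multinomial, weibull`.
#' @param k_pcs number of genotype principal components to adjust for.
#' @param condition character vector of phenotypes entered as covariates
#'   (subset of `location, behaviour, age, extent`).
#' @param min_maf,max_missing per-variant filters.
#' @param genome_wide,suggestive significance thresholds.
#' @return list of class `ScanConfig`.
#' @export
scanConfig <- function(phenotype, model = "auto", k_pcs = 5,
                       condition = character(),
                       min_maf = 0.01, max_missing = 0.05,
                       genome_wide = .GENOME_WIDE, suggestive = .SUGGESTIVE) {
  if (suggestive <= genome_wide)
    stop("suggestive threshold must exceed genome_wide threshold")
  structure(list(phenotype = phenotype, model = model, k_pcs = k_pcs,
                 condition = condition, min_maf = min_maf,
                 max_missing = max_missing, genome_wide = genome_wide,
                 suggestive = suggestive),
            class = "ScanConfig")
}

#' Per-variant association scan
#'
#' Runs the phenotype-appropriate regression engine for every variant passing
#' the MAF/missingness filters, adjusted for the top genotype principal
#' components and any conditioning phenotypes, and tiers the p-values.
#'
#' @param x an [IBDCohort-class].
#' @param cfg a [scanConfig()].
#' @param variants optional character vector restricting the scan.
#' @param pcs optional precomputed PC data.frame (rows = all samples of `x`);
#'   computed with [computePCs()] when NULL and `k_pcs > 0`.
#' @return data.frame (one row per variant-contrast) in the [assocTable()]
#'   layout plus a `tier` column.
#' @export
runScan <- function(x, cfg, variants = NULL, pcs = NULL) {
  stopifnot(inherits(cfg, "ScanConfig"))
  P <- phenotypes(x)
  vi <- variantInfo(x)
  pass <- !is.na(vi$maf) & vi$maf >= cfg$min_maf & vi$missingness <= cfg$max_missing
  if (!is.null(variants)) pass <- pass & vi$id %in% variants
  if (!any(pass)) stop("zero variants pass filters")
  ids <- vi$id[pass]

  if (is.null(pcs) && cfg$k_pcs > 0) pcs <- computePCs(x, k = cfg$k_pcs)
  Xc <- .conditionCovariates(P, cfg$condition)
  X <- if (cfg$k_pcs > 0) pcs[, seq_len(cfg$k_pcs), drop = FALSE] else NULL
  if (!is.null(Xc)) X <- if (is.null(X)) Xc else cbind(X, Xc)

  resp <- .scanResponse(P, cfg$phenotype)
  model <- if (cfg$model == "auto") unname(.PHENO_MODELS[cfg$phenotype]) else cfg$model
  keep <- resp$keep
  D <- dosages(x, samplesInRows = TRUE)
  Xk <- if (is.null(X)) NULL else X[keep, , drop = FALSE]

  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- D[keep, ids[i]]
    res <- tryCatch(
      switch(model,
        linear = fitLinear(inverseNormalTransform(resp$y[keep]), g, Xk),
        binary = fitBinaryLogistic(resp$y[keep], g, Xk),
        ordinal = fitOrdinalLogistic(resp$y[keep], g, Xk),
        multinomial = fitMultinomialLogistic(resp$y[keep], g, Xk, reference = "L2"),
        weibull = fitWeibullAFT(resp$time[keep], resp$event[keep], g, Xk),
        stop("unknown model: ", model)
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(variant = ids[i], model = model, contrast = "g",
                              beta = NA_real_, se = NA_real_, or_hr = NA_real_,
                              ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                              n = 0L, converged = FALSE, stringsAsFactors = FALSE)
    } else {
      res$variant <- ids[i]
      rows[[i]] <- assocTable(res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  flagSignificance(out, cfg)
}

#' Tier scan results by significance
#'
#' Labels each result `genome_wide` (p < genome-wide threshold, strict),
#' `suggestive`, or `null`.
#'
#' @param results data.frame with a `p` column.
#' @param cfg a [scanConfig()] (or NULL for the default 5e-8 / 1e-5 tiers).
#' @return `results` with a `tier` column.
#' @export
flagSignificance <- function(results, cfg = NULL) {
  gw <- if (is.null(cfg)) .GENOME_WIDE else cfg$genome_wide
  sg <- if (is.null(cfg)) .SUGGESTIVE else cfg$suggestive
  results$tier <- ifelse(is.na(results$p), "null",
                         ifelse(results$p < gw, "genome_wide",
                                ifelse(results$p < sg, "suggestive", "null")))
  results
}

## ----------------------------------------------------------------------------

## Log-likelihood of a 3-category outcome under a "binary" genetic model:
## genotype moves only the top-vs-rest split; the split within the rest is
## genotype-independent. Gives a likelihood on the same data as the ordinal
## and multinomial candidates, so BICs are comparable.
.binaryCandidateLL <- function(y, g, X, top) {
  ytop <- as.integer(y == top)
  fit <- suppressWarnings(glm(ytop ~ ., data = cbind(data.frame(ytop = ytop, g = g),
                                                     X)[, , drop = FALSE],
                              family = binomial()))
  ll <- as.numeric(logLik(fit))
  rest <- table(y[y != top])
  rest <- rest[rest > 0]
  ll_rest <- sum(rest * log(rest / sum(rest)))
  npar <- length(coef(fit)) + (length(rest) - 1)
  list(ll = ll + ll_rest, npar = npar)
}

#' Genetic model selection for a multicategory phenotype
#'
#' Fits binary (top category vs rest, remainder split genotype-independent),
#' proportional-odds ordinal, and multinomial models for every variant in a
#' designated associated-variant panel, sums BIC over the panel, and returns
#' the minimum-total-BIC model. Ties within 2 BIC units return the simplest
#' model (binary < ordinal < multinomial) with a tie flag.
#'
#' @param x an [IBDCohort-class].
#' @param phenotype `"location"`, `"behaviour"` or `"extent"`.
#' @param panel character vector of variant ids (>= 10 advised).
#' @param k_pcs PCs to adjust for.
#' @param pcs optional precomputed PCs.
#' @return list `model` (chosen), `bic` (named totals), `margin`
#'   (runner-up BIC minus chosen), `tie` (logical).
#' @export
selectGeneticModel <- function(x, phenotype, panel, k_pcs = 0, pcs = NULL) {
  P <- phenotypes(x)
  resp <- .scanResponse(P, phenotype)
  keep <- resp$keep
  y <- factor(resp$y[keep])
  if (is.null(pcs) && k_pcs > 0) pcs <- computePCs(x, k = k_pcs)
  X <- if (k_pcs > 0) pcs[keep, seq_len(k_pcs), drop = FALSE] else
    data.frame(row.names = seq_len(sum(keep)))
  D <- dosages(x, samplesInRows = TRUE)
  lv <- levels(droplevels(factor(y[!is.na(y)])))
  two_cat <- length(lv) <= 2
  top <- lv[length(lv)]

  bic <- c(binary = 0, ordinal = 0, multinomial = 0)
  for (v in panel) {
    g <- D[keep, v]
    ok <- !is.na(y) & !is.na(g) & complete.cases(X)
    yy <- droplevels(factor(y[ok])); gg <- g[ok]
    XX <- X[ok, , drop = FALSE]
    nobs <- length(yy)
    if (two_cat) {
      fb <- fitBinaryLogistic(as.integer(yy) - 1L, gg,
                              if (ncol(XX)) XX else NULL)
      llb <- as.numeric(logLik(fb$fit)); npb <- length(coef(fb$fit))
      bic["binary"] <- bic["binary"] + (-2 * llb + npb * log(nobs))
      bic["ordinal"] <- bic["ordinal"] + (-2 * llb + npb * log(nobs))
      bic["multinomial"] <- bic["multinomial"] + (-2 * llb + npb * log(nobs))
      next
    }
    bcand <- .binaryCandidateLL(yy, gg, XX, top)
    bic["binary"] <- bic["binary"] + (-2 * bcand$ll + bcand$npar * log(nobs))
    fo <- fitOrdinalLogistic(factor(yy, ordered = TRUE), gg,
                             if (ncol(XX)) XX else NULL)
    llo <- as.numeric(logLik(fo$fit))
    npo <- length(coef(fo$fit)) + length(fo$fit$zeta)
    bic["ordinal"] <- bic["ordinal"] + (-2 * llo + npo * log(nobs))
    fm <- fitMultinomialLogistic(yy, gg, if (ncol(XX)) XX else NULL,
                                 reference = lv[1])
    llm <- -fm$fit$deviance / 2
    npm <- length(coef(fm$fit))
    bic["multinomial"] <- bic["multinomial"] + (-2 * llm + npm * log(nobs))
  }
  ord <- c("binary", "ordinal", "multinomial")  # simplicity order
  best <- ord[which.min(bic[ord])]
  tie_set <- ord[bic[ord] <= min(bic) + 2]
  tie <- length(tie_set) > 1
  if (tie) best <- tie_set[1]
  margin <- sort(bic)[2] - min(bic)
  list(model = best, bic = bic, margin = unname(margin), tie = tie)
}

#' Combine discovery with replication
#'
#' Fixed-effect meta-analysis of discovery and replication effects per
#' variant; a variant is promoted to genome-wide significance iff the
#' combined p-value is below the threshold. A p-threshold replication mode
#' (replication p below `replication_alpha` with concordant direction) is
#' available behind `mode`.
#'
#' @param discovery,replication data.frames in the [assocTable()] layout
#'   (single-contrast rows; the suggestive set is usually passed as
#'   discovery).
#' @param genome_wide promotion threshold for the combined p.
#' @param mode `"meta"` (default) or `"threshold"`.
#' @param replication_alpha used by the threshold mode.
#' @return data.frame: variant, beta_disc, beta_repl, beta_combined,
#'   se_combined, p_combined, promoted.
#' @export
combineReplication <- function(discovery, replication,
                               genome_wide = .GENOME_WIDE,
                               mode = c("meta", "threshold"),
                               replication_alpha = 0.05) {
  mode <- match.arg(mode)
  shared <- intersect(discovery$variant, replication$variant)
  missing <- setdiff(discovery$variant, replication$variant)
  if (length(missing))
    warning("no replication results for: ", paste(missing, collapse = ", "),
            " (skipped)")
  if (!length(shared)) return(NULL)
  rows <- lapply(shared, function(v) {
    d <- discovery[discovery$variant == v, ][1, ]
    r <- replication[replication$variant == v, ][1, ]
    m <- metaFixed(data.frame(beta = c(d$beta, r$beta), se = c(d$se, r$se)))
    promoted <- if (mode == "meta") m$p < genome_wide else
      (r$p < replication_alpha && sign(d$beta) == sign(r$beta))
    data.frame(variant = v, beta_disc = d$beta, beta_repl = r$beta,
               beta_combined = m$beta, se_combined = m$se, p_combined = m$p,
               promoted = promoted, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
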