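## Maximum-likelihood regression engines used by every scan: linear, binary
## logistic, proportional-odds ordinal, multinomial, Weibull survival, plus
## the inverse-normal transform and fixed-effect meta-analysis.

.newAssocResult <- function(model, contrasts, p, n, converged,
                            variant = NA_character_, intercepts = NULL,
                            cutpoints = NULL, shape = NA_real_, fit = NULL) {
  structure(list(
    variant = variant, model = model, contrasts = contrasts,
    p = p, n = n, converged = converged,
    intercepts = intercepts, cutpoints = cutpoints, shape = shape,
    fit = fit
  ), class = "assocResult")
}

#' @export
print.assocResult <- function(x, ...) {
  cat(sprintf("assocResult [%s] variant=%s n=%d converged=%s p=%.3g\n",
              x$model, x$variant, x$n, x$converged, x$p))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Flatten association results to a results table
#'
#' One row per contrast with columns
#' `variant, model, contrast, beta, se, or_hr, ci_low, ci_high, p, n, converged`.
#' Odds/hazard ratios and their 95% CIs are `exp(beta +/- 1.96 se)` (for the
#' linear engine the effect is reported on the outcome scale and `or_hr` is NA).
#'
#' @param results an `assocResult` or a list of them.
#' @return data.frame.
#' @export
assocTable <- function(results) {
  if (inherits(results, "assocResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    ctr <- r$contrasts
    ratio <- r$model != "linear"
    data.frame(
      variant = r$variant, model = r$model, contrast = ctr$contrast,
      beta = ctr$beta, se = ctr$se,
      or_hr = if (ratio) exp(ctr$beta) else NA_real_,
      ci_low = if (ratio) exp(ctr$beta - 1.96 * ctr$se) else ctr$beta - 1.96 * ctr$se,
      ci_high = if (ratio) exp(ctr$beta + 1.96 * ctr$se) else ctr$beta + 1.96 * ctr$se,
      p = r$p, n = r$n, converged = r$converged,
      stringsAsFactors = FALSE
    )
  }))
}

## ----------------------------------------------------------------------------

#' Rank-based inverse normal transform
#'
#' Maps `y` to `qnorm((rank - 0.5) / n)` with average ranks for ties; missing
#' values are passed through. Invariant to monotone rescaling of the input.
#'
#' @param y numeric vector with at least two distinct non-missing values.
#' @return numeric vector, mean approximately 0 and variance approximately 1.
#' @export
#' @examples
#' inverseNormalTransform(c(3, 1, 2))
inverseNormalTransform <- function(y) {
  ok <- !is.na(y)
  yy <- y[ok]
  if (length(unique(yy)) < 2) stop("need at least two distinct non-missing values")
  r <- rank(yy, ties.method = "average")
  out <- rep(NA_real_, length(y))
  out[ok] <- qnorm((r - 0.5) / length(yy))
  out
}

.designFrame <- function(g, X, extra) {
  df <- data.frame(g = g)
  if (!is.null(X)) {
    X <- as.data.frame(X)
    stopifnot(nrow(X) == length(g))
    df <- cbind(df, X)
  }
  cbind(extra, df)
}

.covTerms <- function(X) {
  if (is.null(X) || ncol(as.data.frame(X)) == 0) character() else colnames(as.data.frame(X))
}

.rhs <- function(X, with_g = TRUE) {
  terms <- c(if (with_g) "g", .covTerms(X))
  if (!length(terms)) "1" else paste(terms, collapse = " + ")
}

## ----------------------------------------------------------------------------

#' Linear association (per-allele OLS)
#'
#' @param y numeric response (typically an inverse-normal transformed trait).
#' @param g per-allele dosage vector.
#' @param X optional covariate data.frame (PCs, conditioning phenotypes).
#' @return an `assocResult` with a single `g` contrast and two-sided Wald p.
#' @export
fitLinear <- function(y, g, X = NULL) {
  df <- .designFrame(g, X, data.frame(y = y))
  df <- df[complete.cases(df), , drop = FALSE]
  npar <- 2 + length(.covTerms(X))
  if (nrow(df) < npar + 1) stop("too few complete cases")
  fit <- lm(as.formula(paste("y ~", .rhs(X))), data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("collinear design, dropped columns: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  ctr <- data.frame(contrast = "g", beta = sm["g", 1], se = sm["g", 2],
                    stringsAsFactors = FALSE)
  .newAssocResult("linear", ctr, p = sm["g", 4], n = nrow(df), converged = TRUE,
                  intercepts = coef(fit)["(Intercept)"], fit = fit)
}

#' Binary logistic association
#'
#' Maximum likelihood by iteratively reweighted least squares; reports the
#' per-allele log odds ratio. Perfect separation is flagged as non-converged
#' rather than silently returned.
#'
#' @inheritParams fitLinear
#' @param y 0/1 (or logical/two-level factor) response.
#' @param p_method `"wald"` or `"lrt"` for the reported p-value.
#' @return an `assocResult`.
#' @export
fitBinaryLogistic <- function(y, g, X = NULL, p_method = c("wald", "lrt")) {
  p_method <- match.arg(p_method)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  df <- .designFrame(g, X, data.frame(y = y))
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$y)) < 2) stop("both classes must be present among complete cases")
  fit <- suppressWarnings(
    glm(as.formula(paste("y ~", .rhs(X))), family = binomial(), data = df,
        control = list(maxit = 100, epsilon = 1e-10))
  )
  mu <- fitted(fit)
  separated <- any(mu > 1 - 1e-8) || any(mu < 1e-8) || abs(coef(fit)["g"]) > 15
  conv <- fit$converged && !separated
  sm <- summary(fit)$coefficients
  pv <- if (p_method == "wald") sm["g", 4] else {
    fit0 <- suppressWarnings(glm(as.formula(paste("y ~", .rhs(X, FALSE))),
                                 family = binomial(), data = df))
    pchisq(fit0$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  }
  ctr <- data.frame(contrast = "g", beta = unname(coef(fit)["g"]),
                    se = sm["g", 2], stringsAsFactors = FALSE)
  .newAssocResult("binary", ctr, p = pv, n = nrow(df), converged = conv,
                  intercepts = coef(fit)["(Intercept)"], fit = fit)
}

#' Proportional-odds ordinal logistic association
#'
#' Fits `logit P(Y > k) = -theta_k + beta g + gamma' X` with a single
#' per-allele proportional log odds ratio; positive beta means a shift toward
#' the higher (more complicated) categories. The p-value defaults to a 1-df
#' likelihood-ratio test against `beta = 0`.
#'
#' @inheritParams fitBinaryLogistic
#' @param y ordered factor (or values coercible to one with the natural order,
#'   e.g. B1 < B2 < B3).
#' @return an `assocResult`; `cutpoints` holds the strictly increasing
#'   theta_k.
#' @export
fitOrdinalLogistic <- function(y, g, X = NULL, p_method = c("lrt", "wald")) {
  p_method <- match.arg(p_method)
  if (!is.ordered(y)) y <- factor(y, ordered = TRUE)
  df <- .designFrame(g, X, data.frame(y = y))
  df <- df[complete.cases(df), , drop = FALSE]
  df$y <- droplevels(df$y)
  k <- nlevels(df$y)
  if (k < 2) stop("need at least two occupied categories")
  if (k == 2) {                       # model collapse: single cumulative logit
    res <- fitBinaryLogistic(as.integer(df$y) - 1L, df$g,
                             df[, .covTerms(X), drop = FALSE],
                             p_method = p_method)
    res$model <- "ordinal"
    res$cutpoints <- -res$intercepts
    return(res)
  }
  fit <- suppressWarnings(
    MASS::polr(as.formula(paste("y ~", .rhs(X))), data = df, Hess = TRUE,
               method = "logistic")
  )
  conv <- fit$convergence == 0 && !is.unsorted(fit$zeta, strictly = TRUE)
  se <- sqrt(diag(vcov(fit)))["g"]
  pv <- if (p_method == "wald") {
    2 * pnorm(-abs(coef(fit)["g"] / se))
  } else {
    ll0 <- if (length(.covTerms(X))) {
      logLik(suppressWarnings(MASS::polr(as.formula(paste("y ~", .rhs(X, FALSE))),
                                         data = df, method = "logistic")))
    } else {
      tab <- table(df$y)
      sum(tab * log(tab / sum(tab)))   # intercept-only ordinal log-likelihood
    }
    pchisq(2 * (as.numeric(logLik(fit)) - as.numeric(ll0)), 1, lower.tail = FALSE)
  }
  ctr <- data.frame(contrast = "g", beta = unname(coef(fit)["g"]), se = unname(se),
                    stringsAsFactors = FALSE)
  .newAssocResult("ordinal", ctr, p = pv, n = nrow(df), converged = conv,
                  cutpoints = fit$zeta, fit = fit)
}

#' Baseline-category multinomial logistic association
#'
#' Per-contrast log odds ratios against the reference category (for Crohn's
#' disease location: ileal vs colonic and ileocolonic vs colonic), Wald SEs,
#' and an overall 2-df likelihood-ratio p for the genotype term.
#'
#' @inheritParams fitBinaryLogistic
#' @param y unordered factor of 3+ categories (e.g. L1/L2/L3).
#' @param reference reference category (default `"L2"` when present, else the
#'   first level).
#' @return an `assocResult` with one row per non-reference category.
#' @export
fitMultinomialLogistic <- function(y, g, X = NULL, reference = "L2") {
  y <- factor(y, ordered = FALSE)
  df <- .designFrame(g, X, data.frame(y = y))
  df <- df[complete.cases(df), , drop = FALSE]
  df$y <- droplevels(df$y)
  lv <- levels(df$y)
  if (length(lv) < 2) stop("need at least two occupied categories")
  if (!reference %in% lv) {
    if (identical(reference, "L2")) reference <- lv[1]
    else stop("empty reference category '", reference,
              "'; drop it or choose another reference")
  }
  df$y <- relevel(df$y, ref = reference)
  if (length(lv) == 2) {               # collapse to binary logistic
    res <- fitBinaryLogistic(as.integer(df$y) - 1L, df$g,
                             df[, .covTerms(X), drop = FALSE])
    res$model <- "multinomial"
    res$contrasts$contrast <- paste0(setdiff(lv, reference), "_vs_", reference)
    return(res)
  }
  fit <- nnet::multinom(as.formula(paste("y ~", .rhs(X))), data = df,
                        trace = FALSE, maxit = 200, Hess = TRUE, reltol = 1e-12)
  fit0 <- nnet::multinom(as.formula(paste("y ~", .rhs(X, FALSE))), data = df,
                         trace = FALSE, maxit = 200, reltol = 1e-12)
  ndf <- length(lv) - 1
  pv <- pchisq(fit0$deviance - fit$deviance, df = ndf, lower.tail = FALSE)
  cf <- coef(fit)
  V <- vcov(fit)
  gidx <- grep(":g$|^g$", colnames(V))
  ses <- sqrt(diag(V))[gidx]
  ctr <- data.frame(
    contrast = paste0(rownames(cf), "_vs_", reference),
    beta = unname(cf[, "g"]),
    se = unname(ses),
    stringsAsFactors = FALSE
  )
  .newAssocResult("multinomial", ctr, p = pv, n = nrow(df),
                  converged = fit$convergence == 0,
                  intercepts = cf[, "(Intercept)"], fit = fit)
}

#' Weibull accelerated failure time association
#'
#' Right-censored Weibull AFT maximum likelihood,
#' `log T = mu + beta g + gamma' X + sigma W`. Reports the AFT coefficient,
#' the shape `k = 1/sigma`, and the derived proportional-hazards effect
#' `log HR = -beta k` with a delta-method SE.
#'
#' @param time positive event/censoring times.
#' @param event 0/1 event indicator (1 = event observed).
#' @inheritParams fitLinear
#' @return an `assocResult` with contrasts `g_aft` (time scale) and `g_loghr`;
#'   `shape` holds k; `p` is the Wald p on the AFT coefficient.
#' @export
fitWeibullAFT <- function(time, event, g, X = NULL) {
  df <- .designFrame(g, X, data.frame(time = time, event = event))
  df <- df[complete.cases(df), , drop = FALSE]
  if (any(df$time <= 0)) stop("times must be positive")
  if (sum(df$event) < 1) stop("no events: all observations censored")
  fit <- survival::survreg(
    as.formula(paste("survival::Surv(time, event) ~", .rhs(X))),
    data = df, dist = "weibull",
    control = survival::survreg.control(maxiter = 100, rel.tolerance = 1e-10)
  )
  beta <- unname(coef(fit)["g"])
  sigma <- fit$scale
  kshape <- 1 / sigma
  V <- vcov(fit)                       # includes Log(scale)
  ig <- which(rownames(V) == "g")
  is_ <- which(rownames(V) == "Log(scale)")
  se_aft <- sqrt(V[ig, ig])
  ## logHR = -beta * exp(-s), s = log sigma; grad = (-1/sigma, beta/sigma)
  grad <- c(-1 / sigma, beta / sigma)
  se_loghr <- sqrt(drop(t(grad) %*% V[c(ig, is_), c(ig, is_)] %*% grad))
  ctr <- data.frame(
    contrast = c("g_aft", "g_loghr"),
    beta = c(beta, -beta * kshape),
    se = c(se_aft, se_loghr),
    stringsAsFactors = FALSE
  )
  pv <- 2 * pnorm(-abs(beta / se_aft))
  .newAssocResult("weibull", ctr, p = pv, n = nrow(df),
                  converged = is.null(fit$fail),
                  intercepts = coef(fit)["(Intercept)"],
                  shape = kshape, fit = fit)
}

## ----------------------------------------------------------------------------

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools per-study effects with weights `w_i = 1/SE_i^2`:
#' `beta = sum(w beta_i)/sum(w)`, `SE = sum(w)^(-1/2)`, two-sided normal p.
#'
#' @param results list of `assocResult`s on the same variant and contrast
#'   scale, or a data.frame with columns `beta` and `se` (and optionally
#'   `variant`).
#' @param contrast which contrast row to pool when given `assocResult`s
#'   (default the first).
#' @return list of class `metaResult`: `beta, se, z, p, studies`.
#' @export
metaFixed <- function(results, contrast = NULL) {
  if (is.data.frame(results)) {
    tab <- results
    if (!is.null(tab$variant) && length(unique(tab$variant)) > 1)
      stop("mismatched variant ids: ", paste(unique(tab$variant), collapse = ", "))
  } else {
    if (length(results) < 2) stop("need at least two results to meta-analyse")
    ids <- vapply(results, function(r) as.character(r$variant), "")
    if (length(unique(ids)) > 1)
      stop("mismatched variant ids: ", paste(unique(ids), collapse = ", "))
    tab <- do.call(rbind, lapply(results, function(r) {
      ctr <- r$contrasts
      row <- if (is.null(contrast)) ctr[1, ] else ctr[ctr$contrast == contrast, ]
      data.frame(beta = row$beta, se = row$se)
    }))
  }
  if (nrow(tab) < 2) stop("need at least two results to meta-analyse")
  w <- 1 / tab$se^2
  beta <- sum(w * tab$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  structure(list(beta = beta, se = se, z = z,
                 p = 2 * pnorm(-abs(z)), studies = tab),
            class = "metaResult")
}

#' @export
print.metaResult <- function(x, ...) {
  cat(sprintf("fixed-effect meta: beta=%.4g se=%.4g z=%.3g p=%.3g (%d studies)\n",
              x$beta, x$se, x$z, x$p, nrow(x$studies)))
  invisible(x)
}
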