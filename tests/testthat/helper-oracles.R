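## Independent log-likelihood oracles: each engine is checked against a
## generic numeric maximizer of the hand-written likelihood, never against
## the library that fitted it.

## binary logistic: par = (intercept, beta_g, gammas...)
nllLogistic <- function(par, y, X) {
  eta <- drop(X %*% par)
  -sum(y * eta - log1p(exp(eta)))
}

oracleLogistic <- function(y, g, Xc = NULL) {
  X <- cbind(1, g, Xc)
  opt <- optim(rep(0, ncol(X)), nllLogistic, y = y, X = X, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  opt$par
}

## proportional odds: par = (theta1, log(theta2-theta1), ..., beta, gammas)
## y integer 1..K
nllOrdinal <- function(par, y, X, K) {
  theta <- cumsum(c(par[1], exp(par[2:(K - 1)])))
  beta <- par[K:length(par)]
  eta <- drop(X %*% beta)
  ## P(Y <= k) = plogis(theta_k - eta)
  cdf <- cbind(0, plogis(outer(-eta, theta, "+")), 1)
  pr <- cdf[cbind(seq_along(y), y + 1)] - cdf[cbind(seq_along(y), y)]
  -sum(log(pmax(pr, 1e-300)))
}

oracleOrdinal <- function(y, g, Xc = NULL) {
  y <- as.integer(factor(y))
  K <- max(y)
  X <- cbind(g, Xc)
  start <- c(qlogis(cumsum(table(y) / length(y))[1]),
             rep(0, K - 2), rep(0, ncol(X)))
  opt <- optim(start, nllOrdinal, y = y, X = X, K = K, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  theta <- cumsum(c(opt$par[1], exp(opt$par[2:(K - 1)])))
  list(theta = theta, beta = opt$par[K:length(opt$par)],
       logLik = -opt$value)
}

## baseline-category multinomial, reference = level 1 of factor(y)
## par = per non-reference class: (intercept, beta_g, gammas...)
nllMultinomial <- function(par, y, X, K) {
  p <- ncol(X)
  B <- matrix(par, nrow = p, ncol = K - 1)
  eta <- cbind(0, X %*% B)
  ll <- eta[cbind(seq_along(y), y)] - log(rowSums(exp(eta)))
  -sum(ll)
}

oracleMultinomial <- function(y, g, Xc = NULL) {
  y <- as.integer(factor(y))
  K <- max(y)
  X <- cbind(1, g, Xc)
  opt <- optim(rep(0, ncol(X) * (K - 1)), nllMultinomial, y = y, X = X, K = K,
               method = "BFGS", control = list(maxit = 5000, reltol = 1e-14))
  list(B = matrix(opt$par, ncol = K - 1), logLik = -opt$value)
}

## Weibull AFT: par = (mu, beta..., log sigma); log T = mu + X beta + sigma W
nllWeibullAFT <- function(par, time, event, X) {
  k <- length(par)
  sigma <- exp(par[k])
  eta <- drop(cbind(1, X) %*% par[-k])
  z <- (log(time) - eta) / sigma
  ## event: log f = -log(sigma t) + z - e^z ; censored: log S = -e^z
  -sum(event * (z - log(sigma * time)) - exp(z))
}

oracleWeibullAFT <- function(time, event, g, Xc = NULL) {
  X <- cbind(g, Xc)
  start <- c(log(mean(time)), rep(0, ncol(X)), 0)
  opt <- optim(start, nllWeibullAFT, time = time, event = event, X = X,
               method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  k <- length(opt$par)
  list(mu = opt$par[1], beta = opt$par[2:(k - 1)], sigma = exp(opt$par[k]),
       logLik = -opt$value)
}

## small deterministic cohort builder for IO / scoring tests
makeToyCohort <- function(n = 40, nv = 6, seed = 42, phenotypes = TRUE) {
  set.seed(seed)
  d <- matrix(rbinom(n * nv, 2, 0.3), nrow = nv,
              dimnames = list(paste0("v", seq_len(nv)),
                              sprintf("S%03d", seq_len(n))))
  ph <- NULL
  if (phenotypes) {
    dg <- rep(c("CD", "UC"), length.out = n)
    ph <- data.frame(
      sample_id = colnames(d), diagnosis = dg,
      location = ifelse(dg == "CD", sample(c("L1", "L2", "L3"), n, TRUE), NA),
      behaviour = ifelse(dg == "CD", sample(c("B1", "B2", "B3"), n, TRUE), NA),
      extent = ifelse(dg == "UC", sample(c("E1", "E2", "E3"), n, TRUE), NA),
      age_at_diagnosis = round(runif(n, 10, 60)),
      sex = sample(c("male", "female"), n, TRUE),
      smoking = sample(c("smoker", "ex", "never"), n, TRUE),
      family_history = runif(n) < 0.25,
      year_of_birth = sample(1950:1990, n, TRUE),
      site = sample(c("siteA", "siteB"), n, TRUE),
      country = "X",
      followup_years = round(runif(n, 2, 25), 1),
      surgery_event = runif(n) < 0.4,
      diagnosis_revised = NA,
      stringsAsFactors = FALSE
    )
    ph$surgery_time_years <- round(pmin(rexp(n, 0.1), ph$followup_years), 2)
    stopifnot(all(ph$surgery_time_years <= ph$followup_years))
  }
  IBDCohort(d, phenotypes = ph)
}

## phenotype table expanded from category counts (Table-1 style fixtures)
expandCounts <- function(diagnosis, column, counts, n_group) {
  vals <- c(rep(names(counts), counts),
            rep(NA, n_group - sum(counts)))
  df <- data.frame(sample_id = paste0(diagnosis, seq_len(n_group)),
                   diagnosis = diagnosis, stringsAsFactors = FALSE)
  df[[column]] <- vals
  df
}
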