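## Kaplan-Meier estimation, log-rank comparisons, and behaviour-prevalence
## curves over follow-up.

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator per stratum with Greenwood-variance confidence
#' bands (via [survival::survfit]).
#'
#' @param time nonnegative event/censoring times.
#' @param event 0/1 event indicator.
#' @param strata optional stratum labels.
#' @param conf_level CI level.
#' @return data.frame of class `SurvivalCurve`: time, surv, ci_low, ci_high,
#'   n_risk, n_event, stratum.
#' @export
kmEstimate <- function(time, event, strata = NULL, conf_level = 0.95) {
  if (any(time < 0, na.rm = TRUE)) stop("negative times not allowed")
  df <- data.frame(time = time, event = as.integer(event))
  if (is.null(strata)) {
    df$stratum <- "all"
  } else df$stratum <- as.character(strata)
  df <- df[complete.cases(df), ]
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = df,
                           conf.int = conf_level)
  sm <- summary(fit, censored = TRUE)
  stratum <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
    sub("^stratum=", "", as.character(sm$strata))
  structure(data.frame(
    time = sm$time, surv = sm$surv,
    ci_low = sm$lower, ci_high = sm$upper,
    n_risk = sm$n.risk, n_event = sm$n.event,
    stratum = stratum, stringsAsFactors = FALSE
  ), class = c("SurvivalCurve", "data.frame"))
}

#' Evaluate a KM step function
#'
#' @param curve a `SurvivalCurve` (single stratum or use `stratum`).
#' @param t times at which to evaluate S(t).
#' @param stratum stratum to evaluate (default the first).
#' @return numeric S(t) values (S(0) = 1 before the first event).
#' @export
survivalAt <- function(curve, t, stratum = NULL) {
  if (is.null(stratum)) stratum <- curve$stratum[1]
  cc <- curve[curve$stratum == stratum & curve$n_event > 0, , drop = FALSE]
  cc <- cc[order(cc$time), ]
  vapply(t, function(tt) {
    i <- which(cc$time <= tt)
    if (!length(i)) 1 else cc$surv[max(i)]
  }, 0)
}

#' Log-rank test
#'
#' @inheritParams kmEstimate
#' @return list: `chisq`, `df`, `p`.
#' @export
logrankTest <- function(time, event, strata) {
  df <- data.frame(time = time, event = as.integer(event),
                   stratum = as.character(strata))
  df <- df[complete.cases(df), ]
  if (length(unique(df$stratum)) < 2) stop("need at least two strata")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = df)
  k <- length(sd_$n) - 1
  list(chisq = unname(sd_$chisq), df = k,
       p = pchisq(sd_$chisq, k, lower.tail = FALSE))
}

#' Behaviour prevalence over time since diagnosis
#'
#' At each grid time t, the proportions of B1/B2/B3 among patients whose
#' follow-up reaches t (risk-set convention; patients remain in the risk set
#' after surgery). A centered moving average over `window` years gives the
#' smoothed curves.
#'
#' @param events progression event log from [simulateProgression()] (columns
#'   t_b2, t_b3, followup_years).
#' @param grid time grid in years (default 0 to max follow-up by 0.5);
#'   truncated where the risk set empties.
#' @param window smoothing window in years (0 = none).
#' @return data.frame: time, pB1, pB2, pB3 (raw), sB1, sB2, sB3 (smoothed),
#'   n_at_risk.
#' @export
behaviourPrevalence <- function(events, grid = NULL, window = 2) {
  if (!nrow(events)) stop("empty event log")
  if (is.null(grid))
    grid <- seq(0, max(events$followup_years), by = 0.5)
  n_at_risk <- vapply(grid, function(t) sum(events$followup_years >= t), 0)
  grid <- grid[n_at_risk > 0]
  n_at_risk <- n_at_risk[n_at_risk > 0]
  props <- t(vapply(grid, function(t) {
    rs <- events[events$followup_years >= t, ]
    state <- ifelse(t >= rs$t_b3, "B3", ifelse(t >= rs$t_b2, "B2", "B1"))
    tab <- table(factor(state, levels = .BEHAVIOUR))
    as.numeric(tab) / nrow(rs)
  }, numeric(3)))
  colnames(props) <- c("pB1", "pB2", "pB3")
  smooth1 <- function(v) {
    if (window <= 0 || length(grid) < 2) return(v)
    step <- median(diff(grid))
    half <- max(1L, round((window / 2) / step))
    vapply(seq_along(v), function(i) {
      idx <- max(1, i - half):min(length(v), i + half)
      mean(v[idx])
    }, 0)
  }
  sm <- apply(props, 2, smooth1)
  if (is.null(dim(sm))) sm <- matrix(sm, nrow = 1)
  colnames(sm) <- c("sB1", "sB2", "sB3")
  data.frame(time = grid, props, sm, n_at_risk = n_at_risk)
}
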