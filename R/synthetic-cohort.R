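## Synthetic cohort generator: emits cohorts with the statistical structure the
## downstream analyses assume (three latent genetic sub-entities, population
## structure, Weibull surgery times, behaviour progression, missingness,
## label swaps) together with ground-truth records.

.SITE_TABLE <- data.frame(
  site = c("UK_Cambridge", "UK_Edinburgh", "UK_Newcastle", "BE_Leuven",
           "DE_Kiel", "NL_Groningen", "CA_Toronto", "US_Pittsburgh",
           "AU_Brisbane", "SE_Orebro"),
  country = c("UK", "UK", "UK", "Belgium", "Germany", "Netherlands",
              "Canada", "USA", "Australia", "Sweden"),
  prob = rep(0.1, 10),
  stringsAsFactors = FALSE
)

#' Default per-locus effect table
#'
#' Builds the default effect panel: 160 small-effect loci whose largest
#' pairwise subtype odds ratio is drawn uniformly in `small_or_range`, with
#' colonic Crohn's disease placed halfway between ileal Crohn's disease and
#' ulcerative colitis by construction (`beta = (1.5c, 0.5c, 0)` per allele);
#' a NOD2-like locus (ileal vs colonic OR 2.5, strong age shift, surgery
#' hazard); an MHC-like locus (ileal vs colonic OR 0.45, extent effect
#' OR 0.70); an MST1-like locus (age shift -0.06 SD, weak location effect);
#' and `n_hla` HLA-type dosage columns with larger contrasts.
#'
#' @param n_small number of small-effect loci.
#' @param n_hla number of HLA-like dosage columns.
#' @param small_or_range subtype OR range for the small loci.
#' @param maf_range MAF range for the small loci.
#' @return data.frame with columns `id, maf, beta_ileal, beta_colonic,
#'   beta_UC, age_shift, surgery_loghr, extent_logor, locus_group, is_hla`.
#'   Draws from the current RNG state.
#' @export
defaultEffectTable <- function(n_small = 160, n_hla = 22,
                               small_or_range = c(1.05, 1.2),
                               maf_range = c(0.05, 0.5)) {
  mkrow <- function(id, maf, bi, bc, bu, age = 0, surg = 0, ext = 0,
                    grp = "OTHER", hla = FALSE) {
    data.frame(id = id, maf = maf, beta_ileal = bi, beta_colonic = bc,
               beta_UC = bu, age_shift = age, surgery_loghr = surg,
               extent_logor = ext, locus_group = grp, is_hla = hla,
               stringsAsFactors = FALSE)
  }
  ## Two effect axes. Susceptibility loci (beta = (a, a, 0)) separate both CD
  ## subtypes from UC equally; location loci (beta = (b, 0, 0)) separate ileal
  ## from colonic CD (and from UC). Colonic CD is thereby intermediate between
  ## ileal CD and UC on the combined CD-vs-UC axis: it carries the full
  ## susceptibility load but none of the ileal-directed location load. The
  ## drawn OR is the largest pairwise subtype OR of the locus.
  spec <- rbind(
    mkrow("NOD2_fs1007", 0.024, 1.216, 0.30, -0.482, age = -0.16,
          surg = log(1.31), grp = "NOD2"),           # ileal vs colonic OR 2.5
    mkrow("HLA_DRB1_0103", 0.116, -0.470, 0.330, 0.630, ext = log(0.70),
          grp = "MHC", hla = TRUE),                  # ileal vs colonic OR 0.45
    mkrow("MST1_3p21", 0.29, 0.060, -0.035, -0.040, age = -0.06, grp = "MST1")
  )
  n_loc <- round(n_small * 0.375)                    # 60 of the default 160
  n_sus <- n_small - n_loc
  ors <- log(runif(n_small, small_or_range[1], small_or_range[2])) *
    sample(c(-1, 1), n_small, replace = TRUE)
  kind <- rep(c("sus", "loc"), c(n_sus, n_loc))
  small <- mkrow(sprintf("snp%04d", seq_len(n_small)),
                 runif(n_small, maf_range[1], maf_range[2]),
                 ors,
                 ifelse(kind == "sus", ors, 0),
                 0)
  ch <- runif(n_hla, 0.1, 0.4) * sample(c(-1, 1), n_hla, replace = TRUE)
  kind_h <- rep(c("sus", "loc"), length.out = n_hla)
  hla <- mkrow(sprintf("HLA_type%02d", seq_len(n_hla)),
               runif(n_hla, 0.02, 0.3),
               ch,
               ifelse(kind_h == "sus", ch, 0),
               0, grp = "MHC", hla = TRUE)
  rbind(spec, small, hla)
}

#' Simulation configuration
#'
#' Returns a validated configuration list for [simulateCohort()]. Defaults
#' describe a consortium-scale IBD case cohort: ~30 000 cases split roughly
#' 57/43 between Crohn's disease and ulcerative colitis, three latent genetic
#' sub-entities (ileal CD, colonic CD, UC), five axes of population structure,
#' behaviour progression over follow-up, and right-censored Weibull surgery
#' times. See the methods vignette for the provenance of each default.
#'
#' @param n_samples cohort size.
#' @param n_null_variants extra variants with no phenotype effect.
#' @param maf_range minor allele frequency range for simulated loci.
#' @param subtype_base_probs baseline probabilities of (ilealCD, colonicCD, UC).
#' @param effect_table per-locus effect table (NULL = [defaultEffectTable()],
#'   drawn from the genotype-stage sub-seed).
#' @param n_pcs_structural number of latent ancestry axes.
#' @param pc_effect_on_freq SD of per-variant logit allele-frequency loadings
#'   on their ancestry axis.
#' @param pc_class_effect log-odds shift of the ileal class per SD of the
#'   first ancestry axis (structure/phenotype confounding).
#' @param ileocolonic_blend a Crohn's sample is ileocolonic (L3) when its
#'   ileal and colonic linear predictors are within this margin.
#' @param ibdu_margin samples whose best CD predictor and UC predictor are
#'   within this margin are labelled IBDU.
#' @param age_model `c(mean, sd)` of age at diagnosis in years; per-locus
#'   `age_shift` is in SD units of this model.
#' @param behaviour_progression list of `c(rate_B1toB2, rate_B2toB3)` per
#'   location (per year).
#' @param weibull_surgery list with `shape` and per-stratum scales
#'   `scale_L1, scale_L2, scale_L3, scale_E3, scale_nonE3` (years).
#' @param extent_base baseline probability of extensive (E3) disease.
#' @param censoring_rate probability of extra administrative censoring of the
#'   surgery time before the end of follow-up.
#' @param missing_rates named list of MCAR missingness rates per field.
#' @param misdiagnosis_rate fraction of CD/UC labels swapped by
#'   [spikeMisdiagnosis()] in pipeline runs.
#' @param revision_sensitivity,revision_background probabilities that masked
#'   re-phenotyping raises doubts about a swapped / correctly labelled case.
#' @param location_other_rate,extent_other_rate rates of the Montreal OTHER
#'   categories.
#' @param followup_meanlog,followup_sdlog log-normal follow-up distribution
#'   (median `exp(meanlog)` years).
#' @param site_table data.frame `site, country, prob` of recruitment sites.
#' @param seed integer seed driving ordered per-stage sub-seeds.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    n_samples = 30000,
    n_null_variants = 15,
    maf_range = c(0.05, 0.5),
    subtype_base_probs = c(ilealCD = 0.28, colonicCD = 0.29, UC = 0.43),
    effect_table = NULL,
    n_pcs_structural = 5,
    pc_effect_on_freq = 0.25,
    pc_class_effect = 0.1,
    ileocolonic_blend = 0.49,
    ibdu_margin = 0.02,
    age_model = c(mean = 28, sd = 12),
    behaviour_progression = list(L1 = c(0.09, 0.10), L2 = c(0.035, 0.06),
                                 L3 = c(0.065, 0.08), OTHER = c(0.035, 0.06)),
    weibull_surgery = list(shape = 1.2, scale_L1 = 11, scale_L2 = 24,
                           scale_L3 = 15, scale_E3 = 30, scale_nonE3 = 60),
    extent_base = 0.48,
    censoring_rate = 0,
    missing_rates = list(location = 0.17, behaviour = 0.17, extent = 0.13,
                         age = 0.13, smoking = 0.27, family_history = 0.20,
                         sex = 0.02, surgery = 0.17),
    misdiagnosis_rate = 0.05,
    revision_sensitivity = 0.80,
    revision_background = 0.06,
    location_other_rate = 0.01,
    extent_other_rate = 0.02,
    followup_meanlog = log(10.5),
    followup_sdlog = 0.55,
    site_table = .SITE_TABLE,
    seed = 1L) {
  cfg <- as.list(environment())
  p <- cfg$subtype_base_probs
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("subtype_base_probs must be a 3-probability simplex")
  if (cfg$weibull_surgery$shape <= 0) stop("Weibull shape must be positive")
  if (any(unlist(cfg$weibull_surgery[-1]) <= 0)) stop("Weibull scales must be positive")
  rates <- c(unlist(cfg$missing_rates), cfg$misdiagnosis_rate,
             cfg$censoring_rate, cfg$revision_sensitivity, cfg$revision_background)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must satisfy 0 < lo <= hi <= 0.5")
  class(cfg) <- "SimulationConfig"
  cfg
}

.subSeeds <- function(seed, n = 8L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.rexpSafe <- function(n, rate) {
  out <- rep(Inf, n)
  pos <- rate > 0
  if (length(rate) == 1) {
    if (pos) out <- rexp(n, rate)
  } else if (any(pos)) {
    out[pos] <- rexp(sum(pos), rate[pos])
  }
  out
}

#' Simulate an IBD case cohort with ground truth
#'
#' Genotypes are drawn `g ~ Binomial(2, p_j(ancestry))` with structure-linked
#' frequencies; each sample's latent sub-entity (ileal CD, colonic CD, UC) is
#' drawn from a multinomial logit over `eta_k = alpha_k + sum_j beta_jk g_j +
#' gamma PC1`; observed diagnosis, Montreal codes, demographics, behaviour
#' progression, and right-censored Weibull surgery times follow, with MCAR
#' missingness applied last. Fully reproducible under `cfg$seed`.
#'
#' @param cfg a [simulationConfig()].
#' @return list with elements `cohort` (an [IBDCohort-class]) and `truth`
#'   (class `TruthRecord`: per-sample latent class, linear predictors,
#'   swapped-label flags, true progression/surgery times, plus the effect
#'   table and stage seeds).
#' @export
simulateCohort <- function(cfg = simulationConfig()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  seeds <- .subSeeds(cfg$seed)
  n <- cfg$n_samples

  ## stage 1: effect table + genotypes ---------------------------------------
  set.seed(seeds[1])
  eff <- cfg$effect_table
  if (is.null(eff)) eff <- defaultEffectTable(maf_range = cfg$maf_range)
  n_eff <- nrow(eff)
  vids <- c(eff$id, if (cfg$n_null_variants > 0)
    sprintf("null%03d", seq_len(cfg$n_null_variants)))
  mafs <- c(eff$maf, runif(cfg$n_null_variants, cfg$maf_range[1], cfg$maf_range[2]))
  nv <- length(vids)
  Z <- matrix(rnorm(n * cfg$n_pcs_structural), n, cfg$n_pcs_structural)
  axis <- sample.int(cfg$n_pcs_structural, nv, replace = TRUE)
  load <- rnorm(nv, 0, cfg$pc_effect_on_freq)
  G <- matrix(0L, n, nv, dimnames = list(sprintf("S%05d", seq_len(n)), vids))
  for (j in seq_len(nv)) {
    pj <- plogis(qlogis(mafs[j]) + load[j] * Z[, axis[j]])
    G[, j] <- rbinom(n, 2L, pj)
  }

  ## stage 2: latent class ----------------------------------------------------
  set.seed(seeds[2])
  B <- as.matrix(eff[, c("beta_ileal", "beta_colonic", "beta_UC")])
  ## center dosages at 2*maf so the configured base probabilities are the
  ## population class frequencies regardless of the drawn effect table
  Gc <- sweep(G[, seq_len(n_eff), drop = FALSE], 2, 2 * mafs[seq_len(n_eff)], "-")
  eta <- Gc %*% B
  eta <- sweep(eta, 2, log(cfg$subtype_base_probs), "+")
  eta[, 1] <- eta[, 1] + cfg$pc_class_effect * Z[, 1]
  gumb <- matrix(-log(rexp(n * 3)), n, 3)
  cls <- max.col(eta + gumb)
  class_lab <- c("ilealCD", "colonicCD", "UC")[cls]

  ## stage 3: phenotype assembly ----------------------------------------------
  set.seed(seeds[3])
  diagnosis <- ifelse(cls == 3, "UC", "CD")
  d_cu <- pmax(eta[, 1], eta[, 2]) - eta[, 3]
  diagnosis[abs(d_cu) < cfg$ibdu_margin] <- "IBDU"
  isCD <- diagnosis == "CD"; isUC <- diagnosis == "UC"

  ## location bands on the ileal-vs-colonic predictor difference: ileocolonic
  ## (L3) when the ileal and colonic linear predictors are within the blend
  ## margin, ileal/colonic outside it
  d_ic <- eta[, 1] - eta[, 2]
  location <- rep(NA_character_, n)
  location[isCD] <- ifelse(d_ic[isCD] > cfg$ileocolonic_blend, "L1",
                           ifelse(d_ic[isCD] < -cfg$ileocolonic_blend, "L2", "L3"))
  loc_other <- isCD & (runif(n) < cfg$location_other_rate)
  location[loc_other] <- "OTHER"

  upper_gi <- ifelse(isCD, runif(n) < 0.14, NA)
  perianal <- ifelse(isCD, runif(n) < 0.20, NA)

  extent <- rep(NA_character_, n)
  ext_eta <- qlogis(cfg$extent_base) + Gc %*% eff$extent_logor
  e3 <- runif(n) < plogis(ext_eta)
  extent[isUC] <- ifelse(e3[isUC], "E3",
                         ifelse(runif(sum(isUC)) < 0.237, "E1", "E2"))
  ext_other <- isUC & (runif(n) < cfg$extent_other_rate)
  extent[ext_other] <- "OTHER"

  age_shift <- drop(G[, seq_len(n_eff), drop = FALSE] %*% eff$age_shift)
  age <- cfg$age_model[["mean"]] +
    cfg$age_model[["sd"]] * (rnorm(n) + age_shift)
  age <- pmin(pmax(age, 1), 90)

  followup <- pmin(pmax(rlnorm(n, cfg$followup_meanlog, cfg$followup_sdlog), 0.5), 40)

  sex <- ifelse(runif(n) < ifelse(isCD, 0.56, 0.49), "female", "male")
  smoke_p <- ifelse(isCD, 1, 0)
  smoking <- character(n)
  u <- runif(n)
  smoking[isCD] <- ifelse(u[isCD] < 0.28, "smoker",
                          ifelse(u[isCD] < 0.42, "ex", "never"))
  smoking[!isCD] <- ifelse(u[!isCD] < 0.12, "smoker",
                           ifelse(u[!isCD] < 0.40, "ex", "never"))
  famhist <- runif(n) < ifelse(isCD, 0.27, 0.21)
  si <- sample.int(nrow(cfg$site_table), n, replace = TRUE,
                   prob = cfg$site_table$prob)
  site <- cfg$site_table$site[si]
  country <- cfg$site_table$country[si]
  yob <- round(2010 - age - followup)

  ## behaviour progression (location-specific exponential waits)
  haz <- cfg$behaviour_progression
  lockey <- ifelse(is.na(location) | !location %in% names(haz), "OTHER", location)
  h12 <- vapply(haz, `[`, 0, 1); h23 <- vapply(haz, `[`, 0, 2)
  r12 <- unname(h12[lockey]); r23 <- unname(h23[lockey])
  t_b2 <- .rexpSafe(n, r12)
  t_b3 <- t_b2 + .rexpSafe(n, r23)
  behaviour <- rep(NA_character_, n)
  behaviour[isCD] <- ifelse(followup[isCD] >= t_b3[isCD], "B3",
                            ifelse(followup[isCD] >= t_b2[isCD], "B2", "B1"))

  ## stage 4: surgery ----------------------------------------------------------
  set.seed(seeds[4])
  ws <- cfg$weibull_surgery
  k <- ws$shape
  scale <- rep(ws$scale_nonE3, n)
  scale[isCD] <- ifelse(location[isCD] == "L1", ws$scale_L1,
                        ifelse(location[isCD] == "L3", ws$scale_L3, ws$scale_L2))
  scale[isCD & is.na(location)] <- ws$scale_L2
  scale[isUC] <- ifelse(!is.na(extent) & extent == "E3", ws$scale_E3,
                        ws$scale_nonE3)[isUC]
  surg_lp <- drop(Gc %*% eff$surgery_loghr)
  scale <- scale * exp(-surg_lp / k)
  t_surg <- rweibull(n, shape = k, scale = scale)
  cens <- followup
  if (cfg$censoring_rate > 0) {
    adm <- runif(n) < cfg$censoring_rate
    cens[adm] <- runif(sum(adm), 0, followup[adm])
  }
  surgery_event <- t_surg <= cens
  surgery_time <- pmin(t_surg, cens)

  P <- data.frame(
    sample_id = rownames(G), diagnosis = diagnosis, location = location,
    upper_gi_L4 = upper_gi, behaviour = behaviour, perianal = perianal,
    extent = extent, age_at_diagnosis = age, age_band = ageBand(age),
    sex = sex, smoking = smoking, family_history = famhist,
    year_of_birth = yob, site = site, country = country,
    followup_years = followup, surgery_event = surgery_event,
    surgery_time_years = surgery_time, diagnosis_revised = NA,
    stringsAsFactors = FALSE
  )

  ## stage 5: missingness (MCAR) ----------------------------------------------
  set.seed(seeds[5])
  mr <- cfg$missing_rates
  mask <- function(col, rate) {
    if (is.null(rate) || rate <= 0) return()
    hit <- runif(n) < rate
    P[hit, col] <<- NA
  }
  mask("location", mr$location); mask("behaviour", mr$behaviour)
  mask("extent", mr$extent); mask("smoking", mr$smoking)
  mask("family_history", mr$family_history); mask("sex", mr$sex)
  if (!is.null(mr$age) && mr$age > 0) {
    hit <- runif(n) < mr$age
    P$age_at_diagnosis[hit] <- NA; P$age_band[hit] <- NA
  }
  if (!is.null(mr$surgery) && mr$surgery > 0) {
    hit <- runif(n) < mr$surgery
    P$surgery_event[hit] <- NA; P$surgery_time_years[hit] <- NA
  }

  vmeta <- data.frame(
    id = vids, chrom = "synth", pos = seq_along(vids),
    ref = "A", alt = "B",
    locus_group = c(eff$locus_group, rep("OTHER", cfg$n_null_variants)),
    is_hla = c(eff$is_hla, rep(FALSE, cfg$n_null_variants)),
    stringsAsFactors = FALSE
  )
  cohort <- IBDCohort(t(G), variants = vmeta, phenotypes = P)

  truth <- structure(list(
    record = data.frame(
      sample_id = rownames(G), class = class_lab,
      eta_ileal = eta[, 1], eta_colonic = eta[, 2], eta_UC = eta[, 3],
      swapped = FALSE, t_b2 = t_b2, t_b3 = t_b3, t_surgery = t_surg,
      stringsAsFactors = FALSE
    ),
    effect_table = eff, config = cfg, seeds = seeds
  ), class = "TruthRecord")
  list(cohort = cohort, truth = truth)
}

#' @export
print.TruthRecord <- function(x, ...) {
  cat("TruthRecord:", nrow(x$record), "samples;",
      nrow(x$effect_table), "effect loci;",
      sum(x$record$swapped), "swapped labels\n")
  invisible(x)
}

#' Spike misdiagnosed (swapped) labels
#'
#' Swaps the diagnosis of a Bernoulli(rate) subset of CD/UC samples and
#' re-codes Montreal fields to the nearest valid state: swapped-to-CD samples
#' become colonic (L2) inflammatory (B1) with extent cleared, swapped-to-UC
#' samples become extensive (E3) with location/behaviour cleared.
#' `diagnosis_revised` is left for downstream assignment
#' (see [assignRevision()]).
#'
#' @param x an [IBDCohort-class] or a phenotype data.frame.
#' @param truth the matching `TruthRecord` (swapped flags are updated).
#' @param rate swap probability in \[0, 1\].
#' @param seed RNG seed.
#' @return list `(x, truth)` with the same type of `x` as supplied.
#' @export
spikeMisdiagnosis <- function(x, truth, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  P <- if (is(x, "IBDCohort")) phenotypes(x) else x
  set.seed(seed)
  eligible <- !is.na(P$diagnosis) & P$diagnosis %in% c("CD", "UC")
  hit <- eligible & (runif(nrow(P)) < rate)
  toUC <- hit & P$diagnosis == "CD"
  toCD <- hit & P$diagnosis == "UC"
  P$diagnosis[toUC] <- "UC"
  P$extent[toUC] <- "E3"
  P$location[toUC] <- NA; P$behaviour[toUC] <- NA
  P$upper_gi_L4[toUC] <- NA; P$perianal[toUC] <- NA
  P$diagnosis[toCD] <- "CD"
  P$location[toCD] <- "L2"; P$behaviour[toCD] <- "B1"
  P$extent[toCD] <- NA
  idx <- match(P$sample_id, truth$record$sample_id)
  truth$record$swapped[idx[hit]] <- TRUE
  if (is(x, "IBDCohort")) phenotypes(x) <- P else x <- P
  list(x = x, truth = truth)
}

#' Assign masked re-phenotyping outcomes
#'
#' Emulates the masked clinical re-phenotyping arm: doubts are raised about a
#' swapped case with probability `sensitivity` and about a correctly labelled
#' case with probability `background`; the result is written to
#' `diagnosis_revised`.
#'
#' @inheritParams spikeMisdiagnosis
#' @param sensitivity,background revision probabilities.
#' @return `x` with `diagnosis_revised` filled.
#' @export
assignRevision <- function(x, truth, sensitivity = 0.80, background = 0.06,
                           seed = 1L) {
  P <- if (is(x, "IBDCohort")) phenotypes(x) else x
  set.seed(seed)
  sw <- truth$record$swapped[match(P$sample_id, truth$record$sample_id)]
  pr <- ifelse(sw, sensitivity, background)
  P$diagnosis_revised <- runif(nrow(P)) < pr
  if (is(x, "IBDCohort")) { phenotypes(x) <- P; x } else P
}

#' Simulate behaviour progression
#'
#' Draws per-sample B1->B2 and B2->B3 exponential waiting times with
#' location-specific rates, records behaviour at last follow-up, and returns
#' the event log used by [behaviourPrevalence()].
#'
#' @param P phenotype data.frame (CD samples with follow-up are progressed).
#' @param hazards list of `c(rate_B1toB2, rate_B2toB3)` per location.
#' @param seed RNG seed.
#' @return list with `events` (sample_id, location, t_b2, t_b3,
#'   followup_years, behaviour) and `phenotypes` (P with behaviour updated).
#' @export
simulateProgression <- function(P,
                                hazards = list(L1 = c(0.10, 0.05),
                                               L2 = c(0.04, 0.02),
                                               L3 = c(0.075, 0.04),
                                               OTHER = c(0.04, 0.02)),
                                seed = 1L) {
  set.seed(seed)
  cd <- !is.na(P$diagnosis) & P$diagnosis == "CD" & !is.na(P$followup_years)
  n <- sum(cd)
  loc <- P$location[cd]
  lockey <- ifelse(is.na(loc) | !loc %in% names(hazards), "OTHER", loc)
  h12 <- vapply(hazards, `[`, 0, 1); h23 <- vapply(hazards, `[`, 0, 2)
  r12 <- unname(h12[lockey]); r23 <- unname(h23[lockey])
  t_b2 <- .rexpSafe(n, r12)
  t_b3 <- t_b2 + .rexpSafe(n, r23)
  fu <- P$followup_years[cd]
  beh <- ifelse(fu >= t_b3, "B3", ifelse(fu >= t_b2, "B2", "B1"))
  P$behaviour[cd] <- beh
  list(
    events = data.frame(sample_id = P$sample_id[cd], location = loc,
                        t_b2 = t_b2, t_b3 = t_b3, followup_years = fu,
                        behaviour = beh, stringsAsFactors = FALSE),
    phenotypes = P
  )
}
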