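# ibdsubpheno

Statistical genetics of inflammatory bowel disease (IBD) subphenotypes:
association scans, genetic risk scores, and natural-history summaries for
Crohn's disease (CD) and ulcerative colitis (UC) cohorts classified under the
Montreal system.

## Who this is for

Statistical geneticists and IBD researchers who have (or want to prototype
against) genotype dosages plus Montreal-coded phenotypes — diagnosis, CD
location (L1 ileal / L2 colonic / L3 ileocolonic), CD behaviour
(B1 < B2 < B3), UC extent (E1/E2/E3), age at onset, follow-up and surgery —
and who want the full genotype–subphenotype toolchain in one tested package.
A synthetic cohort generator with ground-truth records makes every stage
runnable and verifiable without any data download.

## What it computes

Per variant, with the top five genotype principal components and optional
cross-phenotype conditioning as covariates:

* **location** — baseline-category multinomial logit (reference L2):
  odds ratios for ileal vs colonic and ileocolonic vs colonic, overall 2-df
  likelihood-ratio p;
* **behaviour** — proportional odds: `logit P(Y > k) = -theta_k + beta g + gamma'X`,
  one OR for B2+B3 vs B1 (equivalently B3 vs B1+B2);
* **extent / upper-GI / perianal** — binary logistic (E3 vs E1+E2);
* **age at onset** — linear regression on the rank-based inverse normal
  transform (effects in SD units), CD and UC meta-analysed by fixed-effect
  inverse-variance pooling;
* **time to surgery / colectomy** — Weibull accelerated failure time with
  shape `k = 1/sigma` and `log HR = -beta k`.

Tiers: genome-wide p < 5e-8, suggestive p < 1e-5 (strict), with
meta-analytic discovery + replication combination.

Per sample, genetic risk scores `S_i = sum_j w_j d_ij` in natural-log odds
units, with the CD-vs-UC difference score `w = w_CD - w_UC` as the work-horse:
continuum placement of subtypes, site-held-out classification AUC,
score-outlier flagging (CD with S <= -2, UC with S >= +2) with site-matched
comparators and a revision-enrichment test, two-group vs three-group BIC
evidence, McKelvey–Zavoina variance decomposition, analytic power,
Kaplan-Meier curves and behaviour-prevalence trajectories.

## Worked example

```r
library(ibdsubpheno)

sim <- simulateCohort(simulationConfig(n_samples = 8000, seed = 42))
x <- sim$cohort
x
#> IBDCohort: 200 variants x 8000 samples
#>   diagnosis: CD=4561, UC=3314, IBDU=125
#>   locus groups: NOD2=1, MHC=23, MST1=1, OTHER=175 | HLA dosage columns: 23
#>   median MAF: 0.246 | median missingness: 0

## location scan at three loci
res <- runScan(x, scanConfig("location", k_pcs = 5),
               variants = c("NOD2_fs1007", "HLA_DRB1_0103", "snp0001"))
res[, c("variant", "contrast", "or_hr", "p", "tier")]
#>         variant contrast   or_hr         p        tier
#> 1   NOD2_fs1007 L1_vs_L2 12.0522  2.03e-33 genome_wide
#> 2   NOD2_fs1007 L3_vs_L2  3.1608  2.03e-33 genome_wide
#> 3 HLA_DRB1_0103 L1_vs_L2  0.0667 3.76e-107 genome_wide
#> 4 HLA_DRB1_0103 L3_vs_L2  0.2278 3.76e-107 genome_wide
#> 5       snp0001 L1_vs_L2  1.2725  3.62e-03        null
#> 6       snp0001 L3_vs_L2  1.1334  3.62e-03        null

## CD-vs-UC risk score and the subphenotype continuum
P <- phenotypes(x)
pcs <- computePCs(x, 5)
panel <- estimateEffectPanel(x, ifelse(P$diagnosis %in% c("CD", "UC"),
                                       P$diagnosis, NA), pcs = pcs)
s <- scoreSamples(x, buildScoreWeights(panel, "CD_vs_UC"))
grp <- ifelse(P$diagnosis == "UC", "UC",
              ifelse(P$location %in% c("L1", "L2", "L3") & P$diagnosis == "CD",
                     paste0("CD_", P$location), NA))
continuumSummary(s, grp)
#>   group    n   mean     se  ci_low ci_high
#> 3    UC 3314 -0.583 0.0144 -0.6112  -0.555
#> 2 CD_L2  954 -0.300 0.0255 -0.3496  -0.249
#> 1 CD_L3 1577  0.119 0.0188  0.0818   0.155
#> 4 CD_L1 1222  0.611 0.0231  0.5654   0.656
```

Reading the output: the NOD2-like frameshift drives ileal location (its
fitted L1-vs-L2 OR is a band-membership contrast on the observed labels, so
it exceeds the generative per-allele OR of 2.5 — see the methods vignette);
the HLA-like allele pulls toward colonic disease; and the score continuum
orders the groups UC < colonic CD < ileocolonic CD < ileal CD with
non-overlapping 95% CIs, placing colonic CD between UC and ileal CD.

An end-to-end run — cohort, Table-1-style summary, tiered scans, scores,
continuum, outlier/misdiagnosis report, Kaplan-Meier and prevalence curves —
writes a TSV/JSON bundle:

```r
runPipeline(list(seed = 4, simulate = list(n_samples = 2500)), "out/")
```

or from a shell, `Rscript inst/scripts/run_pipeline.R --config cfg.yaml --out out/`.

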