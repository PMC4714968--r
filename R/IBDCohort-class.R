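#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats aggregate as.formula binomial complete.cases coef fisher.test
#'   glm lm logLik na.omit pchisq plogis pnorm qlogis qnorm quantile rbinom rexp
#'   rlnorm rmultinom rnorm runif rweibull sd setNames var vcov weighted.mean
#'   predict anova AIC BIC relevel model.matrix ecdf median fitted
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table head packageVersion
NULL

## Montreal classification vocabulary -----------------------------------------

#' Montreal classification vocabulary
#'
#' Controlled vocabularies used throughout the package for diagnosis, Crohn's
#' disease location (L1 ileal, L2 colonic, L3 ileocolonic), behaviour
#' (B1 inflammatory < B2 stricturing < B3 penetrating), ulcerative colitis
#' extent (E1 proctitis, E2 left-sided, E3 extensive) and age bands
#' (A1 under 17, A2 17-40, A3 over 40).
#'
#' @name montrealVocabulary
#' @keywords internal
NULL

.DIAGNOSIS <- c("CD", "UC", "IBDU")
.LOCATION  <- c("L1", "L2", "L3", "OTHER")
.BEHAVIOUR <- c("B1", "B2", "B3")
.EXTENT    <- c("E1", "E2", "E3", "OTHER")
.AGEBAND   <- c("A1", "A2", "A3")
.SMOKING   <- c("smoker", "ex", "never")
.SEX       <- c("male", "female")
.LOCUS_GROUPS <- c("NOD2", "MHC", "MST1", "OTHER")

.PHENO_COLUMNS <- c(
  "sample_id", "diagnosis", "location", "upper_gi_L4", "behaviour",
  "perianal", "extent", "age_at_diagnosis", "age_band", "sex", "smoking",
  "family_history", "year_of_birth", "site", "country", "followup_years",
  "surgery_event", "surgery_time_years", "diagnosis_revised"
)

#' Montreal age band from age at diagnosis
#'
#' A1 is diagnosis before age 17, A2 between 17 and 40 inclusive, A3 after 40.
#'
#' @param age numeric vector of ages at diagnosis in years (NA allowed).
#' @return character vector of `"A1"`, `"A2"`, `"A3"` or `NA`.
#' @export
#' @examples
#' ageBand(c(16, 17, 40, 41, NA))
ageBand <- function(age) {
  out <- rep(NA_character_, length(age))
  out[!is.na(age) & age < 17] <- "A1"
  out[!is.na(age) & age >= 17 & age <= 40] <- "A2"
  out[!is.na(age) & age > 40] <- "A3"
  out
}

## IBDCohort -------------------------------------------------------------------

#' IBDCohort: genotype dosages with Montreal phenotypes
#'
#' S4 container for a genotyped IBD cohort, extending
#' [SummarizedExperiment::SummarizedExperiment]. Rows are variants, columns are
#' samples. The single assay `"dosage"` holds per-allele dosages in \[0, 2\]
#' (NA for missing genotypes). `rowData` carries the variant table (id, chrom,
#' pos, ref, alt, locus_group, is_hla, maf, missingness); `colData` carries the
#' Montreal phenotype table.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @export
setClass("IBDCohort", contains = "SummarizedExperiment")

.computeVariantStats <- function(d) {
  ## d: variants x samples dosage matrix
  nmiss <- rowSums(is.na(d))
  p <- rowMeans(d, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  list(maf = pmin(p, 1 - p), missingness = nmiss / ncol(d))
}

setValidity("IBDCohort", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    rng <- range(d, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("id", "locus_group", "is_hla", "maf", "missingness")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(rd$id)) msg <- c(msg, "variant ids must be unique")
    maf <- rd$maf
    if (any(!is.na(maf) & (maf < 0 | maf > 0.5)))
      msg <- c(msg, "maf must lie in [0, 0.5]")
    mr <- rd$missingness
    if (any(!is.na(mr) & (mr < 0 | mr > 1)))
      msg <- c(msg, "missingness must lie in [0, 1]")
  }
  cd <- SummarizedExperiment::colData(object)
  if (all(c("surgery_time_years", "followup_years") %in% colnames(cd))) {
    st <- cd$surgery_time_years; fu <- cd$followup_years
    bad <- !is.na(st) & !is.na(fu) & st > fu + 1e-9
    if (any(bad)) msg <- c(msg, "surgery_time_years must not exceed followup_years")
    if (any(!is.na(st) & st < 0)) msg <- c(msg, "event times must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IBDCohort
#'
#' @param dosages numeric matrix of per-allele dosages, variants in rows and
#'   samples in columns (values in \[0, 2\], NA = missing). Row and column
#'   names are used as variant and sample ids when `variants`/`phenotypes`
#'   do not provide them.
#' @param variants optional data.frame of variant metadata with columns among
#'   `id, chrom, pos, ref, alt, locus_group, is_hla`. MAF and missingness are
#'   (re)computed from the dosages.
#' @param phenotypes optional data.frame of per-sample phenotypes keyed by
#'   `sample_id` (see [readPhenotypes()] for the column vocabulary).
#' @return an [IBDCohort-class] object.
#' @export
IBDCohort <- function(dosages, variants = NULL, phenotypes = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("var", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("S", seq_len(ncol(dosages)))
  if (is.null(variants)) {
    variants <- data.frame(id = rownames(dosages), stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants)
  if (!"id" %in% colnames(variants)) variants$id <- rownames(dosages)
  if (anyDuplicated(variants$id))
    stop("duplicate variant id: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (!"chrom" %in% colnames(variants)) variants$chrom <- NA_character_
  if (!"pos" %in% colnames(variants)) variants$pos <- NA_integer_
  if (!"ref" %in% colnames(variants)) variants$ref <- NA_character_
  if (!"alt" %in% colnames(variants)) variants$alt <- NA_character_
  if (!"locus_group" %in% colnames(variants)) variants$locus_group <- "OTHER"
  if (!"is_hla" %in% colnames(variants)) variants$is_hla <- FALSE
  bad <- !variants$locus_group %in% .LOCUS_GROUPS
  if (any(bad))
    stop("unknown locus_group: ", paste(unique(variants$locus_group[bad]), collapse = ", "))
  stats <- .computeVariantStats(dosages)
  variants$maf <- stats$maf
  variants$missingness <- stats$missingness
  rownames(dosages) <- variants$id

  if (is.null(phenotypes)) {
    phenotypes <- data.frame(sample_id = colnames(dosages), stringsAsFactors = FALSE)
  } else {
    phenotypes <- as.data.frame(phenotypes)
    if (!"sample_id" %in% colnames(phenotypes))
      stop("phenotypes must have a sample_id column")
    idx <- match(colnames(dosages), phenotypes$sample_id)
    if (anyNA(idx))
      stop("phenotypes missing for samples: ",
           paste(head(colnames(dosages)[is.na(idx)], 5), collapse = ", "))
    phenotypes <- phenotypes[idx, , drop = FALSE]
  }
  rownames(phenotypes) <- phenotypes$sample_id

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosages),
    rowData = S4Vectors::DataFrame(variants),
    colData = S4Vectors::DataFrame(phenotypes)
  )
  new("IBDCohort", se)
}

## Accessors -------------------------------------------------------------------

#' Accessors for IBDCohort
#'
#' `dosages()` returns the dosage matrix (variants x samples by default),
#' `variantInfo()` the variant metadata data.frame, and `phenotypes()` the
#' Montreal phenotype data.frame.
#'
#' @param x an [IBDCohort-class].
#' @param samplesInRows if TRUE, return the transposed (samples x variants)
#'   dosage matrix.
#' @return see individual descriptions.
#' @name IBDCohort-accessors
#' @aliases dosages variantInfo phenotypes
NULL

#' @rdname IBDCohort-accessors
#' @export
setGeneric("dosages", function(x, samplesInRows = FALSE) standardGeneric("dosages"))

#' @rdname IBDCohort-accessors
#' @export
setMethod("dosages", "IBDCohort", function(x, samplesInRows = FALSE) {
  d <- SummarizedExperiment::assay(x, "dosage")
  if (samplesInRows) t(d) else d
})

#' @rdname IBDCohort-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname IBDCohort-accessors
#' @export
setMethod("variantInfo", "IBDCohort", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @rdname IBDCohort-accessors
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname IBDCohort-accessors
#' @export
setMethod("phenotypes", "IBDCohort", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' Replace the phenotype table of a cohort
#'
#' @param x an [IBDCohort-class].
#' @param value a phenotype data.frame with a `sample_id` column covering all
#'   samples of `x`.
#' @return the updated cohort.
#' @export
setGeneric("phenotypes<-", function(x, value) standardGeneric("phenotypes<-"))

#' @rdname phenotypes-set
#' @name phenotypes<-
#' @export
setMethod("phenotypes<-", "IBDCohort", function(x, value) {
  value <- as.data.frame(value)
  idx <- match(colnames(x), value$sample_id)
  if (anyNA(idx)) stop("phenotypes missing for some samples")
  value <- value[idx, , drop = FALSE]
  rownames(value) <- value$sample_id
  SummarizedExperiment::colData(x) <- S4Vectors::DataFrame(value)
  validObject(x)
  x
})

setMethod("show", "IBDCohort", function(object) {
  cat("IBDCohort:", nrow(object), "variants x", ncol(object), "samples\n")
  ph <- phenotypes(object)
  if ("diagnosis" %in% colnames(ph)) {
    tab <- table(factor(ph$diagnosis, levels = .DIAGNOSIS), useNA = "ifany")
    cat("  diagnosis:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  vi <- variantInfo(object)
  sp <- table(factor(vi$locus_group, levels = .LOCUS_GROUPS))
  cat("  locus groups:", paste(names(sp), sp, sep = "=", collapse = ", "),
      "| HLA dosage columns:", sum(vi$is_hla), "\n")
  cat("  median MAF:", signif(median(vi$maf, na.rm = TRUE), 3),
      "| median missingness:", signif(median(vi$missingness, na.rm = TRUE), 3), "\n")
  invisible(NULL)
})
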