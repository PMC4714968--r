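## Readers/writers for genotype and phenotype data, genotype PCs, and the
## cohort summarizer.

.GT_MAP <- c(
  "0/0" = 0, "0|0" = 0,
  "0/1" = 1, "1/0" = 1, "0|1" = 1, "1|0" = 1,
  "1/1" = 2, "1|1" = 2
)
.GT_MISSING <- c("./.", ".|.", ".", "./0", "0/.")

#' Read a genotype dosage matrix
#'
#' Reads genotypes either from a VCF (using the `DS` dosage FORMAT field when
#' present, otherwise diploid `GT` calls mapped 0/0 -> 0, 0/1 -> 1, 1/1 -> 2,
#' ./. -> NA) or from the package's dosage TSV dialect
#' (`sample_id<TAB>var1<TAB>var2...`, one row per sample, `NA` for missing).
#'
#' @param path path to the input file.
#' @param dialect `"vcf"` or `"dosage_tsv"`.
#' @param variants optional variant metadata data.frame (sidecar table from
#'   [readVariantTable()]) matched to the file's variant ids.
#' @return an [IBDCohort-class] with dosages and computed MAFs (phenotypes
#'   empty; attach with [phenotypes<-]).
#' @export
readGenotypes <- function(path, dialect = c("dosage_tsv", "vcf"), variants = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
    if (anyDuplicated(ids))
      stop("duplicate variant id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
    fmt <- vcf@gt[, "FORMAT"]
    has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
    if (has_ds) {
      d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
      if (any(!is.na(d) & (d < 0 | d > 2))) {
        bad <- which(!is.na(d) & (d < 0 | d > 2), arr.ind = TRUE)[1, ]
        stop(sprintf("dosage outside [0,2] at variant '%s', sample '%s'",
                     ids[bad[1]], colnames(d)[bad[2]]))
      }
    } else {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      tok <- unique(gt[!is.na(gt)])
      unknown <- setdiff(tok, c(names(.GT_MAP), .GT_MISSING))
      if (length(unknown))
        stop("unparseable GT token(s): ", paste(unknown, collapse = ", "))
      d <- matrix(.GT_MAP[gt], nrow = nrow(gt), dimnames = dimnames(gt))
    }
    rownames(d) <- ids
    vmeta <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(tab)[1] != "sample_id")
      stop("dosage TSV must start with a sample_id column")
    vid <- colnames(tab)[-1]
    if (anyDuplicated(vid))
      stop("duplicate variant id: ", paste(unique(vid[duplicated(vid)]), collapse = ", "))
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      suppressWarnings(m2 <- matrix(as.numeric(m), nrow = nrow(m), dimnames = dimnames(m)))
      bad <- is.na(m2) & !(m == "NA" | is.na(m))
      if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1, ]
        stop(sprintf("unparseable dosage '%s' at sample '%s', variant '%s'",
                     m[w[1], w[2]], tab$sample_id[w[1]], vid[w[2]]))
      }
      m <- m2
    }
    out <- !is.na(m) & (m < 0 | m > 2)
    if (any(out)) {
      w <- which(out, arr.ind = TRUE)[1, ]
      stop(sprintf("dosage outside [0,2] (%s) at sample '%s', variant '%s'",
                   m[w[1], w[2]], tab$sample_id[w[1]], vid[w[2]]))
    }
    d <- t(m)
    colnames(d) <- tab$sample_id
    vmeta <- data.frame(id = vid, stringsAsFactors = FALSE)
  }
  if (!is.null(variants)) {
    idx <- match(rownames(d), variants$id)
    if (!anyNA(idx)) {
      extra <- variants[idx, setdiff(colnames(variants), "id"), drop = FALSE]
      vmeta <- cbind(vmeta[, setdiff(colnames(vmeta), colnames(extra)), drop = FALSE], extra)
      vmeta$id <- rownames(d)
    } else {
      warning("variant sidecar does not cover all ids; ignoring it")
    }
  }
  IBDCohort(d, variants = vmeta)
}

#' Write a dosage TSV
#'
#' Writes the dosage TSV dialect read by [readGenotypes()]. Values are written
#' with 17 significant digits so that write-then-read round-trips bit-exactly.
#'
#' @param x an [IBDCohort-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path) {
  d <- dosages(x, samplesInRows = TRUE)
  chr <- matrix(formatC(d, digits = 17, format = "g"), nrow = nrow(d))
  chr[is.na(d)] <- "NA"
  out <- cbind(sample_id = rownames(d), as.data.frame(chr, stringsAsFactors = FALSE))
  colnames(out) <- c("sample_id", colnames(d))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant metadata sidecar TSV
#'
#' Expected columns: `id, chrom, pos, ref, alt, locus_group, is_hla`.
#'
#' @param path path to the TSV.
#' @return data.frame of variant metadata.
#' @export
readVariantTable <- function(path) {
  v <- read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% colnames(v)) stop("variant table must have an id column")
  if ("is_hla" %in% colnames(v)) v$is_hla <- as.logical(v$is_hla)
  if ("locus_group" %in% colnames(v)) {
    bad <- !v$locus_group %in% .LOCUS_GROUPS
    if (any(bad))
      stop("unknown locus_group: ", paste(unique(v$locus_group[bad]), collapse = ", "))
  }
  v
}

## Phenotypes ------------------------------------------------------------------

.checkVocab <- function(x, vocab, column) {
  bad <- !is.na(x) & !x %in% vocab
  if (any(bad))
    stop(sprintf("unknown %s code: %s", column,
                 paste(unique(x[bad]), collapse = ", ")))
  x
}

.asLogicalCol <- function(x, column) {
  if (is.logical(x)) return(x)
  map <- c("TRUE" = TRUE, "FALSE" = FALSE, "1" = TRUE, "0" = FALSE,
           "yes" = TRUE, "no" = FALSE, "Y" = TRUE, "N" = FALSE)
  out <- map[as.character(x)]
  bad <- is.na(out) & !is.na(x) & x != "" & x != "NA"
  if (any(bad))
    stop(sprintf("unknown %s value: %s", column, paste(unique(x[bad]), collapse = ", ")))
  unname(out)
}

#' Validate a Montreal phenotype table
#'
#' Enforces the controlled vocabulary and the Montreal invariants: location and
#' behaviour are defined only for Crohn's disease, extent only for ulcerative
#' colitis, the age band is consistent with age at diagnosis, and event times
#' are nonnegative and bounded by follow-up.
#'
#' @param df phenotype data.frame.
#' @param strict if TRUE, Montreal-invariant violations raise an error; if
#'   FALSE, offending entries are set to NA (hard errors such as
#'   `surgery_time > followup` always raise).
#' @return the validated (possibly nulled) data.frame.
#' @export
validatePhenotypes <- function(df, strict = TRUE) {
  if (!"sample_id" %in% colnames(df)) stop("phenotype table needs sample_id")
  .checkVocab(df$diagnosis, .DIAGNOSIS, "diagnosis")
  if (!is.null(df$location)) .checkVocab(df$location, .LOCATION, "location")
  if (!is.null(df$behaviour)) .checkVocab(df$behaviour, .BEHAVIOUR, "behaviour")
  if (!is.null(df$extent)) .checkVocab(df$extent, .EXTENT, "extent")
  if (!is.null(df$smoking)) .checkVocab(df$smoking, .SMOKING, "smoking")
  if (!is.null(df$sex)) .checkVocab(df$sex, .SEX, "sex")
  if (!is.null(df$age_band)) .checkVocab(df$age_band, .AGEBAND, "age_band")

  notCD <- !is.na(df$diagnosis) & df$diagnosis != "CD"
  notUC <- !is.na(df$diagnosis) & df$diagnosis != "UC"
  cdFields <- intersect(c("location", "behaviour"), colnames(df))
  for (f in cdFields) {
    bad <- notCD & !is.na(df[[f]])
    if (any(bad)) {
      if (strict)
        stop(sprintf("%s recorded for non-CD sample(s): %s", f,
                     paste(head(df$sample_id[bad], 5), collapse = ", ")))
      df[[f]][bad] <- NA
    }
  }
  if ("extent" %in% colnames(df)) {
    bad <- notUC & !is.na(df$extent)
    if (any(bad)) {
      if (strict)
        stop("extent recorded for non-UC sample(s): ",
             paste(head(df$sample_id[bad], 5), collapse = ", "))
      df$extent[bad] <- NA
    }
  }
  if ("age_at_diagnosis" %in% colnames(df)) {
    band <- ageBand(df$age_at_diagnosis)
    if (is.null(df$age_band)) {
      df$age_band <- band
    } else {
      mism <- !is.na(band) & !is.na(df$age_band) & band != df$age_band
      if (any(mism)) {
        if (strict)
          stop("age_band inconsistent with age_at_diagnosis for: ",
               paste(head(df$sample_id[mism], 5), collapse = ", "))
        df$age_band[mism] <- band[mism]
      }
      df$age_band[is.na(df$age_band)] <- band[is.na(df$age_band)]
    }
  }
  if (all(c("surgery_time_years", "followup_years") %in% colnames(df))) {
    st <- df$surgery_time_years; fu <- df$followup_years
    if (any(!is.na(st) & st < 0)) stop("negative surgery_time_years")
    bad <- !is.na(st) & !is.na(fu) & st > fu + 1e-9
    if (any(bad))
      stop("surgery_time_years exceeds followup_years for: ",
           paste(head(df$sample_id[bad], 5), collapse = ", "))
  }
  if ("site" %in% colnames(df) && any(is.na(df$site) | df$site == ""))
    stop("site must be non-empty for every sample")
  df
}

#' Read a Montreal phenotype TSV
#'
#' Columns (all optional except `sample_id` and `diagnosis`):
#' `diagnosis` (CD/UC/IBDU), `location` (L1/L2/L3/OTHER), `upper_gi_L4`,
#' `behaviour` (B1/B2/B3), `perianal`, `extent` (E1/E2/E3/OTHER),
#' `age_at_diagnosis`, `sex`, `smoking` (smoker/ex/never), `family_history`,
#' `year_of_birth`, `site`, `country`, `followup_years`, `surgery_event`,
#' `surgery_time_years`, `diagnosis_revised`. Empty strings and `NA` are
#' treated as missing.
#'
#' @param path path to the TSV.
#' @inheritParams validatePhenotypes
#' @return validated phenotype data.frame.
#' @export
readPhenotypes <- function(path, strict = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  for (col in c("upper_gi_L4", "perianal", "family_history", "surgery_event",
                "diagnosis_revised")) {
    if (col %in% colnames(df)) df[[col]] <- .asLogicalCol(df[[col]], col)
  }
  validatePhenotypes(df, strict = strict)
}

#' Write a phenotype TSV
#' @param df phenotype data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

## Principal components --------------------------------------------------------

#' Genotype principal components
#'
#' Top-k left singular directions of the variant-standardized dosage matrix
#' (missing dosages mean-imputed per variant). Columns are orthonormal and
#' ordered by decreasing singular value; signs are fixed by forcing the
#' largest-magnitude variant loading of each component positive.
#'
#' @param x an [IBDCohort-class] or a samples x variants dosage matrix.
#' @param k number of components (default 5, the usual adjustment set for
#'   population structure).
#' @return data.frame with rownames = sample ids and columns `PC1..PCk`;
#'   attribute `"d"` holds the singular values.
#' @export
computePCs <- function(x, k = 5) {
  m <- if (is(x, "IBDCohort")) dosages(x, samplesInRows = TRUE) else as.matrix(x)
  n <- nrow(m); p <- ncol(m)
  if (k >= min(n, p)) stop("k must be smaller than min(n_samples, n_variants)")
  cm <- colMeans(m, na.rm = TRUE)
  for (j in seq_len(p)) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- cm[j]
  }
  sds <- apply(m, 2, sd)
  keep <- !is.na(sds) & sds > 0
  if (!any(keep)) stop("no polymorphic variants")
  ms <- scale(m[, keep, drop = FALSE])
  sv <- svd(ms, nu = k, nv = k)
  u <- sv$u; v <- sv$v
  for (j in seq_len(k)) {           # deterministic sign: top |loading| positive
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  out <- as.data.frame(u)
  colnames(out) <- paste0("PC", seq_len(k))
  rownames(out) <- rownames(m)
  attr(out, "d") <- sv$d[seq_len(k)]
  out
}

## Cohort summarizer -----------------------------------------------------------

.pctHalfUp <- function(n, denom) {
  if (denom == 0) return(rep(NA_real_, length(n)))
  floor(100 * n / denom + 0.5)
}

.summBlock <- function(values, categories, group_n) {
  counts <- vapply(categories, function(cc) sum(!is.na(values) & values == cc), 0L)
  denom <- sum(counts)
  miss <- group_n - denom
  data.frame(
    category = c(categories, "Missing"),
    n = c(counts, miss),
    pct = c(.pctHalfUp(counts, denom), .pctHalfUp(miss, group_n)),
    stringsAsFactors = FALSE
  )
}

#' Table-1-style cohort summary
#'
#' Counts and integer percentages by diagnosis group for each demographic and
#' Montreal block. Category percentages are computed among non-missing records
#' (OTHER categories included in the denominator); the Missing row is a
#' percentage of the group total. Percentages are rounded half-up.
#'
#' @param P phenotype data.frame (or an [IBDCohort-class]).
#' @return object of class `CohortSummary`: a nested list
#'   `summary[[group]][[block]]` of data.frames with a print method.
#' @export
summarizeCohort <- function(P) {
  if (is(P, "IBDCohort")) P <- phenotypes(P)
  if (nrow(P) == 0) stop("empty phenotype table")
  groups <- list(
    CD = P[!is.na(P$diagnosis) & P$diagnosis == "CD", , drop = FALSE],
    UC = P[!is.na(P$diagnosis) & P$diagnosis == "UC", , drop = FALSE],
    IBD = P
  )
  blockdefs <- list(
    sex = list(col = "sex", cats = .SEX, groups = c("CD", "UC", "IBD")),
    age_band = list(col = "age_band", cats = .AGEBAND, groups = c("CD", "UC", "IBD")),
    family_history = list(col = "family_history", cats = c(TRUE, FALSE),
                          labels = c("yes", "no"), groups = c("CD", "UC", "IBD")),
    smoking = list(col = "smoking", cats = .SMOKING, groups = c("CD", "UC", "IBD")),
    location = list(col = "location", cats = .LOCATION, groups = "CD"),
    upper_gi = list(col = "upper_gi_L4", cats = c(TRUE, FALSE),
                    labels = c("L4", "no_L4"), groups = "CD"),
    behaviour = list(col = "behaviour", cats = .BEHAVIOUR, groups = "CD"),
    extent = list(col = "extent", cats = .EXTENT, groups = "UC"),
    surgery = list(col = "surgery_event", cats = c(TRUE, FALSE),
                   labels = c("yes", "no"), groups = c("CD", "UC"))
  )
  out <- list()
  for (g in names(groups)) {
    gd <- groups[[g]]
    blocks <- list()
    for (b in names(blockdefs)) {
      def <- blockdefs[[b]]
      if (!g %in% def$groups) next
      if (!def$col %in% colnames(gd)) next
      blk <- .summBlock(gd[[def$col]], def$cats, nrow(gd))
      if (!is.null(def$labels))
        blk$category <- c(def$labels, "Missing")
      blocks[[b]] <- blk
    }
    out[[g]] <- blocks
  }
  structure(list(n = vapply(groups, nrow, 0L), blocks = out),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  for (g in names(x$blocks)) {
    cat(sprintf("== %s (n=%d) ==\n", g, x$n[[g]]))
    for (b in names(x$blocks[[g]])) {
      blk <- x$blocks[[g]][[b]]
      cat(" ", b, ": ",
          paste(sprintf("%s %d (%s%%)", blk$category, blk$n,
                        ifelse(is.na(blk$pct), "-", blk$pct)), collapse = ", "),
          "\n", sep = "")
    }
  }
  invisible(x)
}
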