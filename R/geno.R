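## Genotype container and per-locus frequency machinery.
##
## Genotypes are stored as two samples x loci integer matrices of allele
## indices (0 = REF, 1 = first ALT, ...), NA = uncalled allele.  Phased and
## unphased calls are treated identically (allele multiset).  Positions are
## 0-based internally; the printed VCF (1-based) position survives only
## inside the locus id.

new_geno_matrix <- function(samples, loci, a1, a2) {
  stopifnot(is.matrix(a1), is.matrix(a2),
            nrow(a1) == length(samples), ncol(a1) == nrow(loci),
            all(dim(a1) == dim(a2)))
  dimnames(a1) <- dimnames(a2) <- list(samples, loci$locus_id)
  structure(list(samples = samples, loci = loci, a1 = a1, a2 = a2),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$samples), "samples x", nrow(x$loci),
      "loci on", length(unique(x$loci$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$a1) | is.na(x$a2))
  cat(sprintf("  multi-allelic loci: %d; missing call rate: %.3f\n",
              sum(x$loci$n_alleles > 2L), miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(length(x$samples), nrow(x$loci))

#' Read genotypes from a VCF file
#'
#' Reads a VCF 4.x file (plain or bgzipped) into a `geno_matrix`.  One
#' locus is kept per VCF record; multi-allelic records keep all ALT
#' alleles at a single locus.  Missing genotypes (`./.` or `.`) become
#' missing calls.  Internally positions are converted to 0-based.
#'
#' @param path VCF file path.
#' @param sample_subset optional character vector of sample ids to keep;
#'   ids absent from the VCF are an error.
#' @return a `geno_matrix`.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(v@gt) || ncol(v@gt) < 2L)
    stop("VCF has no genotype columns")
  fmt <- v@gt[, "FORMAT"]
  if (any(!grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF record without a GT field in FORMAT")
  samples <- colnames(v@gt)[-1L]
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, samples)
    if (length(missing_s))
      stop("sample(s) not in VCF: ", paste(missing_s, collapse = ", "))
    samples <- sample_subset
  }
  gt <- vcfR::extract.gt(v, element = "GT")  # loci x samples
  gt <- gt[, samples, drop = FALSE]

  chrom <- v@fix[, "CHROM"]
  pos1  <- as.integer(v@fix[, "POS"])
  ref   <- v@fix[, "REF"]
  alt   <- v@fix[, "ALT"]
  alt[is.na(alt)] <- "."
  n_alleles <- 1L + ifelse(alt == ".", 0L,
                           lengths(strsplit(alt, ",", fixed = TRUE)))
  ## at least two alleles per locus: treat ALT="." as a degenerate
  ## monomorphic record and refuse it (cannot define a non-major allele)
  if (any(n_alleles < 2L))
    stop("VCF record with no ALT allele at ",
         chrom[n_alleles < 2L][1L], ":", pos1[n_alleles < 2L][1L])
  loci <- data.frame(
    locus_id = paste(chrom, pos1, ref, alt, sep = ":"),
    chrom = chrom, pos = pos1 - 1L, ref = ref, alt = alt,
    n_alleles = n_alleles, stringsAsFactors = FALSE)

  g <- as.vector(gt)  # column-major: sample blocks of length n_loci
  first  <- sub("^([^/|]*).*$", "\\1", g)
  second <- ifelse(grepl("[/|]", g), sub("^.*[/|]([^/|]*)$", "\\1", g), NA)
  to_idx <- function(tok) {
    tok[is.na(tok) | tok == "." | tok == ""] <- NA
    idx <- suppressWarnings(as.integer(tok))
    if (any(!is.na(tok) & is.na(idx)))
      stop("unparseable GT allele token: ",
           tok[!is.na(tok) & is.na(idx)][1L])
    idx
  }
  n_loci <- nrow(loci)
  a1 <- t(matrix(to_idx(first),  nrow = n_loci))
  a2 <- t(matrix(to_idx(second), nrow = n_loci))
  ok1 <- is.na(a1) | a1 < rep(n_alleles, each = length(samples))
  ok2 <- is.na(a2) | a2 < rep(n_alleles, each = length(samples))
  if (!all(ok1 & ok2))
    stop("GT allele index out of range for its locus")
  new_geno_matrix(samples, loci, a1, a2)
}

#' Read a phenotype file
#'
#' Tab-delimited, no header: `sample_id  status  [covariate ...]` with
#' status coded 0 = control, 1 = case.  Extra columns are kept as numeric
#' covariates.
#'
#' @param path phenotype file path.
#' @return a data frame with columns `sample_id`, `status`, and any
#'   covariates (named `cov1`, `cov2`, ... if unnamed).
#' @export
read_phenotype_file <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs sample_id and status columns")
  names(df)[1:2] <- c("sample_id", "status")
  if (ncol(df) > 2L)
    names(df)[-(1:2)] <- paste0("cov", seq_len(ncol(df) - 2L))
  if (!all(df$status %in% c(0L, 1L)))
    stop("phenotype status must be 0 (control) or 1 (case)")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in phenotype file")
  df
}

## Align a phenotype data frame to a geno_matrix: returns integer status
## vector over gm$samples order (NA for unphenotyped samples) plus index
## vectors of cases and controls.
.align_phenotype <- function(gm, phen) {
  unknown <- setdiff(phen$sample_id, gm$samples)
  if (length(unknown))
    stop("phenotype sample(s) not in genotype data: ",
         paste(unknown, collapse = ", "))
  status <- rep(NA_integer_, length(gm$samples))
  status[match(phen$sample_id, gm$samples)] <- as.integer(phen$status)
  list(status = status,
       cases = which(status == 1L),
       controls = which(status == 0L),
       phenotyped = which(!is.na(status)))
}

## Per-locus allele counts over a row subset: (max alleles) x n_loci matrix,
## count of allele index a-1 in row a.  NA-called alleles do not count.
.allele_count_matrix <- function(gm, rows = seq_along(gm$samples)) {
  K <- max(gm$loci$n_alleles)
  a1 <- gm$a1[rows, , drop = FALSE]
  a2 <- gm$a2[rows, , drop = FALSE]
  out <- matrix(0L, nrow = K, ncol = nrow(gm$loci))
  for (a in seq_len(K) - 1L) {
    out[a + 1L, ] <- colSums(a1 == a, na.rm = TRUE) +
      colSums(a2 == a, na.rm = TRUE)
  }
  out
}

#' Per-allele frequencies at one locus
#'
#' Frequencies are computed from observed (non-missing) allele calls
#' only.  If every call in the subset is missing the locus has no data
#' and a vector of `NA`s is returned.
#'
#' @param gm a `geno_matrix`.
#' @param locus locus id or index.
#' @param subset optional sample ids (default: all samples).
#' @return numeric vector of length `n_alleles` (REF first), summing to 1
#'   when any allele was observed; all-`NA` when the subset has no data.
#' @export
compute_allele_freqs <- function(gm, locus, subset = NULL) {
  j <- if (is.character(locus)) match(locus, gm$loci$locus_id) else locus
  if (is.na(j) || j < 1L || j > nrow(gm$loci)) stop("unknown locus: ", locus)
  rows <- .subset_rows(gm, subset)
  if (!length(rows)) stop("empty sample subset")
  cnt <- .allele_count_matrix(gm, rows)[, j]
  k <- gm$loci$n_alleles[j]
  cnt <- cnt[seq_len(k)]
  tot <- sum(cnt)
  if (tot == 0L) return(rep(NA_real_, k))
  cnt / tot
}

.subset_rows <- function(gm, subset) {
  if (is.null(subset)) return(seq_along(gm$samples))
  if (is.numeric(subset)) return(as.integer(subset))
  rows <- match(subset, gm$samples)
  if (anyNA(rows))
    stop("unknown sample(s): ", paste(subset[is.na(rows)], collapse = ", "))
  rows
}

#' Non-major allele frequency (NMAF)
#'
#' NMAF is 1 minus the frequency of the most common allele at the locus,
#' computed over the given sample subset; for biallelic loci it equals
#' the classical minor allele frequency.  Loci with no observed calls in
#' the subset get `NA` ("no data").
#'
#' @param gm a `geno_matrix`.
#' @param subset optional sample ids or row indices.
#' @param loci optional locus ids or indices (default: all).
#' @return named numeric vector of NMAF values in `[0, (k-1)/k]`.
#' @export
compute_nmaf <- function(gm, subset = NULL, loci = NULL) {
  rows <- .subset_rows(gm, subset)
  cnt <- .allele_count_matrix(gm, rows)
  tot <- colSums(cnt)
  nmaf <- ifelse(tot > 0L, 1 - apply(cnt, 2L, max) / tot, NA_real_)
  names(nmaf) <- gm$loci$locus_id
  if (!is.null(loci)) {
    j <- if (is.character(loci)) match(loci, gm$loci$locus_id) else loci
    if (anyNA(j)) stop("unknown locus id(s)")
    nmaf <- nmaf[j]
  }
  nmaf
}

#' Major allele at each locus
#'
#' The major (most frequent) allele index per locus over a sample
#' subset; ties break toward the lower allele index (REF first) for
#' determinism.  Loci with no data default to the REF allele.
#'
#' @inheritParams compute_nmaf
#' @return integer vector of allele indices (0 = REF).
#' @export
major_alleles <- function(gm, subset = NULL) {
  cnt <- .allele_count_matrix(gm, .subset_rows(gm, subset))
  as.integer(apply(cnt, 2L, which.max)) - 1L
}

#' Encode one genotype call under a disease model
#'
#' Given a call (an unordered allele pair, `NA` for uncalled alleles) and
#' the locus's major allele, the call's contribution to a bin score is
#' derived from `m`, the number of non-major alleles in the call:
#' additive gives `m` (0/1/2), dominant gives `1` if `m >= 1`, recessive
#' gives `1` only for `m == 2`.  Fully or partially missing alleles count
#' as major (a missing genotype contributes 0 under every model).
#'
#' @param call integer vector of length 2: allele indices, `NA` allowed.
#' @param major integer major-allele index for the locus.
#' @param model one of `"additive"`, `"dominant"`, `"recessive"`.
#' @return integer contribution.
#' @export
encode_genotype <- function(call, major,
                            model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  m <- sum(!is.na(call) & call != major)
  switch(model,
         additive = m,
         dominant = as.integer(m >= 1L),
         recessive = as.integer(m == 2L))
}

## Vectorised non-major-allele dosage: samples x loci matrix of encoded
## contributions.  `major` defaults to the full-population major allele,
## fixed once for all downstream encodings.
nonmajor_dosage <- function(gm, model = c("additive", "dominant", "recessive"),
                            major = NULL) {
  model <- match.arg(model)
  if (is.null(major)) major <- major_alleles(gm)
  n <- length(gm$samples)
  mj <- matrix(major, nrow = n, ncol = length(major), byrow = TRUE)
  m1 <- !is.na(gm$a1) & gm$a1 != mj
  m2 <- !is.na(gm$a2) & gm$a2 != mj
  m <- m1 + m2
  out <- switch(model,
                additive = m,
                dominant = (m >= 1L) + 0L,
                recessive = (m == 2L) + 0L)
  dimnames(out) <- list(gm$samples, gm$loci$locus_id)
  out
}
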