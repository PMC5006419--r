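# Fixture builders: everything is generated in code at test time.

# Write a minimal VCF 4.2 with GT-only genotypes.
# gt: samples x loci matrix of GT strings ("0/1", "./.", ...)
write_test_vcf <- function(path, chrom, pos1, ref, alt, gt,
                           samples = paste0("S", seq_len(nrow(gt)))) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  rows <- vapply(seq_along(pos1), function(j) {
    paste(c(chrom[j], pos1[j], ".", ref[j], alt[j], ".", "PASS", ".",
            "GT", gt[, j]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  path
}

write_tsv_lines <- function(lines, path = tempfile()) {
  writeLines(lines, path)
  path
}

# A 5-gene toy dataset with known geometry: 5 genes of 1 kb at
# 10k,20k,...,50k on chr1, two rare loci per gene, plus one locus at
# 75000 outside every gene (one 50 kb intergenic window); 20 samples,
# 10 cases / 10 controls, each rare allele carried by one sample.
toy_dataset <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  genes <- sprintf("GENE_%s", LETTERS[1:5])
  starts <- seq(10000L, 50000L, by = 10000L)
  bed <- file.path(dir, "regions.bed")
  writeLines(sprintf("chr1\t%d\t%d\t%s", starts, starts + 1000L, genes), bed)

  n <- 20L
  pos0 <- c(rbind(starts + 100L, starts + 500L), 75000L)  # 11 loci, 0-based
  gt <- matrix("0/0", n, length(pos0))
  for (j in seq_along(pos0)) gt[((j - 1L) %% n) + 1L, j] <- "0/1"
  vcf <- file.path(dir, "toy.vcf")
  write_test_vcf(vcf, rep("chr1", length(pos0)), pos0 + 1L,
                 rep("A", length(pos0)), rep("G", length(pos0)), gt)

  phen <- file.path(dir, "phenotype.tsv")
  writeLines(sprintf("S%d\t%d", 1:n, rep(c(1L, 0L), each = 10L)), phen)
  list(dir = dir, vcf = vcf, bed = bed, phen = phen,
       genes = genes, n_samples = n)
}

# Random geno_matrix for property tests: biallelic loci, optional
# missingness, via the package constructor.
random_geno <- function(n = 20, k = 10, miss = 0, seed = NULL,
                        chrom = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  q <- runif(k, 0.02, 0.4)
  g <- matrix(rbinom(n * k, 2, rep(q, each = n)), n, k)
  a1 <- (g >= 1) + 0L
  a2 <- (g == 2) + 0L
  if (miss > 0) {
    drop <- matrix(runif(n * k) < miss, n, k)
    a1[drop] <- NA_integer_
    a2[drop] <- NA_integer_
  }
  pos <- sort(sample.int(1e6, k))
  loci <- data.frame(
    locus_id = sprintf("%s:%d:A:G", chrom, pos),
    chrom = chrom, pos = pos - 1L, ref = "A", alt = "G",
    n_alleles = 2L, stringsAsFactors = FALSE)
  rarebin:::new_geno_matrix(sprintf("S%03d", 1:n), loci, a1, a2)
}

random_phenotype <- function(gm, n_cases = floor(length(gm$samples) / 2)) {
  n <- length(gm$samples)
  data.frame(sample_id = gm$samples,
             status = sample(c(rep(1L, n_cases), rep(0L, n - n_cases))),
             stringsAsFactors = FALSE)
}

# Independent enumeration oracle for the two-sided Wilcoxon rank-sum
# test: exhaustive scan of all case/control rank splits.
enumerate_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  mu <- nx * ny / 2
  Ws <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# Independent IRLS logistic regression (Newton scoring written out),
# used as the oracle for the Wald test path.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  mu <- 1 / (1 + exp(-as.vector(X %*% beta)))
  w <- mu * (1 - mu)
  V <- solve(t(X * w) %*% X)
  list(beta = as.vector(beta), se = sqrt(diag(V)))
}
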