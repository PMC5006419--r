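# A small deterministic genotype set for selection tests: 20 samples
# (10 cases, 10 controls), biallelic loci built directly from target
# allele counts in each stratum.
geno_from_counts <- function(case_alt, ctrl_alt, n_per = 10L) {
  k <- length(case_alt)
  fill <- function(m) {          # m alt alleles among n_per diploids
    a1 <- rep(0L, n_per); a2 <- rep(0L, n_per)
    a2[seq_len(min(m, n_per))] <- 1L
    if (m > n_per) a1[seq_len(m - n_per)] <- 1L
    cbind(a1, a2)
  }
  a1 <- matrix(0L, 2L * n_per, k); a2 <- matrix(0L, 2L * n_per, k)
  for (j in seq_len(k)) {
    ca <- fill(case_alt[j]); co <- fill(ctrl_alt[j])
    a1[, j] <- c(ca[, 1], co[, 1]); a2[, j] <- c(ca[, 2], co[, 2])
  }
  pos <- (seq_len(k)) * 1000L
  loci <- data.frame(locus_id = sprintf("chr1:%d:A:G", pos), chrom = "chr1",
                     pos = pos - 1L, ref = "A", alt = "G", n_alleles = 2L,
                     stringsAsFactors = FALSE)
  gm <- rarebin:::new_geno_matrix(sprintf("S%02d", seq_len(2L * n_per)),
                                  loci, a1, a2)
  phen <- data.frame(sample_id = gm$samples,
                     status = rep(c(1L, 0L), each = n_per))
  list(gm = gm, phen = phen)
}

test_that("NMAF selection modes and the strict threshold boundary", {
  # locus 1: case NMAF 0.04 impossible with 20 alleles; use 500/500 design
  d <- geno_from_counts(case_alt = c(1, 2, 6, 1),
                        ctrl_alt = c(2, 1, 6, 1), n_per = 10L)
  # stratum NMAFs (20 alleles each): L1 .05/.10, L2 .10/.05, L3 .30/.30, L4 .05/.05
  ids <- d$gm$loci$locus_id
  expect_equal(select_loci(d$gm, d$phen, 0.08, "either"), sort(ids[c(1, 2, 4)]))
  expect_equal(select_loci(d$gm, d$phen, 0.08, "both"), sort(ids[4]))
  # strict '<': pooled NMAF of L4 is 2/40 = 0.05 exactly
  expect_equal(select_loci(d$gm, d$phen, 0.05, "overall"), character())
  expect_equal(select_loci(d$gm, d$phen, 0.0501, "overall"), sort(ids[4]))
  # 0.30 in both strata excluded under every mode at T = 0.05
  for (m in c("either", "both", "overall"))
    expect_false(ids[3] %in% select_loci(d$gm, d$phen, 0.05, m))
})

test_that("stratified selection requires both strata", {
  d <- geno_from_counts(c(1, 1), c(1, 1))
  all_case <- data.frame(sample_id = d$gm$samples, status = 1L)
  expect_error(select_loci(d$gm, all_case, 0.05, "either"), "case")
  expect_silent(select_loci(d$gm, all_case, 0.05, "overall"))
})

test_that("role filters include, exclude, and compose", {
  roles <- data.frame(locus_id = "L1", role = "damaging")
  expect_equal(apply_role_filter(c("L1", "L2"), roles, "include"), "L1")
  expect_equal(apply_role_filter(c("L1", "L2"), roles, "exclude"), "L2")
  none <- data.frame(locus_id = character(), role = character())
  expect_equal(apply_role_filter(c("L1", "L2"), none, "exclude"),
               c("L1", "L2"))
  inc <- apply_role_filter(c("L1", "L2"), roles, "include")
  expect_equal(apply_role_filter(inc, roles, "exclude"), character())
})

test_that("gene assignment bins loci by containing region", {
  rs <- load_region_file(write_tsv_lines(c(
    "chr1\t0\t5000\tGENE_A", "chr1\t4000\t9000\tGENE_B")))
  kb <- knowledge_base(rs)
  d <- geno_from_counts(rep(1, 10), rep(1, 10))  # loci at pos 999,1999,...,9999
  ids <- d$gm$loci$locus_id
  asg <- assign_loci_to_features(d$gm, ids, kb, "gene")
  expect_equal(vapply(asg$bins, `[[`, "", "bin_id"), c("GENE_A", "GENE_B"))
  # loci 1-5 in A (pos 999..4999), 5-9 in B (4000..8999), locus 10 outside
  expect_equal(asg$bins[[1]]$member_loci, sort(ids[1:5]))
  expect_equal(asg$bins[[2]]$member_loci, sort(ids[5:9]))
  expect_equal(asg$unassigned, sort(ids[10]))
  # the overlap locus (pos 4999) is double-assigned
  expect_true(ids[5] %in% asg$bins[[1]]$member_loci &&
                ids[5] %in% asg$bins[[2]]$member_loci)
})

test_that("group assignment unions loci over the expanded group", {
  rs <- load_region_file(write_tsv_lines(c(
    "chr1\t0\t2500\tGENE_A", "chr1\t2500\t5000\tGENE_B",
    "chr1\t5000\t7500\tGENE_C")))
  gs <- load_group_file(write_tsv_lines(c(
    "PW1\tsrc\tregion\tGENE_A", "PW1\tsrc\tgroup\tPW2",
    "PW2\tsrc\tregion\tGENE_B")), rs)
  kb <- knowledge_base(rs, gs)
  d <- geno_from_counts(rep(1, 10), rep(1, 10))
  ids <- d$gm$loci$locus_id
  asg <- assign_loci_to_features(d$gm, ids, kb, "group")
  expect_equal(vapply(asg$bins, `[[`, "", "bin_id"), c("PW1", "PW2"))
  expect_equal(asg$bins[[1]]$member_loci, sort(ids[1:5]))  # pos < 5000
  expect_equal(asg$bins[[2]]$member_loci, sort(ids[3:5]))  # 2500 <= pos < 5000
  # unassigned means outside every region, even with a group subset
  asg2 <- assign_loci_to_features(d$gm, ids, kb, "group", group_ids = "PW2")
  expect_equal(asg2$unassigned, sort(ids[8:10]))           # pos >= 7500
  expect_error(assign_loci_to_features(d$gm, ids, kb, "group",
                                       group_ids = "NOPE"), "NOPE")
})

test_that("feature membership equals a brute-force interval check", {
  set.seed(21)
  gm <- random_geno(10, 40, seed = 21)
  n_reg <- 12L
  start <- sample.int(9e5, n_reg)
  rs <- load_region_file(write_tsv_lines(
    sprintf("chr1\t%d\t%d\tR%02d", start, start + sample.int(2e5, n_reg),
            seq_len(n_reg))))
  kb <- knowledge_base(rs)
  asg <- assign_loci_to_features(gm, gm$loci$locus_id, kb, "gene")
  for (bin in asg$bins) {
    r <- rs[rs$region_id == bin$bin_id, ]
    inside <- gm$loci$locus_id[gm$loci$pos >= r$start & gm$loci$pos < r$stop]
    expect_equal(bin$member_loci, sort(inside))
  }
  in_any <- gm$loci$locus_id[vapply(seq_len(40), function(j)
    any(rs$start <= gm$loci$pos[j] & gm$loci$pos[j] < rs$stop), TRUE)]
  expect_equal(asg$unassigned, sort(setdiff(gm$loci$locus_id, in_any)))
})

test_that("intergenic windows use floor division on position", {
  loci <- data.frame(
    locus_id = c("chr1:123457:A:G", "chr1:10002:A:G", "chr1:50000:A:G",
                 "chr2:10002:A:G"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(123456L, 10001L, 49999L, 10001L),
    ref = "A", alt = "G", n_alleles = 2L, stringsAsFactors = FALSE)
  gm <- rarebin:::new_geno_matrix(paste0("S", 1:2), loci,
                                  matrix(0L, 2, 4), matrix(0L, 2, 4))
  bins <- make_intergenic_bins(gm, loci$locus_id, width_kb = 50)
  ids <- vapply(bins, `[[`, "", "bin_id")
  expect_setequal(ids, c("chr1:100000-150000", "chr1:0-50000",
                         "chr2:0-50000"))
  # pos 123456 -> window 2 = [100000, 150000)
  b <- bins[[which(ids == "chr1:100000-150000")]]
  expect_equal(b$member_loci, "chr1:123457:A:G")
  # 10001 and 49999 share window 0 on chr1; chr2 locus is separate
  b0 <- bins[[which(ids == "chr1:0-50000")]]
  expect_setequal(b0$member_loci, c("chr1:10002:A:G", "chr1:50000:A:G"))
  expect_equal(make_intergenic_bins(gm, character(), 50), list())
})

test_that("Madsen-Browning weights match the closed form", {
  # 500 cases + 500 controls, 4 non-major alleles in controls
  d <- geno_from_counts(case_alt = 10, ctrl_alt = 4, n_per = 500L)
  w <- compute_weights(d$gm, d$phen, d$gm$loci$locus_id, "control")
  expect_equal(w$q, 5 / 1002, tolerance = 1e-12)
  expect_equal(w$n, 1000)
  expect_equal(w$w, 1 / sqrt(1000 * (5 / 1002) * (1 - 5 / 1002)),
               tolerance = 1e-12)
  expect_equal(round(w$w, 4), 0.4488)
  # scheme none: all weights exactly 1
  wn <- compute_weights(d$gm, d$phen, d$gm$loci$locus_id, "none")
  expect_identical(wn$w, 1)
})

test_that("identical strata collapse all population schemes", {
  d <- geno_from_counts(case_alt = c(3, 7), ctrl_alt = c(3, 7), n_per = 50L)
  ids <- d$gm$loci$locus_id
  ws <- lapply(c("control", "minimum", "maximum"), function(s)
    compute_weights(d$gm, d$phen, ids, s)$w)
  expect_equal(ws[[1]], ws[[2]])
  expect_equal(ws[[1]], ws[[3]])
  # overall uses pooled counts, which differ from stratum counts via the
  # pseudo-count, but strata coincide with each other
})

test_that("weight sandwich and monotonicity in q", {
  set.seed(31)
  gm <- random_geno(60, 15, seed = 31)
  phen <- random_phenotype(gm)
  ids <- gm$loci$locus_id
  wmin <- compute_weights(gm, phen, ids, "minimum")$w
  wmax <- compute_weights(gm, phen, ids, "maximum")$w
  expect_true(all(wmin <= wmax))
  # with a common estimation denominator the pooled-frequency weight is
  # sandwiched between the stratum weights (monotonicity of w in q)
  wq <- function(q, n = 200) 1 / sqrt(n * q * (1 - q))
  q1 <- runif(50, 0.001, 0.5); q2 <- runif(50, 0.001, 0.5)
  qbar <- (q1 + q2) / 2
  expect_true(all(wq(qbar) >= pmin(wq(q1), wq(q2)) - 1e-12))
  expect_true(all(wq(qbar) <= pmax(wq(q1), wq(q2)) + 1e-12))
  # w(q) strictly decreasing on (0, 0.5) at fixed n
  q <- seq(0.01, 0.49, by = 0.01)
  w <- 1 / sqrt(100 * q * (1 - q))
  expect_true(all(diff(w) < 0))
})

test_that("custom weights look up the table, defaulting to 1", {
  d <- geno_from_counts(c(1, 2), c(2, 1))
  tbl <- data.frame(locus_id = d$gm$loci$locus_id[1], weight = 2.5)
  w <- compute_weights(d$gm, d$phen, d$gm$loci$locus_id, "custom",
                       custom = tbl)
  expect_equal(w$w, c(2.5, 1))
  expect_error(compute_weights(d$gm, d$phen, d$gm$loci$locus_id, "custom"),
               "weight table")
})

test_that("bin scores are weighted dosage sums", {
  # sample het at two loci, weights 1.0 and 0.5, additive -> 1.5
  d <- geno_from_counts(case_alt = c(1, 1), ctrl_alt = c(0, 0))
  ids <- d$gm$loci$locus_id
  bins <- list(rarebin:::new_bin("B1", "gene", ids, "B1"))
  w <- data.frame(locus_id = ids, q = 0.1, n = 20, w = c(1, 0.5))
  # make S01 het at both loci
  gm <- d$gm
  gm$a2[1, 1:2] <- 1L
  bsm <- score_bins(bins, gm, "additive", w)
  expect_equal(unname(bsm$scores["S01", "B1"]), 1.5)
  # all-reference sample scores 0
  expect_equal(unname(bsm$scores["S20", "B1"]), 0)
  expect_equal(bsm$bins$capacity, 4L)
  expect_error(score_bins(bins, gm, "additive", w[1, ]), "without a weight")
})

test_that("score_bins equals a naive double loop on random fixtures", {
  set.seed(77)
  gm <- random_geno(20, 10, miss = 0.1, seed = 77)
  ids <- gm$loci$locus_id
  bins <- list(rarebin:::new_bin("B1", "gene", ids[1:4], "B1"),
               rarebin:::new_bin("B2", "gene", ids[3:10], "B2"))
  w <- data.frame(locus_id = ids, q = 0.1, n = 20, w = runif(10, 0.2, 3))
  major <- major_alleles(gm)
  for (model in c("additive", "dominant", "recessive")) {
    bsm <- score_bins(bins, gm, model, w)
    for (b in 1:2) {
      for (i in 1:20) {
        acc <- 0
        for (lid in bins[[b]]$member_loci) {
          j <- match(lid, ids)
          acc <- acc + w$w[j] *
            encode_genotype(c(gm$a1[i, j], gm$a2[i, j]), major[j], model)
        }
        expect_equal(unname(bsm$scores[i, b]), acc)
      }
    }
  }
  # scheme none + additive gives the integer non-major allele count
  phen <- random_phenotype(gm)
  wn <- compute_weights(gm, phen, ids, "none")
  bsm <- score_bins(bins, gm, "additive", wn)
  expect_true(all(bsm$scores == round(bsm$scores)))
  expect_true(all(bsm$scores <= 2 * rep(bsm$bins$n_loci, each = 20)))
})

test_that("bin reports round-trip through TSV", {
  gm <- random_geno(5, 6, seed = 13)
  ids <- gm$loci$locus_id
  bins <- list(rarebin:::new_bin("B1", "gene", ids[1:3], "B1"),
               rarebin:::new_bin("B2", "intergenic", ids[4:6], "B2"))
  w <- data.frame(locus_id = ids, q = 0.1, n = 5, w = runif(6))
  bsm <- score_bins(bins, gm, "additive", w)
  prefix <- tempfile()
  paths <- write_bin_report(bsm, prefix)
  sc <- read.table(paths["scores"], header = TRUE, sep = "\t",
                   check.names = FALSE)
  expect_equal(nrow(sc), 5L)             # header + one row per sample
  expect_equal(as.matrix(sc[, -1]), unname(bsm$scores),
               ignore_attr = TRUE, tolerance = 1e-9)
  info <- read.table(paths["bins"], header = TRUE, sep = "\t")
  expect_equal(info$n_loci, c(3L, 3L))
  expect_equal(info$level, c("gene", "intergenic"))
})
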