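## Simulation harness: case-control sequence data under a documented
## generative model (Hardy-Weinberg genotypes over a rare-skewed site
## frequency spectrum, logistic disease model with prevalence-calibrated
## intercept), and the type I error / power studies over the weighting
## schemes and burden tests.

#' Simulation study configuration
#'
#' Bundles the parameters of a type I error or power study.  Defaults
#' match the reference study design: 500 cases and 500 controls, 5%
#' disease prevalence, gene-sized bins of Normal(50, 5) variants
#' (xl_gene: Normal(200, 5); pathway: 2-50 concatenated gene-sized
#' sub-bins), NMAF threshold 0.05, 10 causal variants under the
#' alternative, 1000 replicates.
#'
#' @param n_cases,n_controls sample counts.
#' @param prevalence population disease probability in (0, 1).
#' @param bin_kind `"gene"`, `"xl_gene"`, or `"pathway"`.
#' @param n_variants_mean,n_variants_sd bin-size distribution
#'   (Normal, rounded, truncated at `n_causal + 1`); the mean defaults
#'   by `bin_kind` (gene 50, xl_gene 200).
#' @param n_causal causal variant count under the alternative.
#' @param odds_ratio per-causal-allele odds ratio (1 = null).
#' @param maf_bounds bounds `(a, b)` of the default frequency spectrum,
#'   density proportional to `1/q` on `[a, b]`.
#' @param maf_empirical optional numeric vector of allele frequencies
#'   sampled with replacement instead of the analytic spectrum.
#' @param threshold,nmaf_mode NMAF selection threshold and mode (see
#'   [select_loci()]).
#' @param schemes weighting schemes to evaluate.
#' @param tests burden tests to run.
#' @param n_sims replicate count.
#' @param seed RNG seed (all study randomness flows from it).
#' @param restrict_causal_rare if `TRUE`, causal variants are drawn only
#'   from loci with spectrum frequency below `threshold`, so every
#'   disease site survives selection.
#' @param alpha per-bin significance level used for rejection rates.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 500, n_controls = 500,
                              prevalence = 0.05,
                              bin_kind = c("gene", "xl_gene", "pathway"),
                              n_variants_mean = NULL, n_variants_sd = 5,
                              n_causal = 10, odds_ratio = 1,
                              maf_bounds = c(5e-4, 0.5),
                              maf_empirical = NULL,
                              threshold = 0.05,
                              nmaf_mode = c("either", "overall", "both"),
                              schemes = c("none", "control", "minimum",
                                          "maximum", "overall"),
                              tests = c("logistic", "wilcoxon"),
                              n_sims = 1000, seed = 1,
                              restrict_causal_rare = FALSE,
                              alpha = 0.05) {
  bin_kind <- match.arg(bin_kind)
  nmaf_mode <- match.arg(nmaf_mode)
  schemes <- match.arg(schemes, c("none", "control", "minimum",
                                  "maximum", "overall"), several.ok = TRUE)
  tests <- match.arg(tests, c("logistic", "wilcoxon"), several.ok = TRUE)
  if (is.null(n_variants_mean))
    n_variants_mean <- switch(bin_kind, gene = 50, xl_gene = 200, pathway = 50)
  stopifnot(prevalence > 0, prevalence < 1, odds_ratio >= 1,
            n_cases >= 1, n_controls >= 1, n_sims >= 0,
            threshold > 0, threshold < 1,
            length(maf_bounds) == 2, maf_bounds[1] > 0,
            maf_bounds[2] <= 0.5, maf_bounds[1] < maf_bounds[2])
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 prevalence = prevalence, bin_kind = bin_kind,
                 n_variants_mean = n_variants_mean,
                 n_variants_sd = n_variants_sd,
                 n_causal = n_causal, odds_ratio = odds_ratio,
                 maf_bounds = maf_bounds, maf_empirical = maf_empirical,
                 threshold = threshold, nmaf_mode = nmaf_mode,
                 schemes = schemes, tests = tests,
                 n_sims = n_sims, seed = seed,
                 restrict_causal_rare = restrict_causal_rare,
                 alpha = alpha),
            class = "simulation_config")
}

#' Draw allele frequencies from the site frequency spectrum
#'
#' Default spectrum: density proportional to `1/q` on `[a, b]`
#' (rare-skewed, neutral-like), sampled by inverse CDF
#' `q = a (b/a)^u` with `u ~ Uniform(0, 1)`; the CDF is
#' `log(q/a) / log(b/a)`.  Alternatively an empirical frequency vector
#' (e.g. parsed from a reference panel) is resampled with replacement.
#'
#' @param k number of frequencies to draw (>= 1).
#' @param bounds spectrum bounds `(a, b)`, `0 < a < b <= 0.5`.
#' @param empirical optional numeric frequency vector to resample.
#' @return numeric vector of `k` frequencies.
#' @export
sample_maf_spectrum <- function(k, bounds = c(5e-4, 0.5), empirical = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (!is.null(empirical)) {
    if (!length(empirical) || any(empirical <= 0 | empirical > 0.5))
      stop("empirical frequencies must lie in (0, 0.5]")
    return(sample(empirical, k, replace = TRUE))
  }
  a <- bounds[1]; b <- bounds[2]
  if (!(a > 0 && b <= 0.5 && a < b)) stop("invalid spectrum bounds")
  a * (b / a)^runif(k)
}

## Raw Hardy-Weinberg dosage matrix: n samples x k loci of Binomial(2, q)
## alternate-allele counts.
.sim_dosage <- function(freqs, n) {
  k <- length(freqs)
  matrix(rbinom(n * k, 2L, rep(freqs, each = n)), nrow = n, ncol = k)
}

## Wrap a dosage matrix as a geno_matrix (biallelic synthetic loci laid
## out every 500 bp on one synthetic chromosome).
.dosage_to_geno <- function(G, chrom = "sim1", start = 0L, spacing = 500L) {
  n <- nrow(G); k <- ncol(G)
  pos <- start + spacing * (seq_len(k) - 1L)
  loci <- data.frame(
    locus_id = sprintf("%s:%d:A:T", chrom, pos + 1L),
    chrom = chrom, pos = pos, ref = "A", alt = "T",
    n_alleles = 2L, stringsAsFactors = FALSE)
  a1 <- (G >= 1L) + 0L
  a2 <- (G == 2L) + 0L
  new_geno_matrix(sprintf("S%04d", seq_len(n)), loci, a1, a2)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Independent biallelic loci; each sample's alternate-allele count at a
#' locus with frequency `q` is `Binomial(2, q)`.  No missingness, no
#' linkage disequilibrium.
#'
#' @param freqs per-locus alternate allele frequencies, all in (0, 1).
#' @param n sample count.
#' @return a `geno_matrix` of synthetic loci.
#' @export
simulate_genotypes <- function(freqs, n) {
  if (any(freqs <= 0 | freqs >= 1)) stop("frequencies must be in (0, 1)")
  .dosage_to_geno(.sim_dosage(freqs, n))
}

## Intercept alpha such that E[plogis(alpha + beta * burden)] equals the
## prevalence, where burden is a sum of independent Binomial(2, q_j)
## causal counts (exact pmf by convolution; root found to 1e-10).
.solve_intercept <- function(q_causal, beta, prevalence) {
  if (!length(q_causal) || beta == 0) return(qlogis(prevalence))
  pmf <- 1
  for (q in q_causal)
    pmf <- convolve(pmf, rev(c((1 - q)^2, 2 * q * (1 - q), q^2)),
                    type = "open")
  pmf[pmf < 0] <- 0
  s <- seq_along(pmf) - 1
  f <- function(alpha) sum(pmf * plogis(alpha + beta * s)) - prevalence
  uniroot(f, c(-80, 80), tol = 1e-10)$root
}

#' Assign case/control status under the logistic disease model
#'
#' Each individual's disease probability is
#' `plogis(alpha + log(OR) * burden)`, where `burden` is the non-major
#' allele count over the causal loci and `alpha` is calibrated so the
#' population prevalence equals `config$prevalence` (with no causal
#' variants, `alpha = qlogis(prevalence)`).  Individuals in the supplied
#' pool are scanned in order until exactly `n_cases` cases and
#' `n_controls` controls have been collected; a pool too small to supply
#' them is an error.
#'
#' @param gm a `geno_matrix` pool (typically much larger than
#'   `n_cases + n_controls`).
#' @param config a [simulation_config()].
#' @param causal_ids locus ids of the causal variants (empty under the
#'   null).  Calibration uses the pool's observed allele frequencies at
#'   those loci.
#' @return a phenotype data frame (`sample_id`, `status`) for the
#'   selected individuals.
#' @export
assign_phenotypes <- function(gm, config, causal_ids = character()) {
  stopifnot(inherits(config, "simulation_config"))
  j <- match(causal_ids, gm$loci$locus_id)
  if (anyNA(j)) stop("causal id(s) not in genotype data")
  beta <- log(config$odds_ratio)
  if (length(j)) {
    dos <- nonmajor_dosage(gm, "additive")[, j, drop = FALSE]
    burden <- rowSums(dos)
    q <- colSums(dos) / (2 * nrow(dos))
    alpha <- .solve_intercept(q, beta, config$prevalence)
  } else {
    burden <- rep(0, length(gm$samples))
    alpha <- qlogis(config$prevalence)
  }
  status <- rbinom(length(burden), 1L, plogis(alpha + beta * burden))
  case_rows <- which(status == 1L)
  ctrl_rows <- which(status == 0L)
  if (length(case_rows) < config$n_cases ||
      length(ctrl_rows) < config$n_controls)
    stop("pool exhausted before reaching ", config$n_cases, " cases and ",
         config$n_controls, " controls (drew ", length(case_rows),
         " cases, ", length(ctrl_rows), " controls)")
  keep <- c(case_rows[seq_len(config$n_cases)],
            ctrl_rows[seq_len(config$n_controls)])
  data.frame(sample_id = gm$samples[keep],
             status = c(rep(1L, config$n_cases),
                        rep(0L, config$n_controls)),
             stringsAsFactors = FALSE)
}

## ---- internal study engine -------------------------------------------

## Draw one bin size.  Gene-like kinds: Normal(mean, sd) rounded,
## truncated at n_causal + 1 (and at 2); pathway: 2-50 concatenated
## gene-sized sub-bins.
.draw_bin_size <- function(config) {
  lo <- as.integer(max(2, config$n_causal + 1))
  draw1 <- function(mean) max(lo, as.integer(round(rnorm(1, mean,
                                                         config$n_variants_sd))))
  if (config$bin_kind == "pathway") {
    n_sub <- sample(2:50, 1L)
    sum(vapply(seq_len(n_sub), function(i) draw1(config$n_variants_mean), 1L))
  } else {
    draw1(config$n_variants_mean)
  }
}

## Score one simulated bin under every scheme and test it with every
## requested test.  G: n x k alternate-allele dosage; status: 0/1 vector.
## Returns list(p = matrix schemes x tests, size = selected locus count).
.bin_test_all <- function(G, status, config) {
  n <- nrow(G)
  case <- which(status == 1L); ctrl <- which(status == 0L)
  f_all <- colSums(G) / (2 * n)
  M <- G
  flip <- f_all > 0.5            # major allele is the alternate: recount
  if (any(flip)) M[, flip] <- 2L - M[, flip, drop = FALSE]

  f_case <- colSums(M[case, , drop = FALSE]) / (2 * length(case))
  f_ctrl <- colSums(M[ctrl, , drop = FALSE]) / (2 * length(ctrl))
  nm_case <- pmin(f_case, 1 - f_case)
  nm_ctrl <- pmin(f_ctrl, 1 - f_ctrl)
  nm_all <- pmin(colSums(M) / (2 * n), 1 - colSums(M) / (2 * n))
  sel <- switch(config$nmaf_mode,
                either = pmin(nm_case, nm_ctrl) < config$threshold,
                both = pmax(nm_case, nm_ctrl) < config$threshold,
                overall = nm_all < config$threshold)

  p <- matrix(NA_real_, length(config$schemes), length(config$tests),
              dimnames = list(config$schemes, config$tests))
  size <- sum(sel)
  if (size == 0L) return(list(p = p, size = 0L))
  Msel <- M[, sel, drop = FALSE]
  m_ctrl <- colSums(Msel[ctrl, , drop = FALSE])
  m_case <- colSums(Msel[case, , drop = FALSE])
  w_ctrl <- mb_weight(m_ctrl, length(ctrl), n)$w
  w_case <- mb_weight(m_case, length(case), n)$w
  w_all <- mb_weight(m_ctrl + m_case, n, n)$w

  for (sc in config$schemes) {
    w <- switch(sc,
                none = rep(1, size),
                control = w_ctrl,
                minimum = pmin(w_ctrl, w_case),
                maximum = pmax(w_ctrl, w_case),
                overall = w_all)
    score <- as.vector(Msel %*% w)
    for (tst in config$tests) {
      if (tst == "logistic") {
        res <- .wald_logistic(score, status)
        p[sc, tst] <- if (is.character(res)) NA_real_ else res[["p"]]
      } else {
        if (var(score) > 0)
          p[sc, tst] <- .wilcoxon_p(score[case], score[ctrl])$p
      }
    }
  }
  list(p = p, size = size)
}

## One null replicate (OR = 1): status independent of genotype, so the
## case/control sample can be generated directly at the target counts.
.null_replicate <- function(config) {
  k <- .draw_bin_size(config)
  freqs <- sample_maf_spectrum(k, config$maf_bounds, config$maf_empirical)
  n <- config$n_cases + config$n_controls
  G <- .sim_dosage(freqs, n)
  status <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  .bin_test_all(G, status, config)
}

## One alternative replicate: causal genotypes are generated in batches
## and individuals retained by their disease status (rejection sampling);
## neutral genotypes, independent of status, are generated only for the
## retained individuals.
.alt_replicate <- function(config, generation_cap = 1e7) {
  k <- .draw_bin_size(config)
  for (try in 1:100) {
    freqs <- sample_maf_spectrum(k, config$maf_bounds, config$maf_empirical)
    eligible <- if (config$restrict_causal_rare)
      which(freqs < config$threshold) else seq_len(k)
    if (length(eligible) >= config$n_causal) break
    if (try == 100) stop("could not draw ", config$n_causal,
                         " eligible causal loci")
  }
  causal <- sort(sample(eligible, config$n_causal))
  beta <- log(config$odds_ratio)
  alpha <- .solve_intercept(freqs[causal], beta, config$prevalence)

  need_case <- config$n_cases; need_ctrl <- config$n_controls
  got_case <- got_ctrl <- NULL
  generated <- 0L
  batch <- as.integer(ceiling((need_case + need_ctrl) / config$prevalence / 4))
  while (need_case > 0L || need_ctrl > 0L) {
    if (generated >= generation_cap)
      stop("generation cap reached before filling case/control quota")
    b <- min(batch, as.integer(generation_cap - generated))
    Gc <- .sim_dosage(freqs[causal], b)
    generated <- generated + b
    pr <- plogis(alpha + beta * rowSums(Gc))
    st <- rbinom(b, 1L, pr)
    if (need_case > 0L) {
      rows <- which(st == 1L)
      take <- rows[seq_len(min(length(rows), need_case))]
      got_case <- rbind(got_case, Gc[take, , drop = FALSE])
      need_case <- need_case - length(take)
    }
    if (need_ctrl > 0L) {
      rows <- which(st == 0L)
      take <- rows[seq_len(min(length(rows), need_ctrl))]
      got_ctrl <- rbind(got_ctrl, Gc[take, , drop = FALSE])
      need_ctrl <- need_ctrl - length(take)
    }
  }
  n <- config$n_cases + config$n_controls
  G <- matrix(0L, n, k)
  G[, causal] <- rbind(got_case, got_ctrl)
  neutral <- setdiff(seq_len(k), causal)
  if (length(neutral))
    G[, neutral] <- .sim_dosage(freqs[neutral], n)
  status <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  out <- .bin_test_all(G, status, config)
  out$causal_freqs <- freqs[causal]
  out
}

.collect_study <- function(config, replicate_fun) {
  n_s <- length(config$schemes); n_t <- length(config$tests)
  pvals <- array(NA_real_, c(config$n_sims, n_s, n_t),
                 dimnames = list(NULL, config$schemes, config$tests))
  sizes <- integer(config$n_sims)
  for (r in seq_len(config$n_sims)) {
    rep_ <- replicate_fun(config)
    pvals[r, , ] <- rep_$p
    sizes[r] <- rep_$size
  }
  rates <- expand.grid(scheme = config$schemes, test = config$tests,
                       stringsAsFactors = FALSE)
  rates$rate <- NA_real_; rates$se <- NA_real_
  for (i in seq_len(nrow(rates))) {
    p <- pvals[, rates$scheme[i], rates$test[i]]
    rej <- !is.na(p) & p < config$alpha
    rates$rate[i] <- mean(rej)
    rates$se[i] <- sqrt(rates$rate[i] * (1 - rates$rate[i]) / config$n_sims)
  }
  rates$n_sims <- config$n_sims
  list(rates = rates, pvals = pvals, sizes = sizes)
}

#' Type I error study
#'
#' Per replicate: draw a bin size for the configured bin kind, draw
#' allele frequencies from the spectrum, simulate Hardy-Weinberg
#' genotypes for the case/control sample (status is independent of
#' genotype under the null, odds ratio 1), select loci below the NMAF
#' threshold, collapse the bin under every weighting scheme, and test
#' with every requested test.  The type I error of a scheme x test cell
#' is the fraction of replicates with `p < alpha`.
#'
#' @param config a [simulation_config()] with `odds_ratio = 1`.
#' @return a `sim_result`: rejection-rate table (`scheme`, `test`,
#'   `rate`, `se`, `n_sims`), per-replicate p-value array, and selected
#'   bin sizes.
#' @export
run_type1_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$odds_ratio != 1)
    stop("type I error study requires odds_ratio = 1")
  set.seed(config$seed)
  out <- .collect_study(config, .null_replicate)
  structure(c(out, list(config = config, kind = "type1")),
            class = "sim_result")
}

#' Power study over an odds-ratio sweep
#'
#' Per replicate and odds ratio: a gene-sized bin is simulated with
#' `n_causal` causal loci drawn uniformly from the bin (optionally
#' restricted to spectrum frequency below the selection threshold),
#' disease status follows the prevalence-calibrated logistic model, and
#' the bin is selected, collapsed, and tested as in the type I error
#' study.  Power is the fraction of replicates with `p < alpha`.
#'
#' @param config a [simulation_config()]; `odds_ratio` is overridden by
#'   the sweep values.
#' @param or_values odds ratios to sweep (default: the standard
#'   1.25-5 grid).
#' @return a `sim_result` whose `rates` table has one row per
#'   `odds_ratio` x `scheme` x `test`.
#' @export
run_power_study <- function(config,
                            or_values = c(1.25, 1.5, 1.75, 2, 2.5, 3, 4, 5)) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_causal < 1) stop("power study requires n_causal >= 1")
  if (config$n_causal >= config$n_variants_mean)
    stop("n_causal must be below the mean bin size")
  set.seed(config$seed)
  all_rates <- list(); all_p <- list(); all_sizes <- list()
  for (or in or_values) {
    cfg <- config
    cfg$odds_ratio <- or
    out <- .collect_study(cfg, if (or == 1) .null_replicate else .alt_replicate)
    out$rates <- cbind(odds_ratio = or, out$rates)
    all_rates[[length(all_rates) + 1L]] <- out$rates
    all_p[[as.character(or)]] <- out$pvals
    all_sizes[[as.character(or)]] <- out$sizes
  }
  structure(list(rates = do.call(rbind, all_rates), pvals = all_p,
                 sizes = all_sizes, config = config, kind = "power"),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result (", x$kind, " study): ", x$config$n_sims,
      " replicates, bin kind '", x$config$bin_kind, "'\n", sep = "")
  tab <- x$rates
  tab$rate <- sprintf("%.3f", tab$rate)
  tab$se <- sprintf("%.4f", tab$se)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Regression of p-values on bin size
#'
#' Quantifies whether larger bins are more prone to false positives:
#' a fractional-response (quasi-binomial) regression of the replicate
#' p-values on the replicate bin sizes.  For a well-calibrated scheme
#' the slope is indistinguishable from zero; for control-only weighting
#' it is strongly negative (bigger bins, smaller null p-values).
#'
#' @param pvals per-replicate p-values in `[0, 1]`.
#' @param sizes per-replicate selected locus counts.
#' @return list with `slope`, `se`, `p`.
#' @export
bin_size_bias_regression <- function(pvals, sizes) {
  ok <- !is.na(pvals) & !is.na(sizes)
  pvals <- pvals[ok]; sizes <- sizes[ok]
  if (length(pvals) < 10) stop("need at least 10 replicates")
  if (length(unique(sizes)) < 2) stop("bin size is constant")
  fit <- glm(pvals ~ sizes, family = quasibinomial())
  co <- summary(fit)$coefficients["sizes", ]
  list(slope = unname(co[1]), se = unname(co[2]), p = unname(co[4]))
}
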