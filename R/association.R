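## Burden association tests on collapsed bin scores: logistic regression
## (Wald test on the score coefficient) and the Wilcoxon rank-sum test.

.assoc_row <- function(bin_id, test, statistic, p_value, reason,
                       n_loci, n_cases, n_controls) {
  data.frame(bin_id = bin_id, test = test,
             statistic = statistic, p_value = p_value, reason = reason,
             n_loci = n_loci, n_cases = n_cases, n_controls = n_controls,
             stringsAsFactors = FALSE)
}

## Wald z test on the score coefficient via glm.fit (fast path used
## thousands of times per simulation study).  Returns c(beta, z, p) or a
## reason string.
.wald_logistic <- function(score, status, covariates = NULL) {
  if (length(score) != length(status))
    stop("score and status lengths differ")
  if (var(score) == 0) return("degenerate")
  X <- cbind(`(Intercept)` = 1, score = score, covariates)
  fit <- suppressWarnings(glm.fit(X, status, family = binomial()))
  if (!fit$converged || fit$boundary) return("nonconverged")
  beta <- fit$coefficients[["score"]]
  ## detect (quasi-)separation: the standardised slope diverges
  if (!is.finite(beta) || abs(beta) * stats::sd(score) > 10)
    return("nonconverged")
  p1 <- seq_len(fit$rank)
  pos <- which(fit$qr$pivot[p1] == 2L)  # column of the score coefficient
  if (!length(pos)) return("nonconverged")
  cov_unscaled <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- sqrt(cov_unscaled[pos, pos])
  if (!is.finite(se) || se <= 0) return("nonconverged")
  z <- beta / se
  c(beta = beta, z = z, p = 2 * pnorm(-abs(z)))
}

#' Logistic-regression burden test
#'
#' Fits case/control status on the bin score (plus optional covariates)
#' by logistic regression and reports the Wald test of the score
#' coefficient.  Constant scores give an undefined result with reason
#' `"degenerate"`; non-convergence or separation gives reason
#' `"nonconverged"`.
#'
#' @param scores numeric per-sample bin scores.
#' @param phen phenotype data frame whose sample order matches `scores`
#'   (alternatively a 0/1 status vector).
#' @param covariates optional numeric matrix/data frame of per-sample
#'   covariates.
#' @param bin_id,n_loci metadata carried into the result row.
#' @return one-row data frame: `bin_id`, `test`, `statistic` (Wald z),
#'   `p_value`, `reason`, `n_loci`, `n_cases`, `n_controls`.
#' @export
logistic_burden_test <- function(scores, phen, covariates = NULL,
                                 bin_id = NA_character_, n_loci = NA_integer_) {
  status <- if (is.data.frame(phen)) as.integer(phen$status) else as.integer(phen)
  if (length(scores) != length(status))
    stop("scores and phenotype lengths differ")
  if (!any(status == 1L) || !any(status == 0L))
    stop("need at least one case and one control")
  cv <- if (is.null(covariates)) NULL else as.matrix(covariates)
  res <- .wald_logistic(scores, status, cv)
  if (is.character(res)) {
    return(.assoc_row(bin_id, "logistic", NA_real_, NA_real_, res,
                      n_loci, sum(status == 1L), sum(status == 0L)))
  }
  .assoc_row(bin_id, "logistic", unname(res["z"]), unname(res["p"]), "",
             n_loci, sum(status == 1L), sum(status == 0L))
}

## Two-sided Wilcoxon rank-sum p-value with midranks.  Exact null
## distribution (stats::pwilcox) when both groups are small and there are
## no ties; normal approximation with tie correction otherwise.
.wilcoxon_p <- function(x, y, exact_max = 10L) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U for x
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && min(nx, ny) <= exact_max) {
    if (W > nx * ny / 2) {
      p <- 2 * (1 - pwilcox(W - 1, nx, ny))
    } else {
      p <- 2 * pwilcox(W, nx, ny)
    }
    return(list(W = W, p = min(1, p), exact = TRUE))
  }
  mu <- nx * ny / 2
  sigma2 <- nx * ny / 12 *
    ((nx + ny + 1) - sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
  if (sigma2 <= 0) return(list(W = W, p = NA_real_, exact = FALSE))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)  # continuity correction
  list(W = W, p = 2 * pnorm(-abs(z)), exact = FALSE)
}

#' Wilcoxon rank-sum burden test
#'
#' Two-sided rank-sum test of case versus control bin scores, with
#' midranks for ties.  The exact null distribution is used when the
#' smaller group has at most 10 samples and the scores are tie-free;
#' otherwise the normal approximation with tie correction.
#'
#' @inheritParams logistic_burden_test
#' @return one-row data frame as in [logistic_burden_test()]; the
#'   statistic is the Mann-Whitney U of the cases.
#' @export
wilcoxon_rank_sum_test <- function(scores, phen,
                                   bin_id = NA_character_,
                                   n_loci = NA_integer_) {
  status <- if (is.data.frame(phen)) as.integer(phen$status) else as.integer(phen)
  if (length(scores) != length(status))
    stop("scores and phenotype lengths differ")
  if (!any(status == 1L) || !any(status == 0L))
    stop("need at least one case and one control")
  x <- scores[status == 1L]; y <- scores[status == 0L]
  if (var(scores) == 0) {
    return(.assoc_row(bin_id, "wilcoxon", NA_real_, NA_real_, "degenerate",
                      n_loci, length(x), length(y)))
  }
  res <- .wilcoxon_p(x, y)
  reason <- if (is.na(res$p)) "degenerate" else ""
  .assoc_row(bin_id, "wilcoxon", res$W, res$p, reason,
             n_loci, length(x), length(y))
}

#' Run burden tests over every bin
#'
#' Applies the requested test(s) to each bin's score column and stacks
#' the per-bin results (deterministic bin order, as scored).  Raw
#' p-values are reported; a Bonferroni flag column marks
#' `p < alpha / n_bins` for a user-chosen family-wise level — no
#' correction is applied to the p-values themselves.
#'
#' @param bsm a `bin_scores` object.
#' @param phen phenotype data frame (sample ids matched to the score
#'   matrix rows).
#' @param test `"logistic"`, `"wilcoxon"`, or `"both"`.
#' @param covariates optional per-sample covariates (logistic only).
#' @param alpha family-wise level for the Bonferroni flag (default 0.05).
#' @return data frame of association results, one row per bin x test,
#'   with columns `bin_id`, `level`, `n_loci`, `capacity`, `test`,
#'   `statistic`, `p_value`, `reason`, `n_cases`, `n_controls`,
#'   `signif_bonferroni`.
#' @export
run_association <- function(bsm, phen, test = c("both", "logistic", "wilcoxon"),
                            covariates = NULL, alpha = 0.05) {
  test <- match.arg(test)
  tests <- if (test == "both") c("logistic", "wilcoxon") else test
  ord <- match(phen$sample_id, rownames(bsm$scores))
  if (anyNA(ord))
    stop("phenotype sample(s) not in score matrix: ",
         paste(phen$sample_id[is.na(ord)], collapse = ", "))
  out <- vector("list", ncol(bsm$scores) * length(tests))
  k <- 0L
  for (b in seq_len(ncol(bsm$scores))) {
    sc <- bsm$scores[ord, b]
    for (tst in tests) {
      k <- k + 1L
      row <- if (tst == "logistic") {
        logistic_burden_test(sc, phen, covariates,
                             bin_id = bsm$bins$bin_id[b],
                             n_loci = bsm$bins$n_loci[b])
      } else {
        wilcoxon_rank_sum_test(sc, phen,
                               bin_id = bsm$bins$bin_id[b],
                               n_loci = bsm$bins$n_loci[b])
      }
      row$level <- bsm$bins$level[b]
      row$capacity <- bsm$bins$capacity[b]
      out[[k]] <- row
    }
  }
  res <- if (k) do.call(rbind, out) else
    cbind(.assoc_row(character(), character(), numeric(), numeric(),
                     character(), integer(), integer(), integer()),
          level = character(), capacity = integer())
  n_bins <- max(1L, ncol(bsm$scores))
  res$signif_bonferroni <- !is.na(res$p_value) & res$p_value < alpha / n_bins
  res <- res[, c("bin_id", "level", "n_loci", "capacity", "test",
                 "statistic", "p_value", "reason", "n_cases", "n_controls",
                 "signif_bonferroni")]
  rownames(res) <- NULL
  res
}
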