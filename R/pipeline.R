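## End-to-end pipeline: VCF + phenotype + knowledge files in, bin scores
## and association results out, with per-stage locus accounting.

#' Run the full binning and association pipeline
#'
#' Executes, in order: VCF reading, NMAF-threshold locus selection,
#' optional role filtering, feature assignment at the requested level,
#' optional intergenic window binning of the leftover loci, locus
#' weighting, bin scoring, and burden testing.  Stage-by-stage locus
#' counts are logged and satisfy the conservation identities
#' `loci_read = loci_selected + loci_filtered` and (with intergenic bins
#' enabled) `loci_selected = loci_in_feature_bins + loci_intergenic`,
#' counting a locus in several overlapping features once.
#'
#' @param vcf path to the VCF file.
#' @param phenotype path to the phenotype file, or a phenotype data
#'   frame (see [read_phenotype_file()]).
#' @param regions path to the region file, or a `region_set`.
#' @param groups optional group file path (or `group_set`); required for
#'   `level = "group"`.
#' @param roles optional role file path (or data frame) for
#'   include/exclude variant filtering.
#' @param roles_mode `"exclude"` (default) or `"include"`.
#' @param weights_file optional custom weight file path (or data frame);
#'   implies `scheme = "custom"` must be requested explicitly.
#' @param level binning level, `"gene"` or `"group"`.
#' @param group_ids optional subset of groups to bin on.
#' @param threshold NMAF selection threshold (default 0.05).
#' @param nmaf_mode NMAF mode, see [select_loci()].
#' @param model disease model encoding (default `"additive"`).
#' @param scheme weighting scheme (default `"none"`).
#' @param intergenic_kb intergenic window width in kb; 0 disables
#'   intergenic bins.
#' @param test `"both"` (default), `"logistic"`, or `"wilcoxon"`.
#' @param source_tag knowledge source tag for the region file.
#' @param out optional output path prefix; when given,
#'   `<out>_scores.tsv`, `<out>_bins.tsv` and `<out>_results.tsv` are
#'   written.
#' @param verbose log stage counts to stderr.
#' @return a `binning_run` object: `scores` (a `bin_scores`), `results`
#'   (association table), `counts` (stage accounting), `config`.
#' @export
run_binning_pipeline <- function(vcf, phenotype, regions, groups = NULL,
                                 roles = NULL, roles_mode = "exclude",
                                 weights_file = NULL,
                                 level = c("gene", "group"),
                                 group_ids = NULL,
                                 threshold = 0.05,
                                 nmaf_mode = "either",
                                 model = "additive",
                                 scheme = "none",
                                 intergenic_kb = 50,
                                 test = "both",
                                 source_tag = "custom",
                                 out = NULL, verbose = TRUE) {
  level <- match.arg(level)
  log_ <- function(...) if (verbose) message("[rarebin] ", ...)

  ## validate inputs before any computation
  for (p in c(vcf, Filter(is.character, list(phenotype, regions, groups,
                                             roles, weights_file)))) {
    if (is.character(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  phen <- if (is.character(phenotype)) read_phenotype_file(phenotype) else phenotype
  rset <- if (is.character(regions)) load_region_file(regions, source_tag) else regions
  gset <- if (is.character(groups)) load_group_file(groups, rset) else groups
  role_df <- if (is.character(roles)) read_role_file(roles) else roles
  custom_w <- if (is.character(weights_file)) read_weight_file(weights_file) else weights_file
  if (level == "group" && is.null(gset))
    stop("level 'group' requires a group file")
  kb <- knowledge_base(rset, gset)

  gm <- read_vcf(vcf)
  log_("loci read: ", nrow(gm$loci), " (", length(gm$samples), " samples)")

  selected <- select_loci(gm, phen, threshold = threshold, mode = nmaf_mode)
  log_("loci selected at NMAF < ", threshold, " (", nmaf_mode, "): ",
       length(selected), "; filtered: ", nrow(gm$loci) - length(selected))
  if (!is.null(role_df)) {
    selected <- apply_role_filter(selected, role_df, roles_mode)
    log_("loci after role filter (", roles_mode, "): ", length(selected))
  }

  asg <- assign_loci_to_features(gm, selected, kb, level = level,
                                 group_ids = group_ids)
  in_features <- unique(unlist(lapply(asg$bins, `[[`, "member_loci")))
  log_("feature bins: ", length(asg$bins), " covering ",
       length(in_features), " loci; unassigned: ", length(asg$unassigned))

  bins <- asg$bins
  if (intergenic_kb > 0) {
    ig <- make_intergenic_bins(gm, asg$unassigned, intergenic_kb)
    log_("intergenic bins (", intergenic_kb, " kb): ", length(ig))
    bins <- c(bins, ig)
  }
  bins <- bins[order(vapply(bins, `[[`, "", "bin_id"))]

  binned <- unique(unlist(lapply(bins, `[[`, "member_loci")))
  w <- compute_weights(gm, phen, sort(binned), scheme = scheme,
                       custom = custom_w)
  bsm <- score_bins(bins, gm, model = model, weights = w)
  results <- run_association(bsm, phen, test = test)
  log_("tested ", ncol(bsm$scores), " bins with ",
       paste(unique(results$test), collapse = " + "))

  counts <- list(loci_read = nrow(gm$loci),
                 loci_selected = length(selected),
                 loci_filtered = nrow(gm$loci) - length(selected),
                 loci_in_feature_bins = length(in_features),
                 loci_intergenic = if (intergenic_kb > 0)
                   length(asg$unassigned) else 0L,
                 loci_unassigned = if (intergenic_kb > 0) 0L
                   else length(asg$unassigned))
  run <- structure(list(scores = bsm, results = results, counts = counts,
                        config = list(level = level, threshold = threshold,
                                      nmaf_mode = nmaf_mode, model = model,
                                      scheme = scheme,
                                      intergenic_kb = intergenic_kb,
                                      test = test)),
                   class = "binning_run")
  if (!is.null(out)) {
    write_bin_report(bsm, out)
    write.table(results, paste0(out, "_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_("wrote ", out, "_{scores,bins,results}.tsv")
  }
  run
}

#' @export
print.binning_run <- function(x, ...) {
  cat("binning_run:", x$counts$loci_read, "loci read,",
      x$counts$loci_selected, "selected (NMAF <", x$config$threshold,
      paste0("[", x$config$nmaf_mode, "]),"),
      ncol(x$scores$scores), "bins tested\n")
  cat("  level:", x$config$level, " model:", x$config$model,
      " scheme:", x$config$scheme, "\n")
  invisible(x)
}

#' @export
summary.binning_run <- function(object, ...) {
  res <- object$results
  res <- res[order(res$p_value), ]
  cat("Top associations:\n")
  print(head(res[, c("bin_id", "level", "n_loci", "test", "statistic",
                     "p_value")], 10), row.names = FALSE)
  invisible(res)
}

#' Read a flat key=value study configuration file
#'
#' Keys mirror the [simulation_config()] arguments (e.g. `n_cases=500`,
#' `bin_kind=gene`, `odds_ratio=1`, `schemes=none,control`).  `#`
#' comments and blank lines are skipped.
#'
#' @param path config file path.
#' @return named list of parsed values.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed config line (want key=value)")
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  out <- list()
  for (i in seq_along(keys)) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(v))
    out[[keys[i]]] <- if (anyNA(num)) v else num
  }
  out
}

#' Run a configured simulation study
#'
#' Dispatches [run_type1_study()] (odds ratio 1) or [run_power_study()]
#' (odds ratio above 1, or several values) over the configured bin
#' kinds, and optionally writes a summary rate grid and per-replicate
#' p-value tables.
#'
#' @param config a [simulation_config()], a named list of its
#'   arguments, or a path to a key=value config file
#'   ([read_study_config()]); the list/file may additionally name
#'   several `bin_kind` values.
#' @param out optional output prefix: writes `<out>_summary.tsv` and
#'   `<out>_pvalues.tsv`.
#' @return list of `sim_result`, one per bin kind, plus a combined
#'   `summary` data frame.
#' @export
run_simulation_study <- function(config, out = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  if (inherits(config, "simulation_config")) {
    kinds <- config$bin_kind
    args <- unclass(config)
  } else {
    if (!is.null(config$n_sims) && config$n_sims < 1)
      stop("n_sims must be >= 1")
    kinds <- config$bin_kind
    if (is.null(kinds)) kinds <- "gene"
    args <- config
  }
  or <- args$odds_ratio
  results <- list()
  summaries <- list()
  pv_rows <- list()
  for (bk in kinds) {
    args$bin_kind <- bk
    if (!is.null(or) && length(or) > 1 || isTRUE(or > 1)) {
      args$odds_ratio <- 1
      cfg <- do.call(simulation_config,
                     args[names(args) %in% names(formals(simulation_config))])
      res <- run_power_study(cfg, or_values = or)
      tab <- res$rates
      pv <- do.call(rbind, lapply(names(res$pvals), function(o) {
        .pvals_long(res$pvals[[o]], res$sizes[[o]], bk, odds_ratio = o)
      }))
    } else {
      cfg <- do.call(simulation_config,
                     args[names(args) %in% names(formals(simulation_config))])
      res <- run_type1_study(cfg)
      tab <- res$rates
      pv <- .pvals_long(res$pvals, res$sizes, bk)
    }
    tab$bin_kind <- bk
    results[[bk]] <- res
    summaries[[bk]] <- tab
    pv_rows[[bk]] <- pv
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  if (!is.null(out)) {
    write.table(summary, paste0(out, "_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, pv_rows), paste0(out, "_pvalues.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  c(results, list(summary = summary))
}

.pvals_long <- function(pvals, sizes, bin_kind, odds_ratio = NA) {
  dn <- dimnames(pvals)
  out <- expand.grid(replicate = seq_len(dim(pvals)[1]),
                     scheme = dn[[2]], test = dn[[3]],
                     stringsAsFactors = FALSE)
  out$p_value <- as.vector(pvals)
  out$n_loci <- sizes[out$replicate]
  out$bin_kind <- bin_kind
  out$odds_ratio <- odds_ratio
  out
}
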