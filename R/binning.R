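## The binning engine: NMAF-threshold locus selection, role filters,
## feature assignment (gene / group / intergenic), Madsen-Browning
## weighting schemes, and per-sample bin scores.

#' Select loci by non-major allele frequency threshold
#'
#' A locus is binned when its NMAF falls strictly below the threshold
#' `T`, under one of three modes: `"overall"` compares the pooled NMAF
#' (cases + controls together); `"either"` selects when the *minimum* of
#' the case and control NMAFs is below `T` (a variant rare in either
#' stratum qualifies — this aggregates both potential risk and protective
#' variants and is the default); `"both"` requires the *maximum* of the
#' two stratum NMAFs below `T` (rare in both strata — the conservative
#' option that keeps type I error in check when the weighting scheme is
#' frequency-sensitive).  Loci with no observed data in a required
#' stratum are excluded.
#'
#' @param gm a `geno_matrix`.
#' @param phen phenotype data frame (see [read_phenotype_file()]); its
#'   sample ids must be a subset of `gm`'s samples.
#' @param threshold strict NMAF upper bound in (0, 1); default 0.05.
#' @param mode `"either"` (default), `"overall"`, or `"both"`.
#' @return sorted character vector of selected locus ids.
#' @export
select_loci <- function(gm, phen, threshold = 0.05,
                        mode = c("either", "overall", "both")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  al <- .align_phenotype(gm, phen)
  if (mode == "overall") {
    nmaf <- compute_nmaf(gm, subset = al$phenotyped)
    sel <- !is.na(nmaf) & nmaf < threshold
  } else {
    if (!length(al$cases) || !length(al$controls))
      stop("mode '", mode, "' needs at least one case and one control")
    nm_case <- compute_nmaf(gm, subset = al$cases)
    nm_ctrl <- compute_nmaf(gm, subset = al$controls)
    ok <- !is.na(nm_case) & !is.na(nm_ctrl)
    stat <- if (mode == "either") pmin(nm_case, nm_ctrl)
            else pmax(nm_case, nm_ctrl)
    sel <- ok & !is.na(stat) & stat < threshold
  }
  sort(gm$loci$locus_id[sel])
}

#' Read a variant role annotation file
#'
#' Tab-delimited `locus_id  role_tag`, one annotation per line; a locus
#' may carry several tags.  `#` comments allowed.
#'
#' @param path role file path.
#' @return data frame with columns `locus_id`, `role`.
#' @export
read_role_file <- function(path) {
  if (!file.exists(path)) stop("role file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines))
    return(data.frame(locus_id = character(), role = character()))
  f <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(f) < 2L)) stop("malformed role line: expected 'locus_id role'")
  data.frame(locus_id = vapply(f, `[[`, "", 1L),
             role = vapply(f, `[[`, "", 2L), stringsAsFactors = FALSE)
}

#' Filter selected loci by role annotations
#'
#' With `mode = "include"` only annotated loci are kept; with
#' `mode = "exclude"` annotated loci are dropped and unannotated loci
#' pass through untouched.  Role annotations typically come from variant
#' effect predictors (PolyPhen, SIFT, SnpEff) via [read_role_file()].
#'
#' @param loci character vector of locus ids.
#' @param roles data frame with a `locus_id` column (roles beyond
#'   membership are not interpreted here).
#' @param mode `"include"` or `"exclude"`.
#' @return filtered locus ids (input order preserved).
#' @export
apply_role_filter <- function(loci, roles, mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  annotated <- unique(roles$locus_id)
  if (mode == "include") loci[loci %in% annotated]
  else loci[!(loci %in% annotated)]
}

new_bin <- function(bin_id, level, member_loci, feature_ref) {
  structure(list(bin_id = bin_id, level = level,
                 member_loci = sort(unique(member_loci)),
                 feature_ref = feature_ref),
            class = "bin_definition")
}

#' Assign selected loci to knowledge-defined features
#'
#' Gene level: one bin per region containing at least one selected locus
#' (a locus inside two overlapping regions contributes to both bins).
#' Group level: one bin per group, whose members are the loci falling in
#' any region of the group's transitive closure ([expand_group()]).
#' Loci covered by no feature are returned as unassigned, ready for
#' [make_intergenic_bins()].
#'
#' @param gm a `geno_matrix` (provides locus positions).
#' @param loci selected locus ids.
#' @param kb a `knowledge_base`.
#' @param level `"gene"` or `"group"`.
#' @param group_ids optional subset of group ids to bin on (group level);
#'   unknown ids are an error.
#' @return list with `bins` (list of `bin_definition`, ordered by
#'   `bin_id`) and `unassigned` (sorted locus ids).
#' @export
assign_loci_to_features <- function(gm, loci, kb,
                                    level = c("gene", "group"),
                                    group_ids = NULL) {
  level <- match.arg(level)
  j <- match(loci, gm$loci$locus_id)
  if (anyNA(j)) stop("unknown locus id(s): ",
                     paste(loci[is.na(j)], collapse = ", "))
  hits <- .region_hits(kb, gm$loci$chrom[j], gm$loci$pos[j])
  hit_loci <- loci[hits$locus]

  if (level == "gene") {
    members <- split(hit_loci, hits$region_id)
    bins <- lapply(sort(names(members)), function(rid)
      new_bin(rid, "gene", members[[rid]], rid))
    assigned <- unique(hit_loci)
  } else {
    gids <- names(kb$groups)
    if (!is.null(group_ids)) {
      unknown <- setdiff(group_ids, gids)
      if (length(unknown))
        stop("unknown group id(s): ", paste(unknown, collapse = ", "))
      gids <- group_ids
    }
    if (!length(gids)) stop("no groups loaded in the knowledge base")
    bins <- list()
    assigned <- character()
    for (gid in sort(gids)) {
      rids <- expand_group(kb, gid)
      mem <- unique(hit_loci[hits$region_id %in% rids])
      if (length(mem)) {
        bins[[length(bins) + 1L]] <- new_bin(gid, "group", mem, gid)
        assigned <- union(assigned, mem)
      }
    }
    ## unassigned relative to *any* region so intergenic bins stay
    ## feature-free regardless of which groups were requested
    assigned_any <- unique(hit_loci)
    return(list(bins = bins,
                unassigned = sort(setdiff(loci, assigned_any))))
  }
  list(bins = bins, unassigned = sort(setdiff(loci, assigned)))
}

#' Collect unassigned loci into fixed-width intergenic bins
#'
#' Each locus falls in window `floor(pos / (width_kb * 1000))` on its
#' chromosome; only non-empty windows are emitted.  Bin ids encode the
#' chromosome and window span, e.g. `chr1:100000-150000`.
#'
#' @param gm a `geno_matrix`.
#' @param unassigned locus ids left over by [assign_loci_to_features()].
#' @param width_kb window width in kilobases (>= 1).
#' @return list of `bin_definition` (level `"intergenic"`), ordered by id.
#' @export
make_intergenic_bins <- function(gm, unassigned, width_kb = 50) {
  stopifnot(width_kb >= 1)
  if (!length(unassigned)) return(list())
  j <- match(unassigned, gm$loci$locus_id)
  if (anyNA(j)) stop("unknown locus id(s)")
  w <- as.integer(width_kb * 1000)
  win <- gm$loci$pos[j] %/% w
  key <- sprintf("%s:%d-%d", gm$loci$chrom[j], win * w, (win + 1L) * w)
  members <- split(unassigned, key)
  lapply(sort(names(members)), function(k)
    new_bin(k, "intergenic", members[[k]], k))
}

#' Read a custom locus weight file
#'
#' Tab-delimited `locus_id  weight`; weights must be positive.
#'
#' @param path weight file path.
#' @return data frame with columns `locus_id`, `weight`.
#' @export
read_weight_file <- function(path) {
  if (!file.exists(path)) stop("weight file not found: ", path)
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("locus_id", "weight"),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$weight) | df$weight <= 0))
    stop("custom weights must be positive and finite")
  df
}

## Madsen-Browning weight: w(q) = 1 / sqrt(n q (1-q)) with the
## pseudo-count estimate q = (m + 1) / (2 n_pop + 2), where m is the
## non-major allele count observed in the weighting population of n_pop
## genotyped individuals, and n is the total number of genotyped
## individuals at the locus (held common across schemes so that the
## minimum <= overall <= maximum sandwich holds).
mb_weight <- function(m, n_pop, n) {
  q <- (m + 1) / (2 * n_pop + 2)
  list(q = q, w = 1 / sqrt(n * q * (1 - q)))
}

#' Madsen-Browning locus weights under a weighting-population scheme
#'
#' The weight of a locus is inversely related to its estimated non-major
#' allele frequency, so rarer variants count more in the bin score:
#' `w(q) = 1 / sqrt(n q (1 - q))` with the pseudo-count estimate
#' `q = (m + 1) / (2 n_pop + 2)`.  The *scheme* chooses which sample
#' stratum supplies `m` and `n_pop`: `"control"` uses controls only (the
#' original proposal — powerful but known to inflate type I error,
#' because case frequencies are left unbounded); `"overall"` uses
#' everyone; `"minimum"`/`"maximum"` take the smaller/larger of the
#' control-based and case-based weights per locus; `"none"` sets every
#' weight to 1; `"custom"` looks weights up in a user table (loci absent
#' from the table get weight 1).  `n` is the total count of genotyped
#' individuals at the locus regardless of scheme.
#'
#' @param gm a `geno_matrix`.
#' @param phen phenotype data frame.
#' @param loci locus ids to weight.
#' @param scheme one of `"none"`, `"control"`, `"minimum"`, `"maximum"`,
#'   `"overall"`, `"custom"`.
#' @param custom data frame `locus_id, weight` (required iff
#'   `scheme = "custom"`).
#' @return data frame with columns `locus_id`, `q` (frequency estimate
#'   from the scheme's population; overall-population estimate for
#'   `"none"`/`"custom"`), `n`, `w`.
#' @export
compute_weights <- function(gm, phen, loci,
                            scheme = c("none", "control", "minimum",
                                       "maximum", "overall", "custom"),
                            custom = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "custom" && is.null(custom))
    stop("scheme 'custom' requires a weight table")
  if (scheme != "custom" && !is.null(custom))
    stop("a weight table is only used with scheme 'custom'")
  al <- .align_phenotype(gm, phen)
  j <- match(loci, gm$loci$locus_id)
  if (anyNA(j)) stop("unknown locus id(s): ",
                     paste(loci[is.na(j)], collapse = ", "))

  major <- major_alleles(gm)                 # fixed in the full population
  dos <- nonmajor_dosage(gm, "additive", major)
  genotyped <- !is.na(gm$a1) & !is.na(gm$a2)

  count_in <- function(rows) {
    g <- genotyped[rows, j, drop = FALSE]
    list(m = colSums((dos[rows, j, drop = FALSE]) * g),
         n_pop = colSums(g))
  }
  n_tot <- colSums(genotyped[al$phenotyped, j, drop = FALSE])

  if (scheme == "none" || scheme == "custom") {
    ov <- count_in(al$phenotyped)
    q <- mb_weight(ov$m, ov$n_pop, n_tot)$q
    w <- rep(1, length(loci))
    if (scheme == "custom") {
      hit <- match(loci, custom$locus_id)
      w[!is.na(hit)] <- custom$weight[hit[!is.na(hit)]]
    }
  } else if (scheme == "overall") {
    ov <- count_in(al$phenotyped)
    mw <- mb_weight(ov$m, ov$n_pop, n_tot)
    q <- mw$q; w <- mw$w
  } else {
    if (!length(al$controls))
      stop("scheme '", scheme, "' needs at least one control")
    if (scheme != "control" && !length(al$cases))
      stop("scheme '", scheme, "' needs at least one case")
    ctrl <- count_in(al$controls)
    mw_ctrl <- mb_weight(ctrl$m, ctrl$n_pop, n_tot)
    if (scheme == "control") {
      q <- mw_ctrl$q; w <- mw_ctrl$w
    } else {
      case <- count_in(al$cases)
      mw_case <- mb_weight(case$m, case$n_pop, n_tot)
      if (scheme == "minimum") {
        w <- pmin(mw_ctrl$w, mw_case$w)
        q <- ifelse(mw_ctrl$w <= mw_case$w, mw_ctrl$q, mw_case$q)
      } else {
        w <- pmax(mw_ctrl$w, mw_case$w)
        q <- ifelse(mw_ctrl$w >= mw_case$w, mw_ctrl$q, mw_case$q)
      }
    }
  }
  data.frame(locus_id = loci, q = q, n = n_tot, w = w,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse loci into per-sample bin scores
#'
#' The score of sample `i` in a bin is the weighted sum of that sample's
#' encoded genotype contributions over the bin's member loci:
#' `score(i, bin) = sum_j w_j * encode(call_ij, model)`.  The per-bin
#' capacity (maximum possible unweighted score) is `2 * n_loci` under the
#' additive model and `n_loci` otherwise.
#'
#' @param bins list of `bin_definition`.
#' @param gm a `geno_matrix`.
#' @param model disease model: `"additive"` (default), `"dominant"`,
#'   `"recessive"`.
#' @param weights data frame from [compute_weights()]; every bin member
#'   must have a weight entry.
#' @return a `bin_scores` object: per-sample score matrix plus a bin
#'   summary table (`bin_id`, `level`, `n_loci`, `nonmajor_total`,
#'   `capacity`).
#' @export
score_bins <- function(bins, gm,
                       model = c("additive", "dominant", "recessive"),
                       weights) {
  model <- match.arg(model)
  major <- major_alleles(gm)
  dos <- nonmajor_dosage(gm, model, major)
  add <- if (model == "additive") dos else nonmajor_dosage(gm, "additive", major)

  n <- length(gm$samples)
  B <- length(bins)
  scores <- matrix(0, nrow = n, ncol = B)
  info <- data.frame(bin_id = character(B), level = character(B),
                     n_loci = integer(B), nonmajor_total = integer(B),
                     capacity = integer(B), stringsAsFactors = FALSE)
  members <- vector("list", B)
  for (b in seq_len(B)) {
    bin <- bins[[b]]
    widx <- match(bin$member_loci, weights$locus_id)
    if (anyNA(widx))
      stop("bin '", bin$bin_id, "' member(s) without a weight entry: ",
           paste(bin$member_loci[is.na(widx)], collapse = ", "))
    j <- match(bin$member_loci, gm$loci$locus_id)
    if (anyNA(j)) stop("bin member not in genotype data")
    scores[, b] <- dos[, j, drop = FALSE] %*% weights$w[widx]
    info$bin_id[b] <- bin$bin_id
    info$level[b] <- bin$level
    info$n_loci[b] <- length(j)
    info$nonmajor_total[b] <- sum(add[, j])
    info$capacity[b] <- if (model == "additive") 2L * length(j) else length(j)
    members[[b]] <- bin$member_loci
  }
  dimnames(scores) <- list(gm$samples, info$bin_id)
  structure(list(scores = scores, bins = info, members = members,
                 model = model),
            class = "bin_scores")
}

#' @export
print.bin_scores <- function(x, ...) {
  cat("bin_scores:", nrow(x$scores), "samples x", ncol(x$scores),
      "bins (model:", x$model, ")\n")
  lv <- table(x$bins$level)
  cat("  levels:", paste(names(lv), lv, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write bin score and bin summary reports
#'
#' Emits `<prefix>_scores.tsv` (rows = samples, columns = bins) and
#' `<prefix>_bins.tsv` (bin_id, level, n_loci, nonmajor_total, capacity).
#'
#' @param bsm a `bin_scores` object.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_bin_report <- function(bsm, prefix) {
  sc <- data.frame(sample_id = rownames(bsm$scores),
                   bsm$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  f1 <- paste0(prefix, "_scores.tsv")
  f2 <- paste0(prefix, "_bins.tsv")
  write.table(sc, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bsm$bins, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(scores = f1, bins = f2))
}
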