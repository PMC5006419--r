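## Knowledge store: plain-text regions (BED-like) and groups (pathways,
## protein families, ...) that define bin boundaries.  Coordinates are
## 0-based half-open internally, the BED convention.

.empty_region_df <- function() {
  data.frame(region_id = character(), name = character(),
             chrom = character(), start = integer(), stop = integer(),
             source = character(), stringsAsFactors = FALSE)
}

new_region_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("region_set", "data.frame")
  df
}

#' Load a region definition file
#'
#' Reads a BED-like tab- (or whitespace-) delimited file with columns
#' `chrom start stop name`.  Coordinates follow the BED convention:
#' 0-based, half-open `[start, stop)`.  Lines starting with `#` and blank
#' lines are skipped.  The region name doubles as its unique id.
#'
#' @param path path to the region file.
#' @param source_tag character tag recorded as the knowledge source of
#'   every region in this file (e.g. `"entrez"`, `"custom"`).
#' @return a `region_set`: a data frame with columns `region_id`, `name`,
#'   `chrom`, `start`, `stop`, `source`.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t1000\t2000\tGENE_A", f)
#' load_region_file(f, "example")
#' @export
load_region_file <- function(path, source_tag = "custom") {
  if (!file.exists(path)) stop("region file not found: ", path)
  lines <- readLines(path)
  data_ln <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(data_ln)) return(new_region_set(.empty_region_df()))
  fields <- strsplit(trimws(lines[data_ln]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("malformed region line ", data_ln[which(nf < 4L)[1L]],
         ": expected 'chrom start stop name'")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  stop_ <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  name  <- vapply(fields, `[[`, "", 4L)
  bad <- is.na(start) | is.na(stop_) | !nzchar(chrom) | !nzchar(name)
  if (any(bad)) {
    stop("malformed region line ", data_ln[which(bad)[1L]],
         ": non-numeric coordinates or empty fields")
  }
  rev_ <- start >= stop_
  if (any(rev_)) {
    stop("region line ", data_ln[which(rev_)[1L]],
         ": start must be < stop (0-based half-open intervals)")
  }
  if (anyDuplicated(name)) {
    stop("duplicate region id(s): ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  new_region_set(data.frame(
    region_id = name, name = name, chrom = chrom,
    start = start, stop = stop_, source = source_tag,
    stringsAsFactors = FALSE))
}

#' Write a region set back to the region-file dialect
#'
#' Inverse of [load_region_file()]: emits `chrom start stop name` lines,
#' tab-delimited, so that reloading reproduces the same `region_set`.
#'
#' @param regions a `region_set`.
#' @param path output path.
#' @export
write_region_file <- function(regions, path) {
  df <- as.data.frame(regions)[, c("chrom", "start", "stop", "name")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a group (pathway / region-set) membership file
#'
#' Each line declares one membership:
#' `group_id  source  member_type  member_id`, where `member_type` is
#' `region` or `group` (nested groups are allowed; cycles are rejected).
#' `member_type` `none` declares an empty group.  Every region member must
#' exist in `regions`; every group member must itself be declared in the
#' file.
#'
#' @param path path to the group file.
#' @param regions a `region_set` the region members resolve against.
#' @return a `group_set`: named list of groups, each with `group_id`,
#'   `source`, `member_region_ids`, `member_group_ids`.
#' @export
load_group_file <- function(path, regions) {
  if (!file.exists(path)) stop("group file not found: ", path)
  lines <- readLines(path)
  data_ln <- which(!grepl("^\\s*(#|$)", lines))
  groups <- list()
  for (i in data_ln) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 3L || (f[3L] != "none" && length(f) < 4L)) {
      stop("malformed group line ", i,
           ": expected 'group_id source member_type member_id'")
    }
    gid <- f[1L]
    if (is.null(groups[[gid]])) {
      groups[[gid]] <- list(group_id = gid, source = f[2L],
                            member_region_ids = character(),
                            member_group_ids = character())
    }
    type <- f[3L]
    if (type == "region") {
      groups[[gid]]$member_region_ids <-
        union(groups[[gid]]$member_region_ids, f[4L])
    } else if (type == "group") {
      groups[[gid]]$member_group_ids <-
        union(groups[[gid]]$member_group_ids, f[4L])
    } else if (type != "none") {
      stop("group line ", i, ": unknown member_type '", type, "'")
    }
  }
  ## resolve region members
  all_regions <- unique(unlist(lapply(groups, `[[`, "member_region_ids")))
  missing_r <- setdiff(all_regions, regions$region_id)
  if (length(missing_r)) {
    stop("group members not found in region set: ",
         paste(missing_r, collapse = ", "))
  }
  all_children <- unique(unlist(lapply(groups, `[[`, "member_group_ids")))
  missing_g <- setdiff(all_children, names(groups))
  if (length(missing_g)) {
    stop("group members not declared as groups: ",
         paste(missing_g, collapse = ", "))
  }
  .check_group_cycles(groups)
  class(groups) <- "group_set"
  groups
}

## DFS three-colour cycle check; errors naming one cycle.
.check_group_cycles <- function(groups) {
  state <- setNames(rep(0L, length(groups)), names(groups))  # 0 new 1 open 2 done
  path <- character()
  visit <- function(gid) {
    if (state[[gid]] == 1L) {
      cyc <- c(path[which(path == gid)[1L]:length(path)], gid)
      stop("group membership cycle: ", paste(cyc, collapse = " -> "))
    }
    if (state[[gid]] == 2L) return(invisible())
    state[[gid]] <<- 1L
    path <<- c(path, gid)
    for (child in groups[[gid]]$member_group_ids) visit(child)
    path <<- path[-length(path)]
    state[[gid]] <<- 2L
    invisible()
  }
  for (gid in names(groups)) visit(gid)
  invisible()
}

#' Assemble a knowledge base from regions and groups
#'
#' Builds the per-chromosome interval index used by [regions_at()] and
#' the feature-assignment step of the binning engine.
#'
#' @param regions a `region_set` from [load_region_file()].
#' @param groups optional `group_set` from [load_group_file()].
#' @return a `knowledge_base` object.
#' @export
knowledge_base <- function(regions, groups = NULL) {
  stopifnot(inherits(regions, "region_set"))
  if (!is.null(groups)) stopifnot(inherits(groups, "group_set"))
  idx <- lapply(split(seq_len(nrow(regions)), regions$chrom), function(rows) {
    list(rows = rows,
         ## BED [start, stop) -> 1-based closed [start+1, stop]
         ranges = IRanges::IRanges(start = regions$start[rows] + 1L,
                                   end = regions$stop[rows]))
  })
  grp <- if (is.null(groups)) structure(list(), class = "group_set") else groups
  structure(list(regions = regions,
                 groups = grp,
                 sources = unique(c(regions$source,
                                    vapply(unclass(grp), `[[`, "", "source"))),
                 index = idx),
            class = "knowledge_base")
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("knowledge_base:", nrow(x$regions), "regions on",
      length(x$index), "chromosome(s),",
      length(x$groups), "group(s), sources:",
      paste(x$sources, collapse = ", "), "\n")
  invisible(x)
}

#' Regions covering a genomic position
#'
#' Point query against the interval index: returns every region with
#' `start <= pos < stop` on `chrom`, ordered by `region_id`.  Positions
#' are 0-based, matching the region files.
#'
#' @param kb a `knowledge_base`.
#' @param chrom chromosome label.
#' @param pos 0-based base position.
#' @return a `region_set` (possibly empty).
#' @export
regions_at <- function(kb, chrom, pos) {
  stopifnot(inherits(kb, "knowledge_base"))
  node <- kb$index[[chrom]]
  if (is.null(node)) return(new_region_set(.empty_region_df()))
  hits <- IRanges::findOverlaps(IRanges::IRanges(pos + 1L, pos + 1L),
                                node$ranges)
  rows <- node$rows[S4Vectors::subjectHits(hits)]
  out <- kb$regions[rows[order(kb$regions$region_id[rows])], , drop = FALSE]
  new_region_set(out)
}

## Vectorised interval hits for many loci at once.
## Returns data.frame(locus = index into pos, region_id).
.region_hits <- function(kb, chrom, pos) {
  out <- vector("list", length(kb$index))
  names(out) <- names(kb$index)
  for (ch in unique(chrom)) {
    node <- kb$index[[ch]]
    if (is.null(node)) next
    q <- which(chrom == ch)
    hits <- IRanges::findOverlaps(IRanges::IRanges(pos[q] + 1L, pos[q] + 1L),
                                  node$ranges)
    out[[ch]] <- data.frame(
      locus = q[S4Vectors::queryHits(hits)],
      region_id = kb$regions$region_id[node$rows[S4Vectors::subjectHits(hits)]],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) res <- data.frame(locus = integer(), region_id = character())
  rownames(res) <- NULL
  res
}

#' Transitive closure of a group's region membership
#'
#' Expands nested groups (depth-first, memoised) and returns the sorted
#' set of region ids reachable from `group_id`.
#'
#' @param kb a `knowledge_base` with groups loaded.
#' @param group_id group to expand.
#' @return character vector of region ids (each once, sorted).
#' @export
expand_group <- function(kb, group_id) {
  stopifnot(inherits(kb, "knowledge_base"))
  groups <- kb$groups
  if (is.null(groups[[group_id]])) stop("unknown group: ", group_id)
  memo <- new.env(parent = emptyenv())
  rec <- function(gid) {
    if (!is.null(memo[[gid]])) return(memo[[gid]])
    g <- groups[[gid]]
    ids <- g$member_region_ids
    for (child in g$member_group_ids) ids <- union(ids, rec(child))
    memo[[gid]] <- ids
    ids
  }
  sort(unique(rec(group_id)))
}
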