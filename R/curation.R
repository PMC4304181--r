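# Alignment curation: redundancy clustering, row and column filters, and
# reference-anchored trimming. All operators only remove rows or columns;
# residue characters are never altered.

.ungapped <- function(x) {
  if (is.matrix(x)) stop("internal: expected a character vector")
  x[x != "-"]
}

#' Pairwise sequence identity and coverage
#'
#' Gap-free global comparison of two sequences: gaps are stripped, the
#' shorter sequence is slid over nothing (compared position-by-position from
#' the start), and
#' \itemize{
#'   \item identity = matching positions / length of the longer sequence,
#'   \item coverage = length of the shorter sequence / length of the longer.
#' }
#' This is a deterministic, self-contained surrogate for score-based
#' redundancy clustering tools.
#'
#' @param a,b Character vectors of residues (may contain '-') or single
#'   strings.
#' @return List with elements `identity` and `coverage`, both in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(b, "")[[1]]
  a <- .ungapped(.normalize_residues(a))
  b <- .ungapped(.normalize_residues(b))
  if (length(a) == 0L || length(b) == 0L) {
    stop("empty ungapped sequence in pairwise comparison", call. = FALSE)
  }
  n_long <- max(length(a), length(b))
  n_short <- min(length(a), length(b))
  matches <- sum(a[seq_len(n_short)] == b[seq_len(n_short)])
  list(identity = matches / n_long, coverage = n_short / n_long)
}

#' Cluster redundant sequences
#'
#' Greedy single-linkage clustering: sequences are processed longest-first
#' (ties broken by id), and a sequence joins the first existing cluster
#' containing a member with identity >= `identity_threshold` and coverage
#' >= `coverage_threshold` (see [pairwise_identity()]). The longest member
#' of each cluster is its representative; the reference sequence, when
#' flagged, always represents its own cluster.
#'
#' Defaults mirror redundancy reduction at 85% similarity and 100% coverage.
#'
#' @param aln A `sector_alignment` (sequences may be aligned; identity is
#'   computed gap-free).
#' @param identity_threshold Minimum identity to join a cluster.
#' @param coverage_threshold Minimum coverage to join a cluster.
#' @return List with `representatives` (character vector of ids, in
#'   processing order) and `clusters` (list of character vectors of member
#'   ids; first element of each is the representative).
#' @export
cluster_redundant <- function(aln, identity_threshold = 0.85,
                              coverage_threshold = 1.0) {
  ids <- alignment_ids(aln)
  rows <- lapply(seq_along(ids), function(i) .ungapped(aln$seqs[i, ]))
  names(rows) <- ids
  lens <- vapply(rows, length, integer(1))
  if (any(lens == 0L)) {
    stop("empty ungapped sequence(s): ",
         paste(ids[lens == 0L], collapse = ", "), call. = FALSE)
  }
  ord <- order(-lens, ids)
  clusters <- list()
  for (i in ord) {
    # single linkage: find every cluster with a member linked to i, then
    # merge them all (keeps the result equal to the transitive closure of
    # the pairwise link relation, independent of processing order)
    hits <- which(vapply(clusters, function(members) {
      any(vapply(members, function(j) {
        pw <- pairwise_identity(rows[[i]], rows[[j]])
        pw$identity >= identity_threshold && pw$coverage >= coverage_threshold
      }, logical(1)))
    }, logical(1)))
    if (length(hits) == 0L) {
      clusters[[length(clusters) + 1L]] <- i
    } else {
      merged <- c(unlist(clusters[hits]), i)
      clusters[hits] <- NULL
      clusters[[length(clusters) + 1L]] <- merged
    }
  }
  ref <- aln$reference_id
  out <- lapply(clusters, function(members) {
    members <- members[order(-lens[members], ids[members])]
    member_ids <- ids[members]
    # longest member is representative; reference overrides
    rep_id <- if (!is.null(ref) && ref %in% member_ids) ref else member_ids[1L]
    c(rep_id, setdiff(member_ids, rep_id))
  })
  list(
    representatives = vapply(out, `[`, character(1), 1L),
    clusters = out
  )
}

#' Keep only cluster representatives
#'
#' Convenience wrapper around [cluster_redundant()] that subsets the
#' alignment to representative rows (original row order preserved).
#'
#' @inheritParams cluster_redundant
#' @return List with `alignment` (the reduced `sector_alignment`) and
#'   `clusters` as in [cluster_redundant()].
#' @export
reduce_redundancy <- function(aln, identity_threshold = 0.85,
                              coverage_threshold = 1.0) {
  cl <- cluster_redundant(aln, identity_threshold, coverage_threshold)
  keep <- alignment_ids(aln) %in% cl$representatives
  out <- new_alignment(aln$seqs[keep, , drop = FALSE], aln$reference_id)
  list(alignment = out, clusters = cl$clusters)
}

#' Drop low-quality sequences by header pattern
#'
#' Removes non-reference sequences whose id (or FASTA description, if the id
#' carries it) matches any of the given patterns, emulating the manual
#' elimination of low-quality predicted and partial entries.
#'
#' @param aln A `sector_alignment`.
#' @param patterns Character vector of case-insensitive fixed patterns.
#' @return List with `alignment` and `removed` (data.frame id/reason).
#' @export
filter_low_quality_ids <- function(aln,
                                   patterns = c("LOW QUALITY", "partial")) {
  ids <- alignment_ids(aln)
  hit <- rep(FALSE, length(ids))
  for (p in patterns) {
    hit <- hit | grepl(p, ids, ignore.case = TRUE, fixed = FALSE)
  }
  if (!is.null(aln$reference_id)) hit[ids == aln$reference_id] <- FALSE
  removed <- data.frame(id = ids[hit],
                        reason = rep("low_quality_id", sum(hit)),
                        stringsAsFactors = FALSE)
  if (all(!hit)) return(list(alignment = aln, removed = removed))
  out <- new_alignment(aln$seqs[!hit, , drop = FALSE], aln$reference_id)
  list(alignment = out, removed = removed)
}

#' Remove gap-heavy sequences
#'
#' Removes non-reference rows whose gap fraction exceeds
#' `max_gap_fraction`. The reference row is immune: all downstream position
#' mapping depends on it, so it is retained with a warning instead.
#'
#' @param aln A `sector_alignment`.
#' @param max_gap_fraction Maximum tolerated per-row gap fraction.
#' @return List with `alignment` and `removed` (data.frame id/reason).
#' @export
filter_gap_heavy <- function(aln, max_gap_fraction = 0.25) {
  gap_frac <- rowMeans(aln$seqs == "-")
  ids <- alignment_ids(aln)
  drop <- gap_frac > max_gap_fraction
  if (!is.null(aln$reference_id)) {
    ref_i <- which(ids == aln$reference_id)
    if (drop[ref_i]) {
      warning("reference sequence exceeds the row gap threshold (",
              sprintf("%.1f%%", 100 * gap_frac[ref_i]),
              " gaps) but is retained", call. = FALSE)
      drop[ref_i] <- FALSE
    }
  }
  removed <- data.frame(id = ids[drop],
                        reason = rep("gap_heavy_row", sum(drop)),
                        stringsAsFactors = FALSE)
  if (!any(drop)) return(list(alignment = aln, removed = removed))
  out <- new_alignment(aln$seqs[!drop, , drop = FALSE], aln$reference_id)
  list(alignment = out, removed = removed)
}

#' Trim alignment to the reference span
#'
#' Removes alignment columns before the first and after the last non-gap
#' character of the reference row.
#'
#' @param aln A `sector_alignment` with a reference flagged.
#' @return List with `alignment` and `kept_columns` (original 1-based
#'   column indices retained).
#' @export
trim_to_reference <- function(aln) {
  ref <- reference_row(aln)
  span <- which(ref != "-")
  if (length(span) == 0L) {
    stop("reference sequence is entirely gaps; cannot trim", call. = FALSE)
  }
  keep <- seq(min(span), max(span))
  out <- new_alignment(aln$seqs[, keep, drop = FALSE], aln$reference_id)
  list(alignment = out, kept_columns = keep)
}

#' Drop gap-rich alignment columns
#'
#' Keeps columns whose gap fraction is at most `max_col_gap_fraction` and
#' (by default) where the reference carries a residue. The returned
#' `kept_columns` index map links retained output columns back to input
#' columns and is consumed by the structure-mapping stage.
#'
#' @param aln A `sector_alignment`.
#' @param max_col_gap_fraction Maximum tolerated per-column gap fraction.
#' @param require_reference_residue Drop columns where the reference is
#'   gapped.
#' @return List with `alignment` and `kept_columns` (strictly increasing
#'   original 1-based indices, one per output column).
#' @export
drop_gapped_columns <- function(aln, max_col_gap_fraction = 0.2,
                                require_reference_residue = TRUE) {
  gap_frac <- colMeans(aln$seqs == "-")
  keep <- gap_frac <= max_col_gap_fraction
  if (require_reference_residue) {
    keep <- keep & (reference_row(aln) != "-")
  }
  kept <- which(keep)
  if (length(kept) == 0L) {
    stop("no alignment columns survive the gap filter", call. = FALSE)
  }
  out <- new_alignment(aln$seqs[, kept, drop = FALSE], aln$reference_id)
  list(alignment = out, kept_columns = kept)
}

#' Run the full curation pipeline
#'
#' Applies, in order: id-pattern filtering, redundancy clustering, gap-heavy
#' row removal, trimming to the reference span, and gapped-column dropping.
#'
#' @param aln A `sector_alignment` with reference flagged.
#' @param identity_threshold,coverage_threshold Redundancy clustering
#'   parameters (see [cluster_redundant()]).
#' @param max_row_gap_fraction,max_col_gap_fraction Gap filters.
#' @param low_quality_patterns Header patterns marking removable sequences.
#' @return List with `alignment`, `kept_columns` (original column indices of
#'   the output columns) and `report` (a `curation_report`).
#' @export
curate_alignment <- function(aln,
                             identity_threshold = 0.85,
                             coverage_threshold = 1.0,
                             max_row_gap_fraction = 0.25,
                             max_col_gap_fraction = 0.2,
                             low_quality_patterns = c("LOW QUALITY",
                                                      "partial")) {
  n_input <- n_sequences(aln)
  removed <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)

  lq <- filter_low_quality_ids(aln, low_quality_patterns)
  removed <- rbind(removed, lq$removed)

  red <- reduce_redundancy(lq$alignment, identity_threshold,
                           coverage_threshold)
  dropped <- setdiff(alignment_ids(lq$alignment),
                     alignment_ids(red$alignment))
  if (length(dropped)) {
    removed <- rbind(removed, data.frame(id = dropped,
                                         reason = "redundant",
                                         stringsAsFactors = FALSE))
  }
  n_after_clustering <- n_sequences(red$alignment)

  gh <- filter_gap_heavy(red$alignment, max_row_gap_fraction)
  removed <- rbind(removed, gh$removed)
  n_after_gap_filter <- n_sequences(gh$alignment)

  tr <- trim_to_reference(gh$alignment)
  dc <- drop_gapped_columns(tr$alignment, max_col_gap_fraction)
  kept_columns <- tr$kept_columns[dc$kept_columns]

  report <- structure(
    list(n_input = n_input,
         n_after_clustering = n_after_clustering,
         n_after_gap_filter = n_after_gap_filter,
         n_after_trim = n_sequences(dc$alignment),
         n_columns = n_columns(dc$alignment),
         removed_ids = removed),
    class = "curation_report"
  )
  list(alignment = dc$alignment, kept_columns = kept_columns,
       report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat("  input sequences:      ", x$n_input, "\n")
  cat("  after clustering:     ", x$n_after_clustering, "\n")
  cat("  after row gap filter: ", x$n_after_gap_filter, "\n")
  cat("  final sequences:      ", x$n_after_trim, "\n")
  cat("  final columns:        ", x$n_columns, "\n")
  invisible(x)
}

#' Write a curation report
#'
#' @param report A `curation_report`.
#' @param path Output path; format chosen by extension (`.json` or TSV).
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    counts <- data.frame(
      metric = c("n_input", "n_after_clustering", "n_after_gap_filter",
                 "n_after_trim", "n_columns"),
      value = c(report$n_input, report$n_after_clustering,
                report$n_after_gap_filter, report$n_after_trim,
                report$n_columns)
    )
    utils::write.table(counts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (nrow(report$removed_ids)) {
      utils::write.table(report$removed_ids, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, append = TRUE, col.names = TRUE)
    }
  }
  invisible(path)
}
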