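# Mutation table parsing, region classification and sector annotation.

#' Parse a mutation table
#'
#' Reads a TSV with header columns `substitution`, `phenotype` and
#' optionally `domain_label`. Substitutions use the short protein form,
#' e.g. `G56A` (missense) or `R70TER` (stop gain). Malformed rows are
#' collected into an error report rather than silently dropped.
#'
#' @param path TSV path.
#' @return List with `mutations` (data.frame: `wild_type`, `position`,
#'   `variant`, `phenotype`, `domain_label`) and `errors` (data.frame:
#'   `line`, `substitution`, `problem`).
#' @export
parse_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"substitution" %in% names(df)) {
    stop("mutation table must have a 'substitution' column", call. = FALSE)
  }
  if (!"phenotype" %in% names(df)) df$phenotype <- ""
  if (!"domain_label" %in% names(df)) df$domain_label <- ""
  parsed <- parse_substitutions(df$substitution)
  ok <- parsed$ok
  mutations <- data.frame(
    wild_type = parsed$wild_type[ok],
    position = parsed$position[ok],
    variant = parsed$variant[ok],
    phenotype = df$phenotype[ok],
    domain_label = df$domain_label[ok],
    stringsAsFactors = FALSE
  )
  errors <- data.frame(
    line = which(!ok) + 1L,  # +1 for the header line
    substitution = df$substitution[!ok],
    problem = parsed$problem[!ok],
    stringsAsFactors = FALSE
  )
  list(mutations = mutations, errors = errors)
}

#' Parse substitution strings
#'
#' @param x Character vector like `c("G56A", "R70TER")`.
#' @return List of parallel vectors `wild_type`, `position`, `variant`,
#'   `ok` (logical) and `problem`.
#' @export
parse_substitutions <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)(TER|\\*|[A-Z])$",
                             toupper(trimws(x))))
  n <- length(x)
  wild_type <- variant <- problem <- rep(NA_character_, n)
  position <- rep(NA_integer_, n)
  ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    mi <- m[[i]]
    if (length(mi) == 0L) {
      problem[i] <- "not in short substitution form (e.g. G56A, R70TER)"
      next
    }
    if (!mi[2L] %in% AMINO_ACIDS) {
      problem[i] <- paste0("invalid wild-type residue '", mi[2L], "'")
      next
    }
    v <- mi[4L]
    if (v == "*") v <- "TER"
    if (v != "TER" && !v %in% AMINO_ACIDS) {
      problem[i] <- paste0("invalid variant residue '", v, "'")
      next
    }
    wild_type[i] <- mi[2L]
    position[i] <- as.integer(mi[3L])
    variant[i] <- v
    ok[i] <- TRUE
  }
  list(wild_type = wild_type, position = position, variant = variant,
       ok = ok, problem = problem)
}

#' Build a region scheme
#'
#' A named partition of the author-numbered sequence into closed intervals
#' (e.g. N-terminal / central / C-terminal). Regions must be ordered and
#' non-overlapping; positions outside every region classify as `"other"`.
#'
#' @param names Character vector of region names.
#' @param starts,ends Integer interval bounds (closed), author numbering.
#' @return A `region_scheme` data.frame.
#' @export
region_scheme <- function(names, starts, ends) {
  stopifnot(length(names) == length(starts),
            length(starts) == length(ends))
  df <- data.frame(region = names, start = as.integer(starts),
                   end = as.integer(ends), stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$end < df$start)) {
    stop("region end before start", call. = FALSE)
  }
  if (nrow(df) > 1L && any(df$start[-1L] <= df$end[-nrow(df)])) {
    stop("regions overlap", call. = FALSE)
  }
  class(df) <- c("region_scheme", "data.frame")
  df
}

#' Default region scheme: tertiles of the mapped range
#'
#' When no protein-specific boundaries are configured, the mapped residue
#' range is split into three equal spans labeled N-terminal, central and
#' C-terminal. Output consumers are warned that this is a default.
#'
#' @param smap A `structure_map`.
#' @return A `region_scheme` with attribute `default = TRUE`.
#' @export
default_region_scheme <- function(smap) {
  rng <- range(smap$entries$resnum)
  cuts <- round(seq(rng[1L], rng[2L] + 1L, length.out = 4L))
  sch <- region_scheme(c("N-terminal", "central", "C-terminal"),
                       starts = cuts[1:3],
                       ends = c(cuts[2:3] - 1L, rng[2L]))
  attr(sch, "default") <- TRUE
  sch
}

#' Read a region scheme from TSV
#'
#' Expects columns `region`, `start`, `end` (closed intervals, author
#' numbering).
#'
#' @param path TSV path.
#' @return A `region_scheme`.
#' @export
read_region_scheme <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("region", "start", "end") %in% names(df)))
  region_scheme(df$region, df$start, df$end)
}

#' Classify a position into a region
#'
#' @param position Author residue number(s).
#' @param scheme A `region_scheme`.
#' @return Region name per position; `"other"` outside all regions.
#' @export
classify_region <- function(position, scheme) {
  vapply(position, function(p) {
    hit <- which(scheme$start <= p & p <= scheme$end)
    if (length(hit)) scheme$region[hit[1L]] else "other"
  }, character(1))
}

#' Annotate mutations with sector and region
#'
#' Pure join by author residue number: each mutation receives the sector
#' label of its mapped alignment column (`"-"` when the position is
#' unmapped or in no sector), its region name, and a wild-type match flag
#' comparing the stated wild-type residue with the mapped reference
#' residue. Mismatches are flagged, never dropped.
#'
#' @param mutations data.frame as produced by [parse_mutations()].
#' @param sectors A `sector_assignment`.
#' @param smap A `structure_map`.
#' @param scheme A `region_scheme`; defaults to tertiles of the mapped
#'   range ([default_region_scheme()]).
#' @return data.frame mirroring a Table-1 layout: `residue` (e.g. "G56A"),
#'   `sector`, `region`, `phenotype`, `domain_label`, `wild_type_match`.
#' @export
annotate_mutations <- function(mutations, sectors, smap, scheme = NULL) {
  if (is.null(scheme)) scheme <- default_region_scheme(smap)
  labels <- sector_labels(sectors)
  n <- nrow(mutations)
  out <- data.frame(
    residue = character(n), sector = character(n), region = character(n),
    phenotype = character(n), domain_label = character(n),
    wild_type_match = rep(NA, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    pos <- mutations$position[i]
    entry <- smap$entries[smap$entries$resnum == pos &
                            smap$entries$icode == "", , drop = FALSE]
    sec <- "-"
    wt_match <- NA
    if (nrow(entry) >= 1L) {
      col <- entry$column[1L]
      if (col >= 1L && col <= length(labels)) sec <- labels[col]
      wt_match <- entry$aa_ref[1L] == mutations$wild_type[i]
    }
    out$residue[i] <- paste0(mutations$wild_type[i], pos,
                             mutations$variant[i])
    out$sector[i] <- sec
    out$region[i] <- classify_region(pos, scheme)
    out$phenotype[i] <- mutations$phenotype[i]
    out$domain_label[i] <- mutations$domain_label[i]
    out$wild_type_match[i] <- wt_match
  }
  out
}

#' Write an annotated mutation table
#'
#' TSV mirroring the Residue / Sector / Domain-Region / Phenotype layout,
#' plus the wild-type match flag; a `.json` extension writes the JSON twin.
#'
#' @param annotated data.frame from [annotate_mutations()].
#' @param path Output path (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_annotated_mutations <- function(annotated, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(annotated, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
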