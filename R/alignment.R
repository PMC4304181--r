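# Alignment container and FASTA input/output.
#
# An alignment is stored as an M x L character matrix of uppercase residues
# ('-' for gaps), with sequence ids as rownames and one row flagged as the
# reference. The reference row anchors trimming, column dropping and the
# later mapping onto structure residue numbers.

new_alignment <- function(mat, reference_id) {
  stopifnot(is.matrix(mat), is.character(mat))
  if (nrow(mat) < 1L || ncol(mat) < 1L) {
    stop("alignment must have at least one sequence and one column",
         call. = FALSE)
  }
  ids <- rownames(mat)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("all sequences must carry an id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(reference_id) && !reference_id %in% ids) {
    stop("reference not found: '", reference_id, "' is not a sequence id",
         call. = FALSE)
  }
  structure(
    list(seqs = mat, reference_id = reference_id),
    class = "sector_alignment"
  )
}

#' @export
print.sector_alignment <- function(x, ...) {
  cat("Multiple sequence alignment: ", nrow(x$seqs), " sequences x ",
      ncol(x$seqs), " columns\n", sep = "")
  if (!is.null(x$reference_id)) {
    cat("Reference: ", x$reference_id, "\n", sep = "")
  }
  invisible(x)
}

#' Number of sequences / columns of an alignment
#' @param aln A `sector_alignment`.
#' @return Integer count.
#' @export
n_sequences <- function(aln) nrow(aln$seqs)

#' @rdname n_sequences
#' @export
n_columns <- function(aln) ncol(aln$seqs)

#' Sequence ids of an alignment
#' @param aln A `sector_alignment`.
#' @return Character vector of ids.
#' @export
alignment_ids <- function(aln) rownames(aln$seqs)

#' Reference row of an alignment
#' @param aln A `sector_alignment` with a reference flagged.
#' @return Character vector of residues (length L) for the reference row.
#' @export
reference_row <- function(aln) {
  if (is.null(aln$reference_id)) {
    stop("alignment has no reference sequence flagged", call. = FALSE)
  }
  aln$seqs[aln$reference_id, ]
}

.normalize_residues <- function(x) {
  x <- toupper(x)
  x[x %in% GAP_CHARS] <- "-"
  x
}

#' Read an aligned FASTA file
#'
#' Parses an aligned FASTA file into the package's alignment container.
#' Residues are uppercased and '.' gap characters normalized to '-'. The
#' record named by `reference_id` is flagged as the reference sequence on
#' which trimming, column dropping and structure mapping are anchored.
#'
#' @param path Path to an aligned FASTA file (equal-length sequences).
#' @param reference_id Header token (first whitespace-delimited word of the
#'   FASTA header) of the reference sequence. `NULL` to leave unset.
#' @param min_sequences Emit a warning when fewer sequences are present;
#'   covariance estimates degrade on small alignments.
#' @return A `sector_alignment`.
#' @export
read_alignment <- function(path, reference_id = NULL, min_sequences = 100L) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("could not parse FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(widths), collapse = "-"), ")", call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  mat <- do.call(rbind, strsplit(as.character(set), "", fixed = TRUE))
  mat <- .normalize_residues(mat)
  rownames(mat) <- ids
  aln <- new_alignment(mat, reference_id)
  if (nrow(mat) < min_sequences) {
    warning("alignment has only ", nrow(mat), " sequences (fewer than ",
            min_sequences, "); coupling estimates may be unreliable",
            call. = FALSE)
  }
  aln
}

#' Build an alignment from in-memory sequences
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param reference_id Id of the reference sequence, or `NULL`.
#' @return A `sector_alignment`.
#' @export
alignment_from_strings <- function(seqs, reference_id = NULL) {
  if (length(seqs) == 0L) stop("no sequences given", call. = FALSE)
  if (is.null(names(seqs))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) {
    stop("ragged alignment: sequence lengths differ", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  mat <- .normalize_residues(mat)
  rownames(mat) <- names(seqs)
  new_alignment(mat, reference_id)
}

#' Write an alignment to FASTA
#'
#' @param aln A `sector_alignment`.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  seqs <- apply(aln$seqs, 1L, paste0, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Integer-encode an alignment: 1..20 per AMINO_ACIDS, 0 for gap and any
# non-standard residue ('X', 'B', 'Z', ...). The 0 class carries no
# frequency mass; regularization compensates.
alignment_codes <- function(aln) {
  codes <- match(aln$seqs, AMINO_ACIDS, nomatch = 0L)
  dim(codes) <- dim(aln$seqs)
  rownames(codes) <- rownames(aln$seqs)
  codes
}

# Ungapped residues of the reference row plus the 1-based alignment column
# of each reference position.
reference_positions <- function(aln) {
  ref <- reference_row(aln)
  keep <- which(ref != "-")
  if (length(keep) == 0L) {
    stop("reference sequence is entirely gaps", call. = FALSE)
  }
  list(residues = ref[keep], columns = keep)
}
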