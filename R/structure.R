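# Structure mapping: parse one chain from a PDB file and map alignment
# columns to author residue numbers via a global alignment of the ungapped
# reference sequence against the chain sequence.

#' Read one chain from a PDB file
#'
#' Residues are taken from ATOM coordinate records of the first model,
#' first alternate location only. Three-letter residue names are translated
#' to one-letter codes (selenomethionine and similar map to their parent
#' amino acid; unknowns become 'X'). A residue is identified by its author
#' residue number plus insertion code, so 100 and 100A are distinct.
#'
#' @param path Path to a PDB-format file.
#' @param chain_id Single chain identifier character.
#' @return A `structure_chain`: list with `chain_id` and `residues`, a
#'   data.frame with columns `resnum` (integer author number), `icode`
#'   (insertion code, "" when absent) and `aa` (one-letter code).
#' @export
read_chain <- function(path, chain_id) {
  lines <- readLines(path, warn = FALSE)
  # first model only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  atom <- lines[startsWith(lines, "ATOM")]
  if (length(atom) == 0L) {
    stop("no ATOM records in '", path, "'", call. = FALSE)
  }
  chains <- substr(atom, 22L, 22L)
  present <- unique(chains)
  if (!chain_id %in% chains) {
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(sort(present), collapse = ", "), call. = FALSE)
  }
  atom <- atom[chains == chain_id]
  resname <- trimws(substr(atom, 18L, 20L))
  resnum <- suppressWarnings(as.integer(trimws(substr(atom, 23L, 26L))))
  icode <- trimws(substr(atom, 27L, 27L))
  key <- paste(resnum, icode, sep = "|")
  # one row per residue; the first record seen carries the first alternate
  # location, which is the one retained
  ord <- which(!duplicated(key))
  res <- data.frame(
    resnum = resnum[ord],
    icode = icode[ord],
    aa = unname(AA_THREE_TO_ONE[resname[ord]]),
    stringsAsFactors = FALSE
  )
  res$aa[is.na(res$aa)] <- "X"
  if (anyDuplicated(paste(res$resnum, res$icode))) {
    stop("duplicate residue identifiers in chain ", chain_id, call. = FALSE)
  }
  if (nrow(res) == 0L) {
    stop("chain ", chain_id, " contains no amino-acid residues",
         call. = FALSE)
  }
  structure(list(chain_id = chain_id, residues = res),
            class = "structure_chain")
}

#' @export
print.structure_chain <- function(x, ...) {
  cat("Chain ", x$chain_id, ": ", nrow(x$residues), " residues (",
      x$residues$resnum[1L], "-",
      x$residues$resnum[nrow(x$residues)], ")\n", sep = "")
  invisible(x)
}

#' Chain sequence as a single string
#' @param chain A `structure_chain`.
#' @return One-letter sequence string.
#' @export
chain_sequence <- function(chain) paste0(chain$residues$aa, collapse = "")

#' Map alignment columns to structure residue numbers
#'
#' Globally aligns the ungapped reference sequence against the chain's
#' residue sequence (identity scoring, affine gap penalties) and pairs each
#' aligned reference position with an author residue number. Mismatched
#' pairings are flagged; when the mismatch fraction among paired positions
#' exceeds `max_mismatch_fraction` the reference and structure are deemed
#' to disagree and an error is raised.
#'
#' @param aln A `sector_alignment` with reference flagged.
#' @param chain A `structure_chain` from [read_chain()].
#' @param max_mismatch_fraction Tolerated fraction of mismatched paired
#'   positions.
#' @param numbering Optional data.frame (`position`, `resnum`) overriding
#'   the chain numbering for homology models: `position` is the 1-based
#'   index along the chain, `resnum` the desired author number.
#' @return A `structure_map`: list with `entries` (data.frame: `column` —
#'   1-based alignment column, `ref_pos` — 1-based ungapped reference
#'   position, `resnum`, `icode`, `aa_ref`, `aa_struct`, `match`) and
#'   `coverage` — mapped residues / chain residues.
#' @export
map_alignment_to_chain <- function(aln, chain, max_mismatch_fraction = 0.05,
                                   numbering = NULL) {
  refp <- reference_positions(aln)
  ref_seq <- paste0(refp$residues, collapse = "")
  ch_seq <- chain_sequence(chain)
  resnum <- chain$residues$resnum
  icode <- chain$residues$icode
  if (!is.null(numbering)) {
    stopifnot(all(c("position", "resnum") %in% names(numbering)))
    resnum[numbering$position] <- numbering$resnum
  }

  alphabet <- c(AMINO_ACIDS, "X")
  submat <- matrix(-1L, 21L, 21L, dimnames = list(alphabet, alphabet))
  diag(submat) <- 1L
  submat["X", "X"] <- 0L  # unknowns neither rewarded nor trusted
  pa <- Biostrings::pairwiseAlignment(
    pattern = ref_seq, subject = ch_seq, type = "global",
    substitutionMatrix = submat, gapOpening = 10, gapExtension = 0.5
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]

  ref_i <- 0L; ch_i <- 0L
  rows <- vector("list", length(p))
  n_pair <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") ref_i <- ref_i + 1L
    if (s[k] != "-") ch_i <- ch_i + 1L
    if (p[k] != "-" && s[k] != "-") {
      n_pair <- n_pair + 1L
      rows[[n_pair]] <- data.frame(
        column = refp$columns[ref_i],
        ref_pos = ref_i,
        resnum = resnum[ch_i],
        icode = icode[ch_i],
        aa_ref = p[k],
        aa_struct = s[k],
        match = p[k] == s[k],
        stringsAsFactors = FALSE
      )
    }
  }
  if (n_pair == 0L) {
    stop("reference/structure disagreement: no positions could be paired",
         call. = FALSE)
  }
  entries <- do.call(rbind, rows[seq_len(n_pair)])
  mismatch <- mean(!entries$match)
  if (mismatch > max_mismatch_fraction) {
    stop(sprintf(paste0("reference/structure disagreement: %.1f%% of paired",
                        " positions mismatch (tolerance %.1f%%)"),
                 100 * mismatch, 100 * max_mismatch_fraction),
         call. = FALSE)
  }
  structure(
    list(entries = entries,
         coverage = n_pair / nrow(chain$residues),
         chain_id = chain$chain_id),
    class = "structure_map"
  )
}

#' @export
print.structure_map <- function(x, ...) {
  cat("Structure map: ", nrow(x$entries), " alignment columns -> chain ",
      x$chain_id, " (coverage ", sprintf("%.1f%%", 100 * x$coverage),
      ")\n", sep = "")
  invisible(x)
}

#' Structural coverage of a mapping
#'
#' Fraction of the chain's residues that received an alignment column.
#'
#' @param smap A `structure_map`.
#' @param chain The `structure_chain` it was computed against.
#' @return Fraction in \[0, 1\].
#' @export
coverage_report <- function(smap, chain) {
  if (is.null(smap$entries) || nrow(smap$entries) == 0L) return(0)
  nrow(smap$entries) / nrow(chain$residues)
}

#' Write a structure map as TSV
#'
#' @param smap A `structure_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_structure_map <- function(smap, path) {
  utils::write.table(smap$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a structure map from TSV
#'
#' Inverse of [write_structure_map()]. Coverage cannot be recovered from
#' the table alone (the chain size is not stored) and is set to `NA`.
#'
#' @param path TSV path.
#' @param chain_id Chain identifier to record.
#' @return A `structure_map`.
#' @export
read_structure_map <- function(path, chain_id = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("column", "ref_pos", "resnum") %in% names(df)))
  if (is.null(df$icode)) df$icode <- ""
  df$icode[is.na(df$icode)] <- ""
  structure(list(entries = df, coverage = NA_real_, chain_id = chain_id),
            class = "structure_map")
}

#' Read an external numbering table
#'
#' TSV with columns `position` (1-based chain index) and `resnum` (desired
#' author number), used to renumber homology-model chains.
#'
#' @param path TSV path.
#' @return data.frame with `position` and `resnum`.
#' @export
read_numbering_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "resnum") %in% names(df)))
  df
}
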