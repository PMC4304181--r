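# Synthetic alignments with planted co-evolving sectors, toy PDB files and
# recovery scoring. All generators are pure functions of their parameters
# and seed, so the whole pipeline is testable without any downloads.

.draw_background <- function(n, q, seed_set = FALSE) {
  sample(AMINO_ACIDS, n, replace = TRUE, prob = q)
}

#' Generate an i.i.d. null alignment
#'
#' Every cell is drawn independently from the background distribution `q`:
#' no inter-column correlation and no conservation beyond background, the
#' null model against which sector detection is calibrated.
#'
#' @param M Number of sequences.
#' @param L Number of columns.
#' @param q Background distribution; defaults to [background_frequencies()].
#' @param seed Integer seed (required; generators are deterministic).
#' @return A `sector_alignment` without a reference flagged.
#' @export
generate_null_alignment <- function(M, L, q = background_frequencies(),
                                    seed) {
  stopifnot(M >= 1L, L >= 1L)
  q <- .assert_background(q)
  set.seed(seed)
  mat <- matrix(.draw_background(M * L, q), nrow = M, ncol = L)
  rownames(mat) <- sprintf("null%04d", seq_len(M))
  new_alignment(mat, reference_id = NULL)
}

#' Specification of a planted-sector alignment
#'
#' @param L,M Alignment dimensions.
#' @param sectors List of sector descriptions, each a list with `columns`
#'   (disjoint column sets), `rho` (coupling strength in \[0, 1\]) and
#'   `residues` (length-2 character: residue emitted in latent state 0 /
#'   state 1).
#' @param conserved List of conserved-column descriptions: `column`,
#'   `residue`, `level` (probability of emitting the residue).
#' @param q Background distribution.
#' @return A `planted_sector_spec`.
#' @export
planted_sector_spec <- function(L, M, sectors = list(), conserved = list(),
                                q = background_frequencies()) {
  q <- .assert_background(q)
  all_cols <- unlist(lapply(sectors, `[[`, "columns"))
  if (anyDuplicated(all_cols)) {
    stop("sector column sets overlap", call. = FALSE)
  }
  if (length(all_cols) && (min(all_cols) < 1L || max(all_cols) > L)) {
    stop("sector columns outside 1..L", call. = FALSE)
  }
  for (s in sectors) {
    if (s$rho < 0 || s$rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
    stopifnot(length(s$residues) == 2L, all(s$residues %in% AMINO_ACIDS))
  }
  structure(list(L = L, M = M, sectors = sectors, conserved = conserved,
                 q = q),
            class = "planted_sector_spec")
}

#' Default two-sector benchmark specification
#'
#' The package's standard validation world: M = 500 sequences, L = 100
#' columns, two disjoint 10-column sectors at coupling strength rho = 0.9,
#' and 5 conserved columns at conservation level 0.95. Desk-scale (seconds)
#' yet comfortably above the detection threshold of the method.
#'
#' @param M,L,rho,n_sector_cols,n_conserved Overridable benchmark
#'   parameters.
#' @return A `planted_sector_spec`.
#' @export
two_sector_benchmark <- function(M = 500L, L = 100L, rho = 0.9,
                                 n_sector_cols = 10L, n_conserved = 5L) {
  # spatially interleaved but disjoint column sets: sectors are scattered
  # along the sequence, as real sectors are along a structure
  spacing <- max(1L, (L - 4L) %/% (2L * n_sector_cols))
  s1_cols <- 2L + (seq_len(n_sector_cols) - 1L) * 2L * spacing
  s2_cols <- s1_cols + spacing
  stopifnot(max(s2_cols) <= L)
  free <- setdiff(seq_len(L), c(s1_cols, s2_cols))
  cons_cols <- utils::tail(free, n_conserved)
  planted_sector_spec(
    L = L, M = M,
    sectors = list(
      list(columns = s1_cols, rho = rho, residues = c("W", "H")),
      list(columns = s2_cols, rho = rho, residues = c("C", "M"))
    ),
    conserved = lapply(cons_cols, function(cc) {
      list(column = cc, residue = "G", level = 0.95)
    })
  )
}

#' Generate an alignment with planted sectors
#'
#' Two-state latent-variable emission model: every sequence draws one
#' latent binary state per sector; each sector column then emits that
#' sector's state-linked residue with probability `rho` and a background
#' draw otherwise. Columns in no sector are i.i.d. background; conserved
#' columns emit their residue at the stated level. A gap-free consensus row
#' is appended and flagged as the reference.
#'
#' @param spec A `planted_sector_spec`.
#' @param seed Integer seed.
#' @return List with `alignment` (a `sector_alignment`, reference id
#'   `"REF"`) and `truth` (integer vector of length L: sector id per
#'   column, 0 outside all sectors).
#' @export
generate_planted_alignment <- function(spec, seed) {
  stopifnot(inherits(spec, "planted_sector_spec"))
  set.seed(seed)
  M <- spec$M; L <- spec$L; q <- spec$q
  mat <- matrix(.draw_background(M * L, q), nrow = M, ncol = L)
  truth <- integer(L)
  for (sid in seq_along(spec$sectors)) {
    s <- spec$sectors[[sid]]
    truth[s$columns] <- sid
    state <- sample(0:1, M, replace = TRUE)
    for (cc in s$columns) {
      follow <- stats::runif(M) < s$rho
      mat[follow, cc] <- s$residues[state[follow] + 1L]
    }
  }
  for (cv in spec$conserved) {
    emit <- stats::runif(M) < cv$level
    mat[emit, cv$column] <- cv$residue
  }
  # consensus reference row (gap-free by construction)
  consensus <- apply(mat, 2L, function(col) {
    names(which.max(table(col)))
  })
  mat <- rbind(mat, consensus)
  rownames(mat) <- c(sprintf("sim%04d", seq_len(M)), "REF")
  list(alignment = new_alignment(mat, reference_id = "REF"), truth = truth)
}

#' Write a toy alpha-carbon PDB
#'
#' One CA atom per residue along a straight line (3.8 A spacing), with
#' author numbering starting at `start_number`. Parseable by
#' [read_chain()]; used to exercise structure mapping without downloads.
#'
#' @param sequence One-letter amino-acid string.
#' @param out Output PDB path.
#' @param start_number First author residue number.
#' @param chain Chain identifier.
#' @return `out`, invisibly.
#' @export
generate_toy_pdb <- function(sequence, out, start_number = 1L,
                             chain = "A") {
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!all(res %in% AMINO_ACIDS)) {
    stop("sequence contains non-standard residues: ",
         paste(unique(res[!res %in% AMINO_ACIDS]), collapse = ", "),
         call. = FALSE)
  }
  three <- names(AA_THREE_TO_ONE)[match(res, AA_THREE_TO_ONE)]
  lines <- character(length(res) + 1L)
  for (i in seq_along(res)) {
    lines[i] <- sprintf(
      "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      i, three[i], chain, start_number + i - 1L,
      3.8 * (i - 1L), 0, 0, 1, 0
    )
  }
  lines[length(lines)] <- "END"
  writeLines(lines, out)
  invisible(out)
}

#' Score sector recovery against planted truth
#'
#' Each detected sector is matched to the planted group with maximal
#' member overlap (greedy, in sector order; ties to the lower group id).
#' Precision is the fraction of assigned positions whose sector's matched
#' group truly contains them; recall is that same count over all planted
#' member positions. An empty assignment against nonempty truth scores
#' precision 0 with `empty_assignment = TRUE`.
#'
#' @param assignment A `sector_assignment`.
#' @param truth Integer vector (length L): planted sector id per column,
#'   0 = no sector.
#' @return List with `precision`, `recall`, `matches` (data.frame sector
#'   label / matched group / overlap) and `empty_assignment` flag.
#' @export
evaluate_recovery <- function(assignment, truth) {
  stopifnot(length(truth) == assignment$L)
  truth_groups <- setdiff(sort(unique(truth)), 0L)
  n_true <- sum(truth > 0L)
  if (length(assignment$sectors) == 0L) {
    return(list(precision = 0, recall = 0,
                matches = data.frame(sector = character(0),
                                     group = integer(0),
                                     overlap = integer(0)),
                empty_assignment = TRUE))
  }
  available <- truth_groups
  matches <- data.frame(sector = character(0), group = integer(0),
                        overlap = integer(0), stringsAsFactors = FALSE)
  correct <- 0L
  n_assigned <- 0L
  for (s in assignment$sectors) {
    n_assigned <- n_assigned + length(s$columns)
    if (length(available) == 0L) next
    overlaps <- vapply(available, function(g) {
      sum(truth[s$columns] == g)
    }, integer(1))
    g <- available[which.max(overlaps)]
    ov <- max(overlaps)
    matches <- rbind(matches,
                     data.frame(sector = s$label, group = g, overlap = ov,
                                stringsAsFactors = FALSE))
    correct <- correct + ov
    available <- setdiff(available, g)
  }
  list(
    precision = if (n_assigned > 0L) correct / n_assigned else 0,
    recall = if (n_true > 0L) correct / n_true else 0,
    matches = matches,
    empty_assignment = FALSE
  )
}
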