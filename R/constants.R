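# Alphabet and background composition constants shared across the package.

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. This ordering is the canonical
#' axis for every per-residue vector and frequency tensor in the package.
#'
#' @export
AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Three-letter -> one-letter translation for PDB residue names.
# Common modified residues are mapped to their parent amino acid.
AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
  MSE = "M", SEC = "C", PYL = "K"
)

#' Background amino-acid frequencies
#'
#' Average amino-acid composition of the UniProtKB/Swiss-Prot database,
#' normalized to sum exactly to one. Used as the default background
#' distribution `q` for conservation and coupling computations; override it
#' when a family-specific background is preferred.
#'
#' @return Named numeric vector of length 20 (names = [AMINO_ACIDS]),
#'   strictly positive, summing to 1.
#' @export
background_frequencies <- function() {
  # Swiss-Prot composition statistics (percent), alphabetical one-letter order
  pct <- c(
    A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86,
    G = 7.07, H = 2.27, I = 5.96, K = 5.84, L = 9.66,
    M = 2.42, N = 4.06, P = 4.70, Q = 3.93, R = 5.53,
    S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
  )
  pct / sum(pct)
}

# Fixed sector palette: red, blue, green first, then a documented extension.
SECTOR_PALETTE <- c(
  "red", "blue", "green", "yellow", "purple",
  "orange", "cyan", "magenta", "brown", "pink"
)

GAP_CHARS <- c("-", ".")

.assert_background <- function(q) {
  if (!is.numeric(q) || length(q) != 20L) {
    stop("background q must be a numeric vector of length 20", call. = FALSE)
  }
  if (abs(sum(q) - 1) > 1e-9) {
    stop("background q must sum to 1 within 1e-9 (got ", sum(q), ")",
         call. = FALSE)
  }
  if (any(q <= 0)) stop("background q must be strictly positive", call. = FALSE)
  q <- as.numeric(q)
  names(q) <- AMINO_ACIDS
  q
}
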