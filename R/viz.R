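# Visualization export: sector identity in the B-factor column of a PDB
# copy, and viewer scripts (Jmol, PyMOL) coloring each sector.

# residue number -> sector ordinal (1 = red, 2 = blue, ...) for mapped,
# insertion-code-free positions; 0 = unassigned
.sector_ordinals_by_resnum <- function(sectors, smap) {
  lab <- sector_labels(sectors)
  ords <- stats::setNames(seq_along(sectors$sectors),
                          vapply(sectors$sectors, `[[`, character(1),
                                 "label"))
  out <- integer(0)
  for (r in seq_len(nrow(smap$entries))) {
    e <- smap$entries[r, ]
    l <- lab[e$column]
    key <- paste0(e$resnum, e$icode)
    out[key] <- if (l == "-") 0L else unname(ords[l])
  }
  out
}

#' Write a sector-encoded PDB copy
#'
#' Copies the input PDB, replacing the temperature-factor (B-factor) field
#' of ATOM records in the chosen chain with the sector ordinal of the
#' residue (1 = red, 2 = blue, 3 = green, ..., 0 = unassigned or
#' unmapped). Every other byte of the file is preserved, so downstream
#' tools see an ordinary PDB.
#'
#' @param pdb_in Input PDB path.
#' @param chain_id Chain whose B-factors are rewritten.
#' @param sectors A `sector_assignment`.
#' @param smap The `structure_map` linking alignment columns to residue
#'   numbers.
#' @param out Output PDB path.
#' @return `out`, invisibly.
#' @export
write_sector_pdb <- function(pdb_in, chain_id, sectors, smap, out) {
  lines <- readLines(pdb_in, warn = FALSE)
  ords <- .sector_ordinals_by_resnum(sectors, smap)
  seen <- character(0)
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!startsWith(ln, "ATOM")) next
    if (substr(ln, 22L, 22L) != chain_id) next
    resnum <- trimws(substr(ln, 23L, 26L))
    icode <- trimws(substr(ln, 27L, 27L))
    key <- paste0(resnum, icode)
    val <- if (key %in% names(ords)) ords[[key]] else 0L
    seen <- c(seen, key)
    if (nchar(ln) < 66L) ln <- formatC(ln, width = -66L)
    substr(ln, 61L, 66L) <- sprintf("%6.2f", as.numeric(val))
    lines[k] <- ln
  }
  missing <- setdiff(names(ords)[ords > 0L], unique(seen))
  if (length(missing)) {
    warning("sector residue(s) absent from structure, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  writeLines(lines, out)
  invisible(out)
}

#' Read back per-residue sector ordinals from an encoded PDB
#'
#' Inverse of [write_sector_pdb()] for round-trip checks: the B-factor of
#' the first atom of each residue in the chain, as an integer ordinal.
#'
#' @param pdb Path to a sector-encoded PDB.
#' @param chain_id Chain to read.
#' @return Named integer vector (names = residue number + insertion code).
#' @export
read_sector_ordinals <- function(pdb, chain_id) {
  lines <- readLines(pdb, warn = FALSE)
  atom <- lines[startsWith(lines, "ATOM")]
  atom <- atom[substr(atom, 22L, 22L) == chain_id]
  key <- paste0(trimws(substr(atom, 23L, 26L)),
                trimws(substr(atom, 27L, 27L)))
  first <- !duplicated(key)
  vals <- as.numeric(substr(atom[first], 61L, 66L))
  stats::setNames(as.integer(round(vals)), key[first])
}

#' Write a viewer script coloring each sector
#'
#' Emits a Jmol (`.spt`) or PyMOL (`.pml`) script that selects each
#' sector's mapped residue numbers and colors them with the fixed palette
#' (red, blue, green, ...). Selections are emitted in sector order and
#' residue numbers in increasing order, so output is deterministic.
#'
#' @param sectors A `sector_assignment`.
#' @param smap A `structure_map`.
#' @param dialect `"jmol"` or `"pymol"`.
#' @param out Output script path.
#' @param chain_id Optional chain restriction written into the selections.
#' @return `out`, invisibly.
#' @export
write_viewer_script <- function(sectors, smap, dialect = c("jmol", "pymol"),
                                out, chain_id = NULL) {
  if (!is.character(dialect) || !dialect[1L] %in% c("jmol", "pymol")) {
    stop("unsupported dialect '", dialect[1L],
         "'; supported dialects: jmol, pymol", call. = FALSE)
  }
  dialect <- dialect[1L]
  lab <- sector_labels(sectors)
  lines <- c(
    paste0("# sector coloring script (", dialect, "), generated by ",
           "sectorscan"),
    "# palette: sector rank by eigenvalue -> red, blue, green, ..."
  )
  for (s in sectors$sectors) {
    cols <- s$columns
    resn <- sort(unique(
      smap$entries$resnum[smap$entries$column %in% cols &
                            smap$entries$icode == ""]))
    if (length(resn) == 0L) next
    if (dialect == "jmol") {
      sel <- paste(resn, collapse = ", ")
      if (!is.null(chain_id)) {
        sel <- paste(paste0(resn, ":", chain_id), collapse = ", ")
      }
      lines <- c(lines,
                 paste0("select ", sel, ";"),
                 paste0("color ", s$label, ";"))
    } else {
      sel <- paste(resn, collapse = "+")
      expr <- paste0("resi ", sel)
      if (!is.null(chain_id)) expr <- paste0("chain ", chain_id, " and ",
                                             expr)
      lines <- c(lines,
                 paste0("select sector_", s$label, ", ", expr),
                 paste0("color ", s$label, ", sector_", s$label))
    }
  }
  writeLines(lines, out)
  invisible(out)
}

#' Residue numbers selected by a viewer script
#'
#' Parses a script produced by [write_viewer_script()] back into the
#' per-sector residue sets (used for cross-dialect equivalence checks).
#'
#' @param path Script path.
#' @return Named list: sector label -> sorted integer residue numbers.
#' @export
read_viewer_selections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  pending <- NULL
  for (ln in lines) {
    if (grepl("^select sector_", ln)) {           # pymol
      label <- sub("^select sector_([a-z]+),.*$", "\\1", ln)
      nums <- sub(".*resi ", "", ln)
      out[[label]] <- sort(as.integer(strsplit(nums, "\\+")[[1]]))
    } else if (grepl("^select ", ln)) {           # jmol
      nums <- gsub("select |;|:[A-Za-z]", "", ln)
      pending <- sort(as.integer(strsplit(nums, ",\\s*")[[1]]))
    } else if (grepl("^color ", ln) && !is.null(pending)) {
      label <- sub("^color ([a-z]+)[;,].*$", "\\1",
                   paste0(ln, ";"))
      out[[label]] <- pending
      pending <- NULL
    }
  }
  out
}
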