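# ---- PDB-header LINK / LINKR records ----------------------------------------

#' Parse LINK and LINKR records from a PDB header
#'
#' Fixed-column parsing per the PDB v3.3 LINK layout (atom names in columns
#' 13-16 and 43-46, residue names 18-20 and 48-50, chains 22/52, sequence
#' numbers 23-26/53-56, distance in 74-78).  LINKR is the refinement
#' dialect of the record: same atom columns, with the link-entry id carried
#' in columns 73-80 in place of the distance.  Truncated records are
#' skipped with a warning rather than failing the whole header.
#'
#' @param text File path, single string, or character vector of lines.
#' @param source Label recorded per record (defaults to the file name);
#'   used by [tally_links()] to count distinct files.
#' @return Data frame with columns atom1, res1, chain1, seq1, atom2, res2,
#'   chain2, seq2, distance, link_id, source.
#' @export
parse_link_records <- function(text, source = NULL) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    if (is.null(source)) source <- basename(text)
    readLines(text)
  } else if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  if (is.null(source)) source <- "input"

  empty <- data.frame(atom1 = character(), res1 = character(),
                      chain1 = character(), seq1 = integer(),
                      atom2 = character(), res2 = character(),
                      chain2 = character(), seq2 = integer(),
                      distance = numeric(), link_id = character(),
                      source = character(), stringsAsFactors = FALSE)
  hits <- grep("^LINK( |R)", lines, value = TRUE)
  if (!length(hits)) return(empty)
  rows <- list()
  for (line in hits) {
    is_linkr <- startsWith(line, "LINKR")
    if (nchar(line) < 56L) {
      warning("skipping truncated LINK record: '", line, "'")
      next
    }
    fld <- function(a, b) trimws(substr(line, a, b))
    rec <- data.frame(
      atom1 = fld(13, 16), res1 = fld(18, 20), chain1 = fld(22, 22),
      seq1 = suppressWarnings(as.integer(fld(23, 26))),
      atom2 = fld(43, 46), res2 = fld(48, 50), chain2 = fld(52, 52),
      seq2 = suppressWarnings(as.integer(fld(53, 56))),
      distance = if (is_linkr) NA_real_
                 else suppressWarnings(as.numeric(fld(74, 78))),
      link_id = if (is_linkr) fld(73, 80) else NA_character_,
      source = source, stringsAsFactors = FALSE)
    if (!nzchar(rec$atom1) || !nzchar(rec$atom2) ||
          !nzchar(rec$res1) || !nzchar(rec$res2)) {
      warning("skipping LINK record with empty atom/residue fields")
      next
    }
    if (!is.na(rec$distance) && rec$distance <= 0) {
      warning("skipping LINK record with non-positive distance")
      next
    }
    rows[[length(rows) + 1L]] <- rec
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard amino-acid residue codes
#'
#' The 20 standard residues (selenomethionine included) plus, optionally,
#' the common D-amino-acid codes used in PDB depositions.
#'
#' @param include_d Include D-forms.
#' @return Character vector of three-letter codes.
#' @export
standard_amino_acids <- function(include_d = TRUE) {
  l <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "MSE", "PHE", "PRO", "SER", "THR",
         "TRP", "TYR", "VAL")
  d <- c("DAL", "DAR", "DSG", "DAS", "DCY", "DGN", "DGL", "DHI", "DIL",
         "DLE", "DLY", "MED", "DPN", "DPR", "DSN", "DTH", "DTR", "DTY",
         "DVA")
  if (include_d) c(l, d) else l
}

#' Filter LINK records down to special amino-amino linkages
#'
#' Keeps records where both residues are amino acids, then drops the two
#' record classes that describe ordinary polymer chemistry and are treated
#' as annotation mistakes when they appear in LINK records: main-chain
#' peptide bonds (atom names C and N, in either order) and cysteine
#' disulfides (both residues CYS, both atoms SG).
#'
#' @param records Data frame from [parse_link_records()].
#' @param amino_codes Amino-acid code set defining "amino acid".
#' @return The retained subset (a pure subset: no rows are altered).
#' @export
filter_amino_amino <- function(records,
                               amino_codes = standard_amino_acids()) {
  if (!nrow(records)) return(records)
  both_amino <- records$res1 %in% amino_codes & records$res2 %in% amino_codes
  peptide <- (records$atom1 == "C" & records$atom2 == "N") |
    (records$atom1 == "N" & records$atom2 == "C")
  disulf <- records$res1 == "CYS" & records$res2 == "CYS" &
    records$atom1 == "SG" & records$atom2 == "SG"
  records[both_amino & !peptide & !disulf, , drop = FALSE]
}

#' Tally linkage types
#'
#' A linkage type is the unordered canonical pair
#' ((residue, atom), (residue, atom)), sorted lexicographically, so a
#' record and its side-swapped duplicate count as the same type.  For each
#' type the total number of occurrences and the number of distinct source
#' files are reported.
#'
#' @param records Data frame from [parse_link_records()] (possibly
#'   filtered).
#' @return Data frame (type, res1, atom1, res2, atom2, n_files, n_total)
#'   sorted by decreasing n_files then n_total.
#' @export
tally_links <- function(records) {
  if (!nrow(records))
    return(data.frame(type = character(), res1 = character(),
                      atom1 = character(), res2 = character(),
                      atom2 = character(), n_files = integer(),
                      n_total = integer(), stringsAsFactors = FALSE))
  k1 <- paste(records$res1, records$atom1)
  k2 <- paste(records$res2, records$atom2)
  type <- paste(pmin(k1, k2), pmax(k1, k2), sep = " -- ")
  agg <- lapply(split(seq_along(type), type), function(i)
    data.frame(type = type[i[1]],
               n_files = length(unique(records$source[i])),
               n_total = length(i), stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  halves <- strsplit(out$type, " -- ", fixed = TRUE)
  first <- strsplit(vapply(halves, `[`, character(1), 1L), " ", fixed = TRUE)
  second <- strsplit(vapply(halves, `[`, character(1), 2L), " ", fixed = TRUE)
  out$res1 <- vapply(first, `[`, character(1), 1L)
  out$atom1 <- vapply(first, `[`, character(1), 2L)
  out$res2 <- vapply(second, `[`, character(1), 1L)
  out$atom2 <- vapply(second, `[`, character(1), 2L)
  out <- out[order(-out$n_files, -out$n_total, out$type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("type", "res1", "atom1", "res2", "atom2", "n_files", "n_total")]
}

#' Write a linkage tally as TSV
#'
#' @param tally Data frame from [tally_links()].
#' @param path Output file.
#' @export
write_links_tally <- function(tally, path) {
  utils::write.table(tally, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
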