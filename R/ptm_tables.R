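# Domain containers and file I/O for proteomes and PTM site tables.
#
# Coordinates are 1-based throughout, matching UniProt/PhosphoSitePlus
# conventions: position 1 is the first residue of the sequence.

MOD_KINDS <- c("phospho", "sulfoxide", "ubiquityl", "acetyl")
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a protein set
#'
#' A protein set is a tibble with one row per protein: `accession`,
#' `sequence` (upper-case amino-acid string; the 20 canonical letters plus
#' `X` for unknown), and `abundance` (positive, arbitrary units; `NA` when
#' unknown).
#'
#' @param accession Character vector of unique identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param abundance Optional numeric vector of positive abundances (`NA`
#'   allowed for proteins without data).
#' @return A tibble with columns `accession`, `sequence`, `abundance`,
#'   `length`.
#' @export
protein_set <- function(accession, sequence, abundance = NULL) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(sequence)) {
    stop("`accession` and `sequence` must have the same length")
  }
  if (anyDuplicated(accession)) {
    dup <- unique(accession[duplicated(accession)])
    stop("duplicate accession(s): ", paste(dup, collapse = ", "))
  }
  if (any(nchar(sequence) < 1)) stop("every sequence must have length >= 1")
  bad <- grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "X]"), sequence)
  if (any(bad)) {
    stop("invalid residue letters in sequence(s): ",
         paste(utils::head(accession[bad], 5), collapse = ", "))
  }
  if (is.null(abundance)) {
    abundance <- rep(NA_real_, length(accession))
  } else {
    abundance <- as.numeric(abundance)
    if (length(abundance) != length(accession)) {
      stop("`abundance` must match `accession` in length")
    }
    if (any(!is.na(abundance) & abundance <= 0)) {
      stop("abundances must be > 0 when present")
    }
  }
  tibble::tibble(
    accession = accession,
    sequence = sequence,
    abundance = abundance,
    length = nchar(sequence)
  )
}

#' Construct a PTM site table
#'
#' One row per modification observation: `accession`, 1-based `position`,
#' `residue` letter, `kind` (one of `phospho`, `sulfoxide`, `ubiquityl`,
#' `acetyl`) and, for sulfoxide rows, an optional `oxidized_fraction` in
#' \[0, 1\].
#'
#' @param accession,position,residue,kind Site fields (recycled to a common
#'   length by `tibble`).
#' @param oxidized_fraction Optional numeric in \[0, 1\]; `NA` elsewhere.
#' @return A tibble with the five columns above.
#' @export
site_table <- function(accession = character(), position = integer(),
                       residue = character(), kind = character(),
                       oxidized_fraction = NULL) {
  if (is.null(oxidized_fraction)) {
    oxidized_fraction <- rep(NA_real_, length(accession))
  }
  tbl <- tibble::tibble(
    accession = as.character(accession),
    position = as.integer(position),
    residue = toupper(as.character(residue)),
    kind = as.character(kind),
    oxidized_fraction = as.numeric(oxidized_fraction)
  )
  if (nrow(tbl) > 0) {
    if (any(is.na(tbl$position) | tbl$position < 1)) {
      stop("positions must be integers >= 1 (1-based coordinates)")
    }
    if (any(!tbl$kind %in% MOD_KINDS)) {
      stop("`kind` must be one of: ", paste(MOD_KINDS, collapse = ", "))
    }
    frac <- tbl$oxidized_fraction
    if (any(!is.na(frac) & (frac < 0 | frac > 1))) {
      stop("`oxidized_fraction` must lie in [0, 1]")
    }
  }
  tbl
}

#' Validate a site table against a protein set
#'
#' Drops rows whose accession is absent from `proteins` (with a warning
#' giving the count), then errors on rows whose `position` exceeds the
#' sequence length or whose `residue` letter does not match the sequence
#' (unless `action = "drop"`, in which case mismatches are dropped with a
#' warning). Duplicate `(accession, position, kind)` rows are collapsed to
#' one. Phospho sites are required to sit on S/T/Y and sulfoxide sites on M.
#'
#' @param sites A site table.
#' @param proteins A protein set.
#' @param action `"error"` (default) or `"drop"` for residue-mismatch rows.
#' @return The validated site table.
#' @export
validate_sites <- function(sites, proteins, action = c("error", "drop")) {
  action <- match.arg(action)
  known <- sites$accession %in% proteins$accession
  if (any(!known)) {
    warning(sum(!known), " site row(s) reference unknown accessions; dropped")
    sites <- sites[known, , drop = FALSE]
  }
  if (nrow(sites) == 0) return(sites)
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  lens <- nchar(seqs)[sites$accession]
  at <- substr(seqs[sites$accession], sites$position, sites$position)
  ok <- sites$position <= lens & at == sites$residue
  ok <- ok &
    !(sites$kind == "phospho" & !sites$residue %in% c("S", "T", "Y")) &
    !(sites$kind == "sulfoxide" & sites$residue != "M")
  if (any(!ok)) {
    if (action == "error") {
      bad <- which(!ok)[1]
      stop("site row ", bad, " (", sites$accession[bad], " ",
           sites$residue[bad], sites$position[bad], " ", sites$kind[bad],
           ") does not match the sequence")
    }
    warning(sum(!ok), " site row(s) failed residue/position validation; dropped")
    sites <- sites[ok, , drop = FALSE]
  }
  dplyr::distinct(sites, .data$accession, .data$position, .data$kind,
                  .keep_all = TRUE)
}

#' Load a proteome from FASTA (plus optional abundance TSV)
#'
#' @param fasta_path Path to a FASTA file; the accession is the first
#'   whitespace-delimited token of each header.
#' @param abundance_path Optional TSV with columns `accession`, `abundance`
#'   (tab-delimited, `#` comments ignored).
#' @return A protein set; proteins absent from the abundance table carry
#'   `NA` abundance.
#' @export
load_proteome <- function(fasta_path, abundance_path = NULL) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  if (length(aa) == 0) stop("no records in FASTA file: ", fasta_path)
  acc <- sub("\\s.*$", "", names(aa))
  prot <- protein_set(acc, as.character(aa))
  if (!is.null(abundance_path)) {
    ab <- readr::read_tsv(abundance_path, comment = "#",
                          col_types = readr::cols(
                            accession = readr::col_character(),
                            abundance = readr::col_double()
                          ))
    if (any(!is.na(ab$abundance) & ab$abundance <= 0)) {
      stop("abundances must be > 0")
    }
    prot$abundance <- ab$abundance[match(prot$accession, ab$accession)]
    n_missing <- sum(is.na(prot$abundance))
    if (n_missing > 0) {
      message(n_missing, " protein(s) without abundance data")
    }
  }
  prot
}

#' Load a PTM site table from TSV
#'
#' Expects a tab-delimited header `accession position residue kind
#' oxidized_fraction` (the last column optional); `#` lines are comments.
#' Rows on unknown accessions are dropped with a warning; residue-mismatch
#' rows are dropped with a warning (use [validate_sites()] directly for
#' strict behaviour).
#'
#' @param tsv_path Path to the TSV file.
#' @param proteins Protein set used for validation.
#' @return A validated site table.
#' @export
load_sites <- function(tsv_path, proteins) {
  raw <- readr::read_tsv(tsv_path, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("accession", "position", "residue", "kind")
  if (!all(required %in% names(raw))) {
    stop("site TSV must have columns: ", paste(required, collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(raw$position))
  if (any(is.na(pos) | pos != floor(pos))) {
    stop("malformed row: non-integer position in ", tsv_path)
  }
  frac <- if ("oxidized_fraction" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$oxidized_fraction))
  } else NULL
  sites <- site_table(raw$accession, pos, raw$residue, raw$kind, frac)
  validate_sites(sites, proteins, action = "drop")
}

#' Write a site table / protein set to disk
#'
#' `write_sites()` emits the tab-delimited site format [load_sites()] reads;
#' `write_proteome()` emits FASTA (and optionally the abundance TSV).
#'
#' @param sites A site table.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

#' @rdname write_sites
#' @param proteins A protein set.
#' @param fasta_path FASTA output path.
#' @param abundance_path Optional abundance TSV output path.
#' @export
write_proteome <- function(proteins, fasta_path, abundance_path = NULL) {
  aa <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                proteins$accession))
  Biostrings::writeXStringSet(aa, fasta_path)
  if (!is.null(abundance_path)) {
    keep <- !is.na(proteins$abundance)
    readr::write_tsv(proteins[keep, c("accession", "abundance")],
                     abundance_path)
  }
  invisible(fasta_path)
}

#' Curate sulfoxide sites by oxidized fraction
#'
#' Retains sulfoxide rows whose `oxidized_fraction` is at least
#' `min_fraction` (default 0.20, boundary inclusive); sulfoxide rows with no
#' recorded fraction are ambiguous and dropped with a warning giving the
#' count. Non-sulfoxide rows pass through untouched.
#'
#' @param sites A site table.
#' @param min_fraction Minimum oxidized fraction in \[0, 1\].
#' @return The curated site table.
#' @export
curate_metO <- function(sites, min_fraction = 0.20) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      is.na(min_fraction) || min_fraction < 0 || min_fraction > 1) {
    stop("`min_fraction` must be a single number in [0, 1]")
  }
  sulf <- sites$kind == "sulfoxide"
  ambiguous <- sulf & is.na(sites$oxidized_fraction)
  if (any(ambiguous)) {
    warning(sum(ambiguous),
            " sulfoxide row(s) without oxidized_fraction dropped as ambiguous")
  }
  keep <- !sulf | (!is.na(sites$oxidized_fraction) &
                     sites$oxidized_fraction >= min_fraction)
  sites[keep, , drop = FALSE]
}
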