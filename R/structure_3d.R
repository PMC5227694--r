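# Spatial Met -> phosphosite distances and secondary-structure
# tabulations for the structured-protein subset.
#
# PDB files are read/written with bio3d. DSSP output files (the classic
# fixed-column text the DSSP program prints) are parsed here; the DSSP
# algorithm itself is never re-derived.

ACCEPTOR_ATOMS <- c(S = "OG", T = "OG1", Y = "OH", M = "SD")
DSSP_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' Collapse an 8-state DSSP code to helix / strand / coil
#'
#' 3-10, alpha and pi helices (G, H, I) are `helix`; beta-sheet and
#' beta-bridge (E, B) are `strand`; turn, bend and coil (T, S, C) are
#' `coil`.
#'
#' @param dssp_code Character vector of single-letter DSSP codes.
#' @return Character vector of `"helix"`, `"strand"`, `"coil"`.
#' @export
ss_category <- function(dssp_code) {
  out <- rep(NA_character_, length(dssp_code))
  out[dssp_code %in% c("H", "G", "I")] <- "helix"
  out[dssp_code %in% c("E", "B")] <- "strand"
  out[dssp_code %in% c("T", "S", "C")] <- "coil"
  if (anyNA(out)) {
    stop("unknown DSSP code(s): ",
         paste(unique(dssp_code[is.na(out)]), collapse = ", "))
  }
  out
}

#' Write toy structures as PDB plus DSSP-style text
#'
#' Emits, per accession, `<accession>.pdb` with CA backbone atoms and the
#' relevant side-chain atom (SD for Met, OG/OG1/OH for Ser/Thr/Tyr), and
#' `<accession>.dssp` in the classic fixed-column DSSP output layout.
#'
#' @param structures Tibble from [simulate_structures()].
#' @param dir Output directory (created if needed).
#' @return Invisible tibble `accession` x `pdb_path` x `dssp_path`.
#' @export
write_structures <- function(structures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  accs <- unique(structures$accession)
  paths <- lapply(accs, function(acc) {
    s <- structures[structures$accession == acc, , drop = FALSE]
    pdb_path <- file.path(dir, paste0(acc, ".pdb"))
    dssp_path <- file.path(dir, paste0(acc, ".dssp"))
    has_side <- s$aa %in% names(ACCEPTOR_ATOMS)
    n_atoms <- nrow(s) + sum(has_side)
    xyz <- numeric(0); elety <- character(0); resno <- integer(0)
    resid <- character(0)
    for (i in seq_len(nrow(s))) {
      xyz <- c(xyz, s$bx[i], s$by[i], s$bz[i])
      elety <- c(elety, "CA")
      resno <- c(resno, s$residue_index[i])
      resid <- c(resid, bio3d::aa123(s$aa[i]))
      if (has_side[i]) {
        xyz <- c(xyz, s$sx[i], s$sy[i], s$sz[i])
        elety <- c(elety, ACCEPTOR_ATOMS[[s$aa[i]]])
        resno <- c(resno, s$residue_index[i])
        resid <- c(resid, bio3d::aa123(s$aa[i]))
      }
    }
    bio3d::write.pdb(file = pdb_path, xyz = xyz, elety = elety,
                     resno = resno, resid = resid,
                     chain = rep("A", n_atoms))
    write_dssp(s, dssp_path)
    tibble::tibble(accession = acc, pdb_path = pdb_path,
                   dssp_path = dssp_path)
  })
  invisible(dplyr::bind_rows(paths))
}

# Classic DSSP output layout: residues start after the "  #  RESIDUE AA"
# header line; residue number in columns 6-10, chain in 12, amino acid in
# 14, structure code in 17 (blank = coil).
write_dssp <- function(s, path) {
  header <- c(
    "==== Secondary Structure Definition, toy generator ====",
    sprintf("%5d%3d%3d%3d%3d    TOTAL NUMBER OF RESIDUES", nrow(s), 1, 0, 0, 0),
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"
  )
  code <- ifelse(s$dssp == "C", " ", s$dssp)
  body <- sprintf("%5d%5d %s %s  %s", seq_len(nrow(s)), s$residue_index,
                  "A", s$aa, code)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Parse a classic DSSP output file
#'
#' Reads the fixed-column residue block of DSSP text output. A blank
#' structure column is coil (`"C"`); chain-break rows (`!`) are skipped.
#'
#' @param path Path to a DSSP output file.
#' @return Tibble: `residue_index`, `chain`, `aa`, `dssp`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) != 1) stop("not a DSSP output file: ", path)
  body <- lines[-seq_len(start)]
  keep <- substr(body, 14, 14) != "!" &
    nzchar(trimws(substr(body, 6, 10)))
  body <- body[keep]
  code <- substr(body, 17, 17)
  code[code == " "] <- "C"
  tibble::tibble(
    residue_index = as.integer(substr(body, 6, 10)),
    chain = substr(body, 12, 12),
    aa = substr(body, 14, 14),
    dssp = code
  )
}

#' Read structures from PDB and DSSP files
#'
#' Joins, per accession, the CA backbone and the side-chain atom relevant
#' to the analysis (Met SD; Ser OG; Thr OG1; Tyr OH) with the DSSP code by
#' residue index. Residues whose side-chain atom is missing from the PDB
#' are kept but marked unresolved (side-chain coordinates `NA`) and the
#' count is reported; they are excluded from spatial distance analysis.
#' PDB residue numbers are shifted by `offset` (per-structure mapping) to
#' align with sequence coordinates.
#'
#' @param mapping Tibble/data.frame: `accession`, `pdb_path`, `dssp_path`,
#'   optional `chain` (default `"A"`) and `offset` (default 0; added to PDB
#'   residue numbers).
#' @param proteins A protein set; residues whose PDB amino acid disagrees
#'   with the sequence are dropped with a warning.
#' @return Tibble like [simulate_structures()] output, plus an
#'   `unresolved` logical column.
#' @export
read_structures <- function(mapping, proteins) {
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  out <- lapply(seq_len(nrow(mapping)), function(i) {
    acc <- mapping$accession[i]
    chain <- if ("chain" %in% names(mapping)) mapping$chain[i] else "A"
    offset <- if ("offset" %in% names(mapping)) mapping$offset[i] else 0L
    pdb <- bio3d::read.pdb(mapping$pdb_path[i], verbose = FALSE)
    at <- pdb$atom[pdb$atom$chain == chain, , drop = FALSE]
    at$resno <- at$resno + offset
    ca <- at[at$elety == "CA", , drop = FALSE]
    side <- at[at$elety %in% ACCEPTOR_ATOMS, , drop = FALSE]
    aa1 <- bio3d::aa321(ca$resid)
    # drop residues that disagree with the reference sequence
    chars <- strsplit(seqs[[acc]], "")[[1]]
    ok <- ca$resno >= 1 & ca$resno <= length(chars) &
      chars[pmax(pmin(ca$resno, length(chars)), 1)] == aa1
    if (any(!ok)) {
      warning(sum(!ok), " residue(s) of ", acc,
              " disagree with the sequence; dropped")
      ca <- ca[ok, , drop = FALSE]
      aa1 <- aa1[ok]
    }
    m <- match(ca$resno, side$resno)
    dssp <- read_dssp(mapping$dssp_path[i])
    dssp <- dssp[dssp$chain == chain | dssp$chain == " ", , drop = FALSE]
    dm <- match(ca$resno, dssp$residue_index + offset)
    needs_side <- aa1 %in% names(ACCEPTOR_ATOMS)
    unresolved <- needs_side & is.na(m)
    if (any(unresolved)) {
      message(sum(unresolved), " residue(s) of ", acc,
              " lack the required side-chain atom; excluded from spatial analysis")
    }
    tibble::tibble(
      accession = acc,
      residue_index = ca$resno,
      aa = aa1,
      bx = ca$x, by = ca$y, bz = ca$z,
      sx = side$x[m], sy = side$y[m], sz = side$z[m],
      dssp = ifelse(is.na(dm), "C", dssp$dssp[dm]),
      unresolved = unresolved
    )
  })
  dplyr::bind_rows(out)
}

#' Spatial distance to the nearest acceptor atom
#'
#' Minimum Euclidean distance from one methionine's sulfur coordinates to
#' the hydroxyl oxygens of a set of acceptors; ties resolve to the lowest
#' residue index.
#'
#' @param met_xyz Numeric length-3 vector (Met SD coordinates).
#' @param acceptors Tibble with `residue_index`, `sx`, `sy`, `sz`.
#' @return List with `distance` (Å) and `residue_index` of the closest
#'   acceptor, or `NA`s when no acceptor is resolved.
#' @export
spatial_nearest <- function(met_xyz, acceptors) {
  acceptors <- acceptors[!is.na(acceptors$sx), , drop = FALSE]
  if (nrow(acceptors) == 0) {
    return(list(distance = NA_real_, residue_index = NA_integer_))
  }
  acceptors <- acceptors[order(acceptors$residue_index), , drop = FALSE]
  d <- sqrt((acceptors$sx - met_xyz[1])^2 +
              (acceptors$sy - met_xyz[2])^2 +
              (acceptors$sz - met_xyz[3])^2)
  j <- which.min(d)  # first minimum = lowest residue index on ties
  list(distance = d[j], residue_index = acceptors$residue_index[j])
}

#' Structured-subset proximity analysis
#'
#' For every resolved methionine of every structure: the spatial distance
#' (Å) from its sulfur to the hydroxyl oxygen of the closest phosphosite,
#' the sequence distance to the closest phosphosite (same code path as the
#' primary-structure analysis), oxidation status, and the DSSP category.
#'
#' @param structures Structure tibble ([simulate_structures()] or
#'   [read_structures()]).
#' @param proteins A protein set.
#' @param sites A site table.
#' @return Tibble: `accession`, `met_position`, `met_oxidized`,
#'   `spatial_dist`, `seq_dist`, `dssp`, `ss_category`.
#' @export
structure_distances <- function(structures, proteins, sites) {
  if (!"unresolved" %in% names(structures)) structures$unresolved <- FALSE
  phospho <- sites[sites$kind == "phospho", , drop = FALSE]
  metO <- sites[sites$kind == "sulfoxide", , drop = FALSE]
  p_by_acc <- split(phospho$position, phospho$accession)
  o_by_acc <- split(metO$position, metO$accession)
  accs <- intersect(unique(structures$accession), names(p_by_acc))
  rows <- lapply(accs, function(acc) {
    s <- structures[structures$accession == acc, , drop = FALSE]
    ph <- p_by_acc[[acc]]
    acc_rows <- s[s$residue_index %in% ph & !s$unresolved, , drop = FALSE]
    mets <- s[s$aa == "M" & !s$unresolved, , drop = FALSE]
    if (nrow(mets) == 0) return(NULL)
    sp <- lapply(seq_len(nrow(mets)), function(j) {
      spatial_nearest(c(mets$sx[j], mets$sy[j], mets$sz[j]), acc_rows)
    })
    tibble::tibble(
      accession = acc,
      met_position = mets$residue_index,
      met_oxidized = mets$residue_index %in% o_by_acc[[acc]],
      spatial_dist = vapply(sp, `[[`, numeric(1), "distance"),
      seq_dist = vapply(mets$residue_index, nearest_distance, integer(1),
                        sites = ph),
      dssp = mets$dssp,
      ss_category = ss_category(mets$dssp)
    )
  })
  dplyr::bind_rows(rows)
}

#' Secondary-structure occupancy of Met vs MetO
#'
#' @param structure_dists Output of [structure_distances()].
#' @return Tibble `met_oxidized` x `dssp` x `n` x `proportion`; the
#'   proportions sum to 1 within each oxidation status.
#' @export
ss_proportions <- function(structure_dists) {
  out <- dplyr::count(structure_dists, .data$met_oxidized, .data$dssp)
  dplyr::mutate(dplyr::group_by(out, .data$met_oxidized),
                proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
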