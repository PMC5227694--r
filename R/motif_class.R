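# Kinase-motif decision tree for phosphoserine sites, window extraction,
# determinant-position tallies, and class-frequency tables.
#
# Windows are 15-character strings (offsets -7..+7 around the acceptor);
# positions beyond the protein termini are padded with "_", which never
# satisfies any residue rule.

PAD <- "_"
KINASE_CLASSES <- c("ProDirected", "Acidophilic", "Basophilic", "Others")

#' Extract a fixed-width sequence window
#'
#' @param sequence Amino-acid string.
#' @param center Center position (1-based).
#' @param halfwidth Half-width; the window has `2 * halfwidth + 1` slots.
#' @return A character string of length `2 * halfwidth + 1`, padded with
#'   `"_"` beyond the termini.
#' @export
extract_window <- function(sequence, center, halfwidth = 7) {
  L <- nchar(sequence)
  stopifnot(center >= 1, center <= L)
  pos <- (center - halfwidth):(center + halfwidth)
  chars <- rep(PAD, length(pos))
  ok <- pos >= 1 & pos <= L
  chars[ok] <- strsplit(substr(sequence, max(1, center - halfwidth),
                               min(L, center + halfwidth)), "")[[1]]
  paste(chars, collapse = "")
}

window_char <- function(window, offset, halfwidth = 7) {
  substr(window, halfwidth + 1 + offset, halfwidth + 1 + offset)
}

#' Classify a phosphoserine motif into a kinase class
#'
#' Binary decision tree, rules evaluated strictly in order with first match
#' winning:
#' 1. proline at P+1 -> `ProDirected`;
#' 2. 5 or more D/E within P+1..P+6 -> `Acidophilic`;
#' 3. R or K at P-3 -> `Basophilic`;
#' 4. D or E at P+1, P+2 or P+3 -> `Acidophilic`;
#' 5. 2 or more R/K within P-6..P-1 -> `Basophilic`;
#' 6. otherwise `Others`.
#'
#' Padding slots (`"_"`) never match any rule. The rule order matters: a
#' strongly acidic C-terminal stretch (rule 2) pre-empts a basic residue at
#' P-3 (rule 3).
#'
#' @param window A 15-character window string (see [extract_window()]).
#' @param allowed_center Residues accepted at the center (default `"S"`;
#'   add `"T"` to classify threonine sites with the same tree).
#' @return One of `"ProDirected"`, `"Acidophilic"`, `"Basophilic"`,
#'   `"Others"`.
#' @export
classify_pser_motif <- function(window, allowed_center = "S") {
  halfwidth <- (nchar(window) - 1) / 2
  stopifnot(nchar(window) %% 2 == 1)
  center <- window_char(window, 0, halfwidth)
  if (!center %in% allowed_center) {
    stop("window center '", center, "' is not an allowed phospho-acceptor")
  }
  at <- function(off) window_char(window, off, halfwidth)
  count_in <- function(offs, letters) {
    sum(vapply(offs, at, character(1)) %in% letters)
  }
  if (at(1) == "P") return("ProDirected")
  if (count_in(1:6, c("D", "E")) >= 5) return("Acidophilic")
  if (at(-3) %in% c("R", "K")) return("Basophilic")
  if (count_in(1:3, c("D", "E")) >= 1) return("Acidophilic")
  if (count_in(-(6:1), c("R", "K")) >= 2) return("Basophilic")
  "Others"
}

#' Classify many windows at once
#'
#' @param windows Character vector of window strings.
#' @inheritParams classify_pser_motif
#' @return Factor with levels `ProDirected`, `Acidophilic`, `Basophilic`,
#'   `Others`.
#' @export
classify_motifs <- function(windows, allowed_center = "S") {
  factor(vapply(windows, classify_pser_motif, character(1),
                allowed_center = allowed_center, USE.NAMES = FALSE),
         levels = KINASE_CLASSES)
}

#' Tally the offsets at which methionine appears in recognition motifs
#'
#' Patterns are one motif per line/element, aligned on the phospho-acceptor
#' marked with lowercase `s` or `t`; `X` is a wildcard, every other
#' uppercase letter a required residue (e.g. `"sXXXM"` puts M at P+4;
#' `"MQsF"` puts M at P-2).
#'
#' @param patterns Character vector of motif patterns.
#' @param halfwidth Offsets tallied run -halfwidth..+halfwidth.
#' @return Tibble `offset` x `n_motifs_with_met`.
#' @export
tally_determinant_positions <- function(patterns, halfwidth = 7) {
  offsets <- (-halfwidth):halfwidth
  counts <- stats::setNames(integer(length(offsets)), offsets)
  for (p in patterns) {
    chars <- strsplit(p, "")[[1]]
    acc <- which(chars %in% c("s", "t"))
    if (length(acc) != 1) {
      stop("pattern '", p, "' must mark exactly one acceptor with 's' or 't'")
    }
    met_off <- which(chars == "M") - acc
    met_off <- met_off[met_off >= -halfwidth & met_off <= halfwidth]
    counts[as.character(met_off)] <- counts[as.character(met_off)] + 1L
  }
  tibble::tibble(offset = offsets, n_motifs_with_met = unname(counts))
}

#' Read a motif pattern file
#'
#' One pattern per line; `#` lines and blank lines are ignored.
#'
#' @param path Path to the pattern file.
#' @return Character vector of patterns.
#' @export
read_patterns <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Kinase-class frequencies across named window subsets
#'
#' @param subsets Named list of character vectors of window strings (each
#'   non-empty), e.g. all pSer windows, pSer with MetO at P+1, ...
#' @inheritParams classify_pser_motif
#' @return Tibble `subset` x `class` x `n` x `frequency`; frequencies sum
#'   to 1 within each subset.
#' @export
class_frequencies <- function(subsets, allowed_center = "S") {
  stopifnot(length(subsets) >= 1, !is.null(names(subsets)))
  rows <- lapply(names(subsets), function(nm) {
    w <- subsets[[nm]]
    if (length(w) == 0) stop("empty subset: ", nm)
    cls <- classify_motifs(w, allowed_center)
    tab <- table(cls)
    tibble::tibble(subset = nm, class = names(tab), n = as.integer(tab),
                   frequency = as.numeric(tab) / length(w))
  })
  out <- dplyr::bind_rows(rows)
  out$class <- factor(out$class, levels = KINASE_CLASSES)
  out
}

#' Phosphoserine window subsets used in the crosstalk analysis
#'
#' Builds the standard comparison subsets from a proteome and site table:
#' all pSer windows; pSer from the MetO-proteome (proteins with at least
#' one sulfoxide site); pSer with a MetO within ±`halfwidth`; pSer with a
#' MetO at P+1; and pSer with a MetO at P+4. Subsets with no members are
#' omitted.
#'
#' @param proteins A protein set.
#' @param sites A site table.
#' @param halfwidth Window half-width.
#' @return Named list of window-string vectors.
#' @export
pser_window_subsets <- function(proteins, sites, halfwidth = 7) {
  pser <- sites[sites$kind == "phospho" & sites$residue == "S", , drop = FALSE]
  metO <- sites[sites$kind == "sulfoxide", , drop = FALSE]
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  pser <- pser[pser$accession %in% names(seqs), , drop = FALSE]
  wins <- vapply(seq_len(nrow(pser)), function(i) {
    extract_window(seqs[[pser$accession[i]]], pser$position[i], halfwidth)
  }, character(1))
  o_by_acc <- split(metO$position, metO$accession)
  meto_dist <- vapply(seq_len(nrow(pser)), function(i) {
    oxs <- o_by_acc[[pser$accession[i]]]
    if (is.null(oxs) || length(oxs) == 0) return(NA_integer_)
    as.integer(min(abs(oxs - pser$position[i])))
  }, integer(1))
  meto_at <- function(off) {
    vapply(seq_len(nrow(pser)), function(i) {
      oxs <- o_by_acc[[pser$accession[i]]]
      !is.null(oxs) && (pser$position[i] + off) %in% oxs
    }, logical(1))
  }
  subsets <- list(
    all_pser = wins,
    meto_proteome_pser = wins[pser$accession %in% unique(metO$accession)],
    meto_within_7 = wins[!is.na(meto_dist) & meto_dist <= halfwidth],
    meto_at_p1 = wins[meto_at(1)],
    meto_at_p4 = wins[meto_at(4)]
  )
  subsets[vapply(subsets, length, integer(1)) > 0]
}
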