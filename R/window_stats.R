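# Met / MetO counts in +/-7 windows around phospho-acceptors, their
# acceptor-resampling nulls, and positional frequency profiles P-7..P+7.

#' Count methionines in a window around one acceptor
#'
#' Counts total methionines (`n_met`, oxidized or not) and oxidized
#' methionines (`n_metO`) at offsets -halfwidth..-1 and +1..+halfwidth from
#' `center` (the center itself is excluded); windows are truncated at the
#' protein termini.
#'
#' @param seq_length Length of the protein sequence.
#' @param center Acceptor position (1-based).
#' @param met_positions Positions of all methionines in the protein.
#' @param metO_positions Positions of the oxidized methionines.
#' @param halfwidth Window half-width in residues.
#' @return List with `n_met` and `n_metO`.
#' @export
count_window <- function(seq_length, center, met_positions, metO_positions,
                         halfwidth = 7) {
  stopifnot(center >= 1, center <= seq_length)
  lo <- max(1, center - halfwidth)
  hi <- min(seq_length, center + halfwidth)
  in_win <- function(p) p >= lo & p <= hi & p != center
  list(n_met = sum(in_win(met_positions)),
       n_metO = sum(in_win(metO_positions)))
}

#' Window counts for every phospho-acceptor of a proteome
#'
#' One row per S/T/Y residue of every protein in `proteins`, with its
#' phospho status and the Met/MetO counts in the ±`halfwidth` window.
#' Restrict `proteins` first (e.g. to the MetO phosphoproteome) to
#' reproduce a curated-set analysis.
#'
#' @param proteins A protein set.
#' @param sites A site table.
#' @param halfwidth Window half-width in residues.
#' @return Tibble: `accession`, `acceptor_position`, `acceptor_residue`,
#'   `is_phosphosite`, `n_met`, `n_metO`.
#' @export
acceptor_windows <- function(proteins, sites, halfwidth = 7) {
  phospho <- sites[sites$kind == "phospho", , drop = FALSE]
  metO <- sites[sites$kind == "sulfoxide", , drop = FALSE]
  p_by_acc <- split(phospho$position, phospho$accession)
  o_by_acc <- split(metO$position, metO$accession)
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    acc <- proteins$accession[i]
    chars <- strsplit(proteins$sequence[i], "")[[1]]
    acceptors <- which(chars %in% c("S", "T", "Y"))
    if (length(acceptors) == 0) return(NULL)
    oxs <- o_by_acc[[acc]]
    if (is.null(oxs)) oxs <- integer(0)
    L <- length(chars)
    # windowed counts via cumulative sums; the center is S/T/Y, never M,
    # so it can't contribute to either count
    cum_met <- c(0, cumsum(chars == "M"))
    is_ox <- integer(L)
    is_ox[oxs] <- 1L
    cum_ox <- c(0, cumsum(is_ox))
    lo <- pmax(1L, acceptors - halfwidth)
    hi <- pmin(L, acceptors + halfwidth)
    list(
      accession = rep(acc, length(acceptors)),
      acceptor_position = acceptors,
      acceptor_residue = chars[acceptors],
      is_phosphosite = acceptors %in% p_by_acc[[acc]],
      n_met = as.integer(cum_met[hi + 1] - cum_met[lo]),
      n_metO = as.integer(cum_ox[hi + 1] - cum_ox[lo])
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(tibble::tibble(accession = character(),
                          acceptor_position = integer(),
                          acceptor_residue = character(),
                          is_phosphosite = logical(),
                          n_met = integer(), n_metO = integer()))
  }
  tibble::tibble(
    accession = unlist(lapply(rows, `[[`, "accession")),
    acceptor_position = unlist(lapply(rows, `[[`, "acceptor_position")),
    acceptor_residue = unlist(lapply(rows, `[[`, "acceptor_residue")),
    is_phosphosite = unlist(lapply(rows, `[[`, "is_phosphosite")),
    n_met = unlist(lapply(rows, `[[`, "n_met")),
    n_metO = unlist(lapply(rows, `[[`, "n_metO"))
  )
}

#' Mean Met and MetO per site over a set of windows
#'
#' @param windows Rows of an [acceptor_windows()] table.
#' @return List with `mean_met` and `mean_metO`.
#' @export
mean_per_site <- function(windows) {
  if (nrow(windows) == 0) stop("empty window subset")
  list(mean_met = mean(windows$n_met), mean_metO = mean(windows$n_metO))
}

#' Acceptor-resampling null for a mean window count
#'
#' Each sample draws `n_phospho` acceptors uniformly without replacement
#' from all acceptors of one residue type (regardless of phospho status)
#' and records the mean window count, giving the null distribution of the
#' per-phosphosite mean under no association with phosphorylation.
#'
#' @param windows [acceptor_windows()] rows for one acceptor residue type.
#' @param n_phospho Sample size (number of phosphosites of that type).
#' @param statistic `"n_met"` or `"n_metO"`.
#' @param n_samples Number of resamples.
#' @param seed Integer seed.
#' @return A [null_distribution()].
#' @export
acceptor_null <- function(windows, n_phospho, statistic = c("n_met", "n_metO"),
                          n_samples = 10000, seed = 1L) {
  statistic <- match.arg(statistic)
  x <- windows[[statistic]]
  if (n_phospho > length(x)) stop("n_phospho exceeds the acceptor count")
  set.seed(seed)
  vals <- vapply(seq_len(n_samples), function(i) {
    mean(x[sample.int(length(x), n_phospho)])
  }, numeric(1))
  null_distribution(vals, paste0("mean_", statistic, "_per_site"), seed = seed,
                    constraint = paste0("uniform samples of ", n_phospho,
                                        " from ", length(x), " acceptors"))
}

#' Positional Met / MetO profile around phosphosites
#'
#' For offsets -halfwidth..-1, +1..+halfwidth around phosphosites of one
#' residue type: the methionine frequency (percent of windows with M at
#' that offset, denominator restricted to windows where the offset lies
#' inside the protein) and the MetO count per 500 phosphosites. The control
#' band is mean ± SD of the per-offset Met frequencies around
#' non-phosphorylated acceptors of the same residue type (pooled across
#' offsets by default; per-offset bands are returned alongside).
#'
#' @param proteins A protein set.
#' @param sites A site table.
#' @param site_residue `"S"`, `"T"` or `"Y"`.
#' @param halfwidth Window half-width.
#' @param controls If `FALSE`, skip the control-acceptor tally (profile
#'   columns and band are `NA`); useful in replicated simulations that only
#'   rank the phosphosite-side profile.
#' @return List with `profile` (tibble: offset, met_freq_percent,
#'   metO_per_500, control_freq_percent), `control_band` (pooled mean ± sd),
#'   `n_phosphosites`, `n_controls`.
#' @export
positional_profile <- function(proteins, sites, site_residue = "S",
                               halfwidth = 7, controls = TRUE) {
  stopifnot(site_residue %in% c("S", "T", "Y"))
  phospho <- sites[sites$kind == "phospho" & sites$residue == site_residue, ,
                   drop = FALSE]
  metO <- sites[sites$kind == "sulfoxide", , drop = FALSE]
  if (nrow(phospho) == 0) stop("no phosphosites of residue ", site_residue)
  p_by_acc <- split(phospho$position, phospho$accession)
  o_by_acc <- split(metO$position, metO$accession)
  offsets <- c(-(halfwidth:1), 1:halfwidth)

  tally <- function(centers_by_acc) {
    m_counts <- stats::setNames(numeric(length(offsets)), offsets)
    o_counts <- m_counts
    denom <- m_counts
    n_windows <- 0
    for (acc in names(centers_by_acc)) {
      row <- match(acc, proteins$accession)
      if (is.na(row)) next
      chars <- strsplit(proteins$sequence[row], "")[[1]]
      L <- length(chars)
      oxs <- o_by_acc[[acc]]
      for (center in centers_by_acc[[acc]]) {
        n_windows <- n_windows + 1
        pos <- center + offsets
        ok <- pos >= 1 & pos <= L
        denom[ok] <- denom[ok] + 1
        is_m <- ok & chars[pmax(pmin(pos, L), 1)] == "M"
        m_counts[is_m] <- m_counts[is_m] + 1
        if (!is.null(oxs)) {
          is_o <- is_m & pos %in% oxs
          o_counts[is_o] <- o_counts[is_o] + 1
        }
      }
    }
    list(m = m_counts, o = o_counts, denom = denom, n = n_windows)
  }

  ph <- tally(p_by_acc)
  if (controls) {
    # controls: same residue type, never phosphorylated
    ctrl_by_acc <- lapply(stats::setNames(proteins$accession,
                                          proteins$accession), function(acc) {
      chars <- strsplit(proteins$sequence[match(acc, proteins$accession)],
                        "")[[1]]
      setdiff(which(chars == site_residue), p_by_acc[[acc]])
    })
    ctrl_by_acc <- ctrl_by_acc[vapply(ctrl_by_acc, length, integer(1)) > 0]
    ct <- tally(ctrl_by_acc)
    ctrl_freq <- 100 * ct$m / pmax(ct$denom, 1)
    band <- c(lower = mean(ctrl_freq) - stats::sd(ctrl_freq),
              upper = mean(ctrl_freq) + stats::sd(ctrl_freq))
    n_controls <- ct$n
  } else {
    ctrl_freq <- rep(NA_real_, length(offsets))
    band <- c(lower = NA_real_, upper = NA_real_)
    n_controls <- 0
  }

  met_freq <- 100 * ph$m / pmax(ph$denom, 1)
  profile <- tibble::tibble(
    offset = offsets,
    met_freq_percent = unname(met_freq),
    metO_per_500 = unname(500 * ph$o / ph$n),
    control_freq_percent = unname(ctrl_freq)
  )
  list(
    profile = profile,
    control_band = band,
    n_phosphosites = ph$n,
    n_controls = n_controls
  )
}
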