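# Sequence-distance statistics between methionines and phosphosites, and
# phosphosite cluster counts around methionines.
#
# Distance is the positional difference |i - j| in residues (not the count
# of intervening residues).

#' Distance from a position to the nearest site
#'
#' @param pos Integer position (1-based).
#' @param sites Integer vector of site positions (possibly empty).
#' @return `min |pos - s|`, or `NA` when `sites` is empty.
#' @export
nearest_distance <- function(pos, sites) {
  stopifnot(pos >= 1)
  if (length(sites) == 0) return(NA_integer_)
  as.integer(min(abs(pos - sites)))
}

#' Methionine-to-site distance records
#'
#' For every methionine of every protein that carries at least one
#' phosphosite, computes the distance to the closest site of each kind:
#' `pSer`, `pThr`, `pTyr`, `any_pSite` (any phosphosite), and
#' `nonP_acceptor` (closest S/T/Y never reported phosphorylated). The
#' record is `NA` when the protein has no site of that kind; such
#' methionines are excluded from that kind's comparison (see `coverage`).
#'
#' @param proteins A protein set.
#' @param sites A site table (phospho + sulfoxide rows; curated).
#' @return List with `records` (tibble: `accession`, `met_position`,
#'   `met_oxidized`, `site_kind`, `distance`) and `coverage` (per-kind
#'   counts of methionines with/without a defined distance).
#' @export
distance_tables <- function(proteins, sites) {
  phospho <- sites[sites$kind == "phospho", , drop = FALSE]
  metO <- sites[sites$kind == "sulfoxide", , drop = FALSE]
  phospho_prot <- unique(phospho$accession)
  keep <- proteins[proteins$accession %in% phospho_prot, , drop = FALSE]

  p_by_acc <- split(phospho, phospho$accession)
  o_by_acc <- split(metO$position, metO$accession)

  kinds <- c("pSer", "pThr", "pTyr", "any_pSite", "nonP_acceptor")
  rows <- vector("list", nrow(keep))
  for (i in seq_len(nrow(keep))) {
    acc <- keep$accession[i]
    chars <- strsplit(keep$sequence[i], "")[[1]]
    mets <- which(chars == "M")
    if (length(mets) == 0) next
    ph <- p_by_acc[[acc]]
    kind_sites <- list(
      pSer = ph$position[ph$residue == "S"],
      pThr = ph$position[ph$residue == "T"],
      pTyr = ph$position[ph$residue == "Y"],
      any_pSite = ph$position,
      nonP_acceptor = setdiff(which(chars %in% c("S", "T", "Y")),
                              ph$position)
    )
    ox <- mets %in% o_by_acc[[acc]]
    nm <- length(mets)
    rows[[i]] <- list(
      accession = rep(acc, nm * 5L),
      met_position = rep(mets, 5L),
      met_oxidized = rep(ox, 5L),
      site_kind = rep(kinds, each = nm),
      distance = unlist(lapply(kind_sites, function(s) {
        if (length(s) == 0) return(rep(NA_integer_, nm))
        vapply(mets, function(m) min(abs(m - s)), numeric(1))
      }), use.names = FALSE)
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  records <- if (length(rows) == 0) {
    tibble::tibble(accession = character(), met_position = integer(),
                   met_oxidized = logical(), site_kind = character(),
                   distance = integer())
  } else {
    tibble::tibble(
      accession = unlist(lapply(rows, `[[`, "accession")),
      met_position = unlist(lapply(rows, `[[`, "met_position")),
      met_oxidized = unlist(lapply(rows, `[[`, "met_oxidized")),
      site_kind = unlist(lapply(rows, `[[`, "site_kind")),
      distance = as.integer(unlist(lapply(rows, `[[`, "distance")))
    )
  }
  coverage <- dplyr::summarise(
    dplyr::group_by(records, .data$site_kind),
    n_met = dplyr::n(),
    n_defined = sum(!is.na(.data$distance)),
    n_excluded = sum(is.na(.data$distance)),
    .groups = "drop"
  )
  list(records = records, coverage = coverage)
}

#' Proportion of distances below a threshold
#'
#' "Less than `threshold` residues away" is strict: with the default
#' threshold of 7 a distance of 6 counts, 7 does not. `NA` distances (no
#' site of the queried kind) are removed first.
#'
#' @param distances Integer vector.
#' @param threshold Strict upper bound (residues).
#' @return Fraction of distances `< threshold`.
#' @export
proportion_within <- function(distances, threshold = 7) {
  distances <- distances[!is.na(distances)]
  if (length(distances) == 0) stop("no defined distances")
  mean(distances < threshold)
}

#' Compare MetO vs Met distances to the nearest phosphosite
#'
#' Summarises the distance records of one site kind: mean distances, Welch
#' t-test on the distances, proportions within `threshold`, and the
#' Yates-corrected two-proportion test on those proportions.
#'
#' @param records Distance records from [distance_tables()].
#' @param site_kind Which site kind to compare (default `any_pSite`).
#' @param threshold Strict distance threshold for the proportion comparison.
#' @return A one-row tibble of summary statistics.
#' @export
compare_met_meto <- function(records, site_kind = "any_pSite", threshold = 7) {
  r <- records[records$site_kind == site_kind & !is.na(records$distance), ,
               drop = FALSE]
  d_ox <- r$distance[r$met_oxidized]
  d_un <- r$distance[!r$met_oxidized]
  if (length(d_ox) < 2 || length(d_un) < 2) {
    stop("need at least 2 oxidized and 2 non-oxidized methionines")
  }
  wt <- welch_t(d_ox, d_un)
  x1 <- sum(d_ox < threshold); x2 <- sum(d_un < threshold)
  pt <- two_prop_yates(x1, length(d_ox), x2, length(d_un))
  tibble::tibble(
    site_kind = site_kind,
    n_metO = length(d_ox), n_met = length(d_un),
    mean_dist_metO = mean(d_ox), mean_dist_met = mean(d_un),
    welch_t = wt$t, welch_p = wt$p,
    prop_within_metO = x1 / length(d_ox),
    prop_within_met = x2 / length(d_un),
    yates_chi2 = pt$chi2, yates_p = pt$p
  )
}

#' Phosphosite counts around methionines
#'
#' For each methionine, counts the phosphosites within `radius` residues
#' (`|delta| <= radius`; set `radius = 5` for the half-window reading of a
#' "10 residue window").
#'
#' @param met_positions Integer vector of methionine positions.
#' @param phospho_positions Integer vector of phosphosite positions.
#' @param radius Inclusive radius in residues.
#' @return Integer vector of counts, one per methionine.
#' @export
cluster_counts <- function(met_positions, phospho_positions, radius = 10) {
  stopifnot(radius >= 1)
  if (length(met_positions) == 0) return(integer(0))
  vapply(met_positions, function(m) {
    sum(abs(m - phospho_positions) <= radius)
  }, integer(1))
}

#' Histogram of phosphosite cluster counts, split by oxidation status
#'
#' @param proteins A protein set.
#' @param sites A site table.
#' @param radius Inclusive radius in residues.
#' @return Tibble `met_oxidized` x `n_phosphosites` x `n_met` (one row per
#'   observed count value and oxidation status).
#' @export
cluster_histogram <- function(proteins, sites, radius = 10) {
  phospho <- sites[sites$kind == "phospho", , drop = FALSE]
  metO <- sites[sites$kind == "sulfoxide", , drop = FALSE]
  keep <- proteins[proteins$accession %in% unique(phospho$accession), ,
                   drop = FALSE]
  p_by_acc <- split(phospho$position, phospho$accession)
  o_by_acc <- split(metO$position, metO$accession)
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    acc <- keep$accession[i]
    chars <- strsplit(keep$sequence[i], "")[[1]]
    mets <- which(chars == "M")
    if (length(mets) == 0) return(NULL)
    list(met_oxidized = mets %in% o_by_acc[[acc]],
         n_phosphosites = cluster_counts(mets, p_by_acc[[acc]], radius))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  flat <- tibble::tibble(
    met_oxidized = unlist(lapply(rows, `[[`, "met_oxidized")),
    n_phosphosites = unlist(lapply(rows, `[[`, "n_phosphosites"))
  )
  dplyr::count(flat, .data$met_oxidized, .data$n_phosphosites,
               name = "n_met")
}
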