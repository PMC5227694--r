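# Synthetic proteome generator.
#
# Emulates the statistical structure the analyses assume: residue
# composition with rare methionine (~2.3% of residues), log-normal protein
# abundances, phosphosite placement on S/T/Y, per-methionine oxidation with
# a tunable proximity-to-phosphosite effect on the odds scale, correlated
# per-protein ubiquitination/acetylation flags, and toy 3D structures with
# secondary-structure labels. Planted effects (proximity_odds,
# positional_boost, ptm_corr_odds) exist so calibration and power studies
# can turn them off (neutral value 1 / NULL) or up.

# Human-like background composition; Met fixed at 2.3% of residues.
DEFAULT_COMPOSITION <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
  Q = 0.048, E = 0.071, G = 0.066, H = 0.026, I = 0.043,
  L = 0.099, K = 0.057, M = 0.023, F = 0.037, P = 0.063,
  S = 0.083, T = 0.053, W = 0.012, Y = 0.027, V = 0.060
)

#' Simulation configuration
#'
#' @param n_proteins Number of proteins to generate.
#' @param length_mean,length_dispersion Protein length law: negative
#'   binomial with mean `length_mean` and size `length_dispersion`
#'   (`Inf` = every protein exactly `length_mean` residues), floored at
#'   `length_min`.
#' @param length_min Minimum protein length.
#' @param composition Named residue-frequency vector summing to 1; the
#'   default uses human-like frequencies with methionine at 2.3%.
#' @param p_phospho Named base phosphorylation probabilities for S, T, Y.
#' @param p_oxidize_base Baseline per-methionine oxidation probability.
#' @param proximity_odds Odds multiplier for oxidation of a methionine
#'   within `proximity_radius` residues of a phosphosite (1 = no effect).
#' @param proximity_radius Sequence radius (residues) defining "near".
#' @param positional_boost Optional named numeric, e.g. `c("+1" = 6, "+4" =
#'   6)`: multiplies the phosphorylation probability of a serine when a
#'   methionine sits at the given offset from it (`NULL` = off).
#' @param p_ubiq,p_acetyl Per-protein baseline probabilities of carrying a
#'   ubiquitination / acetylation site.
#' @param ptm_corr_odds Odds multiplier on `p_ubiq`/`p_acetyl` for proteins
#'   that carry at least one MetO (1 = independent).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance law
#'   (natural-log scale).
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 200,
                       length_mean = 450, length_dispersion = 2.5,
                       length_min = 50,
                       composition = DEFAULT_COMPOSITION,
                       p_phospho = c(S = 0.08, T = 0.04, Y = 0.03),
                       p_oxidize_base = 0.067,
                       proximity_odds = 1,
                       proximity_radius = 7,
                       positional_boost = NULL,
                       p_ubiq = 0.45, p_acetyl = 0.35,
                       ptm_corr_odds = 3,
                       abundance_meanlog = 9.2, abundance_sdlog = 2.3,
                       seed = 1L) {
  stopifnot(n_proteins >= 1, length_mean >= length_min, length_min >= 15)
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  if (!all(c("S", "T", "Y") %in% names(p_phospho))) {
    stop("`p_phospho` needs entries for S, T and Y")
  }
  probs <- c(p_phospho, p_oxidize_base, p_ubiq, p_acetyl, composition)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (proximity_odds <= 0 || ptm_corr_odds <= 0) stop("odds must be > 0")
  if (!is.null(positional_boost)) {
    off <- suppressWarnings(as.integer(names(positional_boost)))
    if (any(is.na(off)) || any(off == 0)) {
      stop("positional_boost names must be non-zero offsets like '+1', '-2'")
    }
    if (any(positional_boost <= 0)) stop("boost multipliers must be > 0")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Sub-seed for protein i, derived from the master seed; kept below 2^31.
protein_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 8191) %% 2147483629 + 1
}

#' Simulate a proteome and its PTM site table
#'
#' Sequences are drawn i.i.d. from the configured composition; each S/T/Y
#' is phosphorylated with its base probability (times any positional
#' boost); each methionine is oxidized with probability
#' `plogis(qlogis(p_oxidize_base) + log(proximity_odds))` when within
#' `proximity_radius` residues of a phosphosite, and `p_oxidize_base`
#' otherwise. Oxidized methionines draw `oxidized_fraction ~ U(0.2, 1)`,
#' so [curate_metO()] at its default threshold is the identity on synthetic
#' data. Per-protein ubiquitination/acetylation flags are placed on a random
#' lysine, with odds multiplied by `ptm_corr_odds` for MetO-carrying
#' proteins. Deterministic under a fixed `seed` (per-protein sub-streams).
#'
#' @param config A [sim_config()].
#' @return List with elements `proteins` (protein set) and `sites` (site
#'   table).
#' @export
simulate_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  lens <- if (is.infinite(config$length_dispersion)) {
    rep(round(config$length_mean), n)
  } else {
    pmax(config$length_min,
         stats::rnbinom(n, mu = config$length_mean,
                        size = config$length_dispersion))
  }
  abund <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  acc <- sprintf("SYN%04d", seq_len(n))
  letters20 <- names(config$composition)

  seqs <- character(n)
  site_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(protein_seed(config$seed, i))
    L <- lens[i]
    chars <- sample(letters20, L, replace = TRUE, prob = config$composition)
    seqs[i] <- paste(chars, collapse = "")

    # --- phosphosites -----------------------------------------------------
    p_site <- rep(0, L)
    for (r in c("S", "T", "Y")) p_site[chars == r] <- config$p_phospho[[r]]
    if (!is.null(config$positional_boost)) {
      offs <- as.integer(names(config$positional_boost))
      is_ser <- chars == "S"
      for (j in seq_along(offs)) {
        k <- offs[j]
        idx <- which(is_ser)
        idx <- idx[idx + k >= 1 & idx + k <= L]
        hit <- idx[chars[idx + k] == "M"]
        p_site[hit] <- pmin(1, p_site[hit] * config$positional_boost[j])
      }
    }
    phospho <- which(stats::runif(L) < p_site)

    # --- methionine oxidation --------------------------------------------
    mets <- which(chars == "M")
    oxidized <- integer(0)
    frac <- numeric(0)
    if (length(mets) > 0) {
      near <- if (length(phospho) > 0) {
        vapply(mets, function(m) min(abs(m - phospho)), numeric(1)) <=
          config$proximity_radius
      } else rep(FALSE, length(mets))
      p_ox <- ifelse(near,
                     stats::plogis(stats::qlogis(config$p_oxidize_base) +
                                     log(config$proximity_odds)),
                     config$p_oxidize_base)
      ox <- stats::runif(length(mets)) < p_ox
      oxidized <- mets[ox]
      frac <- stats::runif(length(oxidized), 0.2, 1)
    }

    # --- correlated per-protein ubiquitination / acetylation flags --------
    has_meto <- length(oxidized) > 0
    shift <- if (has_meto) log(config$ptm_corr_odds) else 0
    lys <- which(chars == "K")
    extra_pos <- integer(0)
    extra_kind <- character(0)
    for (mod in c("ubiquityl", "acetyl")) {
      base <- if (mod == "ubiquityl") config$p_ubiq else config$p_acetyl
      p <- stats::plogis(stats::qlogis(base) + shift)
      if (length(lys) > 0 && stats::runif(1) < p) {
        extra_pos <- c(extra_pos, lys[sample.int(length(lys), 1)])
        extra_kind <- c(extra_kind, mod)
      }
    }

    # plain vectors; one tibble is built at the end (fast path)
    position <- c(phospho, oxidized, extra_pos)
    site_rows[[i]] <- list(
      accession = rep(acc[i], length(position)),
      position = position,
      residue = c(chars[phospho], rep("M", length(oxidized)),
                  rep("K", length(extra_pos))),
      kind = c(rep("phospho", length(phospho)),
               rep("sulfoxide", length(oxidized)), extra_kind),
      oxidized_fraction = c(rep(NA_real_, length(phospho)), frac,
                            rep(NA_real_, length(extra_pos)))
    )
  }

  proteins <- protein_set(acc, seqs, abund)
  if (sum(vapply(site_rows, function(r) length(r$position), integer(1))) == 0) {
    return(list(proteins = proteins, sites = site_table()))
  }
  sites <- tibble::tibble(
    accession = unlist(lapply(site_rows, `[[`, "accession")),
    position = as.integer(unlist(lapply(site_rows, `[[`, "position"))),
    residue = unlist(lapply(site_rows, `[[`, "residue")),
    kind = unlist(lapply(site_rows, `[[`, "kind")),
    oxidized_fraction = unlist(lapply(site_rows, `[[`, "oxidized_fraction"))
  )
  list(proteins = proteins, sites = sites)
}

#' Simulate toy 3D structures
#'
#' Backbone coordinates follow a self-avoiding random walk with 3.8 Å steps
#' (consecutive C-alpha spacing); a pseudo side-chain atom (the methionine
#' sulfur or the acceptor hydroxyl oxygen) is offset 2.0 Å from the backbone
#' point in a random direction. Secondary-structure codes are assigned per
#' random segment from the 8-letter DSSP alphabet.
#'
#' @param proteins A protein set.
#' @param seed Integer seed.
#' @param min_separation Minimum allowed distance (Å) between non-adjacent
#'   backbone points before a step is rejected.
#' @return A tibble (one row per residue): `accession`, `residue_index`,
#'   `aa`, backbone `bx, by, bz`, side-chain `sx, sy, sz`, `dssp`.
#' @export
simulate_structures <- function(proteins, seed = 1L, min_separation = 3.0) {
  stopifnot(nrow(proteins) >= 1)
  dssp_codes <- c("H", "G", "I", "E", "B", "T", "S", "C")
  dssp_weights <- c(0.34, 0.04, 0.01, 0.21, 0.01, 0.12, 0.09, 0.18)
  out <- vector("list", nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    set.seed(protein_seed(seed, i))
    L <- proteins$length[i]
    bb <- matrix(0, nrow = L, ncol = 3)
    for (r in seq_len(L)[-1]) {
      for (try in 1:100) {
        u <- stats::rnorm(3)
        step <- bb[r - 1, ] + 3.8 * u / sqrt(sum(u^2))
        prior <- bb[seq_len(r - 2), , drop = FALSE]
        if (nrow(prior) == 0 ||
            min(sqrt(rowSums((prior - matrix(step, nrow(prior), 3,
                                             byrow = TRUE))^2))) >=
              min_separation) break
      }
      bb[r, ] <- step
    }
    sc <- bb + t(vapply(seq_len(L), function(r) {
      u <- stats::rnorm(3)
      2.0 * u / sqrt(sum(u^2))
    }, numeric(3)))
    # secondary structure in runs of geometric length (mean ~ 7 residues)
    dssp <- character(0)
    while (length(dssp) < L) {
      run <- 1 + stats::rgeom(1, 1 / 7)
      dssp <- c(dssp, rep(sample(dssp_codes, 1, prob = dssp_weights), run))
    }
    out[[i]] <- tibble::tibble(
      accession = proteins$accession[i],
      residue_index = seq_len(L),
      aa = strsplit(proteins$sequence[i], "")[[1]],
      bx = bb[, 1], by = bb[, 2], bz = bb[, 3],
      sx = sc[, 1], sy = sc[, 2], sz = sc[, 3],
      dssp = dssp[seq_len(L)]
    )
  }
  dplyr::bind_rows(out)
}
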