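# Replicated simulation experiments: type-I-error calibration of the
# empirical p-value machinery under a neutral generator, and power /
# parameter-recovery studies with planted effects.
#
# The calibration generator uses fixed-length proteins so that protein
# length cannot couple the target set (more methionines -> more likely to
# carry MetO) to the comparison set (more acceptors -> more likely to be a
# phosphoprotein); with variable lengths that coupling is real, is exactly
# the kind of sampling bias the abundance-matched null exists to remove,
# and would show up here as an honest (but uninformative-for-calibration)
# excess of small p-values.

#' Neutral simulation configuration for calibration runs
#'
#' All planted effects at their neutral values (`proximity_odds = 1`, no
#' positional boost, `ptm_corr_odds = 1`), fixed protein length, and
#' moderate phosphosite / overlap rates so the co-occurrence statistic
#' takes enough distinct values for its discrete empirical p to be close
#' to uniform.
#'
#' @param n_proteins Number of proteins per replicate.
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
neutral_config <- function(n_proteins = 400, seed = 1L) {
  sim_config(
    n_proteins = n_proteins,
    length_mean = 300, length_dispersion = Inf,
    p_phospho = c(S = 0.02, T = 0.01, Y = 0.005),
    p_oxidize_base = 0.067,
    proximity_odds = 1, positional_boost = NULL,
    ptm_corr_odds = 1,
    seed = seed
  )
}

# Permutation null for the Met-vs-MetO mean distance gap: permute oxidation
# labels across methionines, statistic = mean(Met dist) - mean(MetO dist).
distance_permutation_p <- function(records, n_perm = 2000, seed = 1L) {
  r <- records[records$site_kind == "any_pSite" & !is.na(records$distance), ,
               drop = FALSE]
  n_ox <- sum(r$met_oxidized)
  if (n_ox < 2 || nrow(r) - n_ox < 2) return(NULL)
  d <- r$distance
  observed <- mean(d[!r$met_oxidized]) - mean(d[r$met_oxidized])
  tot <- sum(d)
  n <- length(d)
  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(i) {
    ox <- sample.int(n, n_ox)
    s_ox <- sum(d[ox])
    (tot - s_ox) / (n - n_ox) - s_ox / n_ox
  }, numeric(1))
  nd <- null_distribution(vals, "mean_dist_gap", seed = seed,
                          constraint = "oxidation labels permuted over methionines")
  empirical_p(nd, observed, tail = "upper")$p
}

#' Type-I-error calibration of the resampling machinery
#'
#' Simulates `n_reps` neutral proteomes and, for each, computes the
#' empirical p-value of (i) the MetO/phospho co-occurrence proportion
#' against the uniform resampling null, (ii) the Met-vs-MetO mean distance
#' gap against an oxidation-label permutation null, and (iii) the mean
#' Met-per-pSer window count against the serine acceptor-resampling null
#' (lower tail). Under the neutral generator all three should be uniform;
#' the returned rejection rates at `alpha` estimate the realized type-I
#' error.
#'
#' @param n_reps Number of simulation replicates.
#' @param n_samples Resamples per null distribution within each replicate.
#' @param n_proteins Proteins per replicate.
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @return List with `p_values` (tibble: replicate, cooccur, distance,
#'   window) and `rejection_rates` (named vector of rates at `alpha`).
#' @export
calibration_study <- function(n_reps = 500, n_samples = 2000,
                              n_proteins = 400, alpha = 0.05, seed = 1L) {
  p_co <- p_di <- p_wi <- rep(NA_real_, n_reps)
  for (rep_i in seq_len(n_reps)) {
    rep_seed <- (as.double(seed) * 7919 + rep_i * 15485863) %% 2147483629 + 1
    sim <- simulate_proteome(neutral_config(n_proteins, seed = rep_seed))
    sites <- sim$sites
    meto_acc <- unique(sites$accession[sites$kind == "sulfoxide"])
    phospho_acc <- unique(sites$accession[sites$kind == "phospho"])

    if (length(meto_acc) >= 1) {
      observed <- overlap_proportion(meto_acc, phospho_acc)
      nd <- null_overlap(sim$proteins, phospho_acc, length(meto_acc),
                         n_samples, seed = rep_seed)
      p_co[rep_i] <- empirical_p(nd, observed, "upper")$p
    }

    dt <- distance_tables(sim$proteins, sites)
    p <- distance_permutation_p(dt$records, n_perm = n_samples,
                                seed = rep_seed)
    if (!is.null(p)) p_di[rep_i] <- p

    aw <- acceptor_windows(sim$proteins, sites)
    ws <- aw[aw$acceptor_residue == "S", , drop = FALSE]
    np <- sum(ws$is_phosphosite)
    if (np >= 1) {
      obs <- mean(ws$n_met[ws$is_phosphosite])
      nd <- acceptor_null(ws, np, "n_met", n_samples, seed = rep_seed)
      p_wi[rep_i] <- empirical_p(nd, obs, "lower")$p
    }
  }
  p_values <- tibble::tibble(replicate = seq_len(n_reps), cooccur = p_co,
                             distance = p_di, window = p_wi)
  rejection_rates <- vapply(p_values[, -1], function(p) {
    mean(p[!is.na(p)] <= alpha)
  }, numeric(1))
  list(p_values = p_values, rejection_rates = rejection_rates)
}

#' Power to recover a planted proximity effect
#'
#' Simulates proteomes with oxidation odds multiplied by `proximity_odds`
#' for methionines near a phosphosite, and tests (Yates-corrected
#' two-proportion test) whether the proportion of MetO within
#' `threshold` residues of a phosphosite exceeds that of non-oxidized Met.
#'
#' @param n_reps Number of replicates.
#' @param proximity_odds Planted odds multiplier.
#' @param n_proteins Proteins per replicate.
#' @param threshold Strict distance threshold.
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @return List with `detection_rate` (share of replicates with p < alpha
#'   and effect in the planted direction), `mean_prop_metO`,
#'   `mean_prop_met`, and the per-replicate tibble `results`.
#' @export
proximity_recovery_study <- function(n_reps = 200, proximity_odds = 4,
                                     n_proteins = 300, threshold = 7,
                                     alpha = 0.05, seed = 1L) {
  res <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    rep_seed <- (as.double(seed) * 6151 + rep_i * 32452843) %% 2147483629 + 1
    cfg <- sim_config(n_proteins = n_proteins,
                      length_mean = 350, length_dispersion = 2.5,
                      p_phospho = c(S = 0.06, T = 0.03, Y = 0.02),
                      p_oxidize_base = 0.05,
                      proximity_odds = proximity_odds,
                      ptm_corr_odds = 1,
                      seed = rep_seed)
    sim <- simulate_proteome(cfg)
    dt <- distance_tables(sim$proteins, sim$sites)
    r <- dt$records[dt$records$site_kind == "any_pSite" &
                      !is.na(dt$records$distance), , drop = FALSE]
    d_ox <- r$distance[r$met_oxidized]
    d_un <- r$distance[!r$met_oxidized]
    if (length(d_ox) < 2 || length(d_un) < 2) next
    prop_ox <- mean(d_ox < threshold)
    prop_un <- mean(d_un < threshold)
    pt <- two_prop_yates(sum(d_ox < threshold), length(d_ox),
                         sum(d_un < threshold), length(d_un))
    res[[rep_i]] <- tibble::tibble(
      replicate = rep_i, n_metO = length(d_ox), n_met = length(d_un),
      prop_metO = prop_ox, prop_met = prop_un, p = pt$p)
  }
  results <- dplyr::bind_rows(res)
  list(
    detection_rate = mean(results$p < alpha &
                            results$prop_metO > results$prop_met),
    mean_prop_metO = mean(results$prop_metO),
    mean_prop_met = mean(results$prop_met),
    results = results
  )
}

#' Recovery of planted positional MetO hot spots
#'
#' Simulates proteomes whose serine phosphorylation probability is boosted
#' when a methionine sits at the planted offsets (default P+1 and P+4),
#' and checks per replicate whether those offsets rank top-2 in the
#' phosphoserine MetO positional profile (`metO_per_500`).
#'
#' @param n_reps Number of replicates.
#' @param boost_offsets Integer offsets of the planted boost.
#' @param boost Multiplier on the serine phosphorylation probability.
#' @param n_proteins Proteins per replicate.
#' @param seed Master seed.
#' @return List with `top2_rate` and per-replicate tibble `results`
#'   (ranks of the planted offsets).
#' @export
positional_recovery_study <- function(n_reps = 200,
                                      boost_offsets = c(1, 4), boost = 6,
                                      n_proteins = 300, seed = 1L) {
  stopifnot(length(boost_offsets) >= 1)
  boost_vec <- stats::setNames(rep(boost, length(boost_offsets)),
                               sprintf("%+d", boost_offsets))
  hits <- logical(n_reps)
  ranks <- vector("list", n_reps)
  for (rep_i in seq_len(n_reps)) {
    rep_seed <- (as.double(seed) * 4409 + rep_i * 49979687) %% 2147483629 + 1
    cfg <- sim_config(n_proteins = n_proteins,
                      length_mean = 350, length_dispersion = 2.5,
                      p_phospho = c(S = 0.06, T = 0.03, Y = 0.02),
                      p_oxidize_base = 0.05,
                      proximity_odds = 4,
                      positional_boost = boost_vec,
                      ptm_corr_odds = 1,
                      seed = rep_seed)
    sim <- simulate_proteome(cfg)
    prof <- positional_profile(sim$proteins, sim$sites, "S",
                               controls = FALSE)$profile
    ord <- order(-prof$metO_per_500,
                 sample.int(nrow(prof)))  # random tie-break
    rk <- match(boost_offsets, prof$offset[ord])
    hits[rep_i] <- all(rk <= length(boost_offsets))
    ranks[[rep_i]] <- tibble::tibble(replicate = rep_i,
                                     offset = boost_offsets, rank = rk)
  }
  list(top2_rate = mean(hits), results = dplyr::bind_rows(ranks))
}
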