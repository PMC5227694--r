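# PTM co-occurrence proportions and their empirical resampling nulls,
# plain (uniform proteome samples) and abundance-matched (quartile-
# stratified samples that reproduce the target set's abundance profile).

#' Proportion of a target protein set covered by another set
#'
#' @param target Character vector of accessions (non-empty).
#' @param other Character vector of accessions.
#' @return `|target intersect other| / |target|`.
#' @export
overlap_proportion <- function(target, other) {
  target <- unique(target)
  if (length(target) == 0) stop("empty target set")
  mean(target %in% other)
}

#' Uniform-resampling null for a co-occurrence proportion
#'
#' Each of `n_samples` samples draws `sample_size` proteins uniformly
#' without replacement (within a sample) from the proteome and records the
#' proportion that belongs to `other`.
#'
#' @param proteome A protein set (or character vector of accessions).
#' @param other Accession set defining the second PTM.
#' @param sample_size Size of each sample (the target set's size).
#' @param n_samples Number of resamples.
#' @param seed Integer seed.
#' @return A [null_distribution()].
#' @export
null_overlap <- function(proteome, other, sample_size, n_samples = 10000,
                         seed = 1L) {
  acc <- if (is.data.frame(proteome)) proteome$accession else as.character(proteome)
  if (sample_size > length(acc)) {
    stop("sample_size exceeds the proteome size")
  }
  in_other <- acc %in% other
  set.seed(seed)
  vals <- vapply(seq_len(n_samples), function(i) {
    mean(in_other[sample.int(length(acc), sample_size)])
  }, numeric(1))
  null_distribution(vals, "overlap_proportion", seed = seed,
                    constraint = paste0("uniform samples of ", sample_size,
                                        " from ", length(acc), " proteins"))
}

#' Abundance-matched resampling null for a co-occurrence proportion
#'
#' Quartile boundaries are computed from the target set's abundance
#' distribution; each sample of size `|target|` is drawn as four strata,
#' one quarter from the proteome proteins whose abundance falls within each
#' target quartile range. Ranges are closed on the left, open on the right,
#' with the outer ranges extended to cover the whole axis; when `|target|`
#' is not divisible by 4 the remainder is allocated one-per-stratum from the
#' lowest quartile upward. Proteins without abundance are excluded from both
#' the target and the candidate pools (with a message giving counts).
#'
#' @param proteome A protein set with abundances.
#' @param target Accession vector of the target (e.g. MetO) proteins.
#' @param other Accession set defining the second PTM.
#' @param n_samples Number of resamples.
#' @param seed Integer seed.
#' @return List with `null` (a [null_distribution()]) and `diagnostics`, a
#'   tibble with per-sample mean log10 abundance and a KS comparison of the
#'   sample vs the target abundance distribution.
#' @export
abundance_matched_null <- function(proteome, target, other,
                                   n_samples = 10000, seed = 1L) {
  stopifnot(is.data.frame(proteome), "abundance" %in% names(proteome))
  pool <- proteome[!is.na(proteome$abundance), , drop = FALSE]
  dropped_pool <- nrow(proteome) - nrow(pool)
  if (dropped_pool > 0) {
    message(dropped_pool, " proteome protein(s) without abundance excluded")
  }
  target <- unique(target)
  tgt <- pool[pool$accession %in% target, , drop = FALSE]
  dropped_tgt <- length(target) - nrow(tgt)
  if (dropped_tgt > 0) {
    message(dropped_tgt, " target protein(s) without abundance excluded")
  }
  m <- nrow(tgt)
  if (m < 4) stop("need at least 4 target proteins with abundance")

  qs <- stats::quantile(tgt$abundance, c(0.25, 0.5, 0.75), names = FALSE)
  # stratum of each candidate: 1..4, left-closed ranges
  stratum <- findInterval(pool$abundance, qs, left.open = FALSE) + 1L
  pools <- split(seq_len(nrow(pool)), factor(stratum, levels = 1:4))
  sizes <- rep(m %/% 4, 4)
  rem <- m %% 4
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  short <- which(vapply(pools, length, integer(1)) < sizes)
  if (length(short) > 0) {
    stop("stratum ", paste(short, collapse = ", "),
         " has fewer candidates than the required stratum size")
  }

  in_other <- pool$accession %in% other
  log10_ab <- log10(pool$abundance)
  tgt_log10 <- log10(tgt$abundance)
  set.seed(seed)
  vals <- numeric(n_samples)
  mean_ab <- numeric(n_samples)
  ks_D <- numeric(n_samples)
  ks_p <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    idx <- unlist(lapply(1:4, function(s) {
      p <- pools[[s]]
      p[sample.int(length(p), sizes[s])]
    }), use.names = FALSE)
    vals[i] <- mean(in_other[idx])
    mean_ab[i] <- mean(log10_ab[idx])
    ks <- ks_two_sample(log10_ab[idx], tgt_log10)
    ks_D[i] <- ks$D
    ks_p[i] <- ks$p
  }
  list(
    null = null_distribution(
      vals, "overlap_proportion", seed = seed,
      constraint = paste0("abundance-matched samples of ", m,
                          " (quartile strata ", paste(sizes, collapse = "/"),
                          ") from ", nrow(pool), " proteins")),
    diagnostics = tibble::tibble(
      sample = seq_len(n_samples), mean_log10_abundance = mean_ab,
      ks_D = ks_D, ks_p = ks_p),
    target_mean_log10_abundance = mean(tgt_log10),
    strata_sizes = sizes
  )
}

#' Co-occurrence test of a target PTM proteome against another PTM
#'
#' Computes the observed overlap proportion and its empirical p-value
#' against a resampling null (uniform or abundance-matched).
#'
#' @param proteome A protein set.
#' @param target,other Accession sets (target = e.g. the MetO-proteome).
#' @param n_samples Number of resamples.
#' @param seed Integer seed.
#' @param matched If `TRUE`, use [abundance_matched_null()].
#' @return List with `observed`, `null`, `p`, `is_bound` (and `diagnostics`
#'   when matched).
#' @export
cooccurrence_test <- function(proteome, target, other, n_samples = 10000,
                              seed = 1L, matched = FALSE) {
  if (matched) {
    res <- abundance_matched_null(proteome, target, other, n_samples, seed)
    pool <- proteome[!is.na(proteome$abundance), , drop = FALSE]
    tgt <- intersect(unique(target), pool$accession)
    observed <- overlap_proportion(tgt, other)
    nd <- res$null
  } else {
    observed <- overlap_proportion(target, other)
    nd <- null_overlap(proteome, other, length(unique(target)), n_samples,
                       seed)
    res <- NULL
  }
  ep <- empirical_p(nd, observed, tail = "upper")
  out <- list(observed = observed, null = nd, p = ep$p,
              is_bound = ep$is_bound, bound = ep$bound)
  if (matched) out$diagnostics <- res$diagnostics
  out
}
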