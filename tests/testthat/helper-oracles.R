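# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately use the most literal enumeration or
# scan available, never the package's own code path.

# -- brute-force oracles -----------------------------------------------------

oracle_nearest <- function(pos, sites) {
  if (length(sites) == 0) return(NA_integer_)
  best <- Inf
  for (s in sites) if (abs(pos - s) < best) best <- abs(pos - s)
  as.integer(best)
}

oracle_window_count <- function(chars, center, metO_positions, halfwidth) {
  n_met <- 0L
  n_metO <- 0L
  for (off in c(-(halfwidth:1), 1:halfwidth)) {
    p <- center + off
    if (p < 1 || p > length(chars)) next
    if (chars[p] == "M") {
      n_met <- n_met + 1L
      if (p %in% metO_positions) n_metO <- n_metO + 1L
    }
  }
  list(n_met = n_met, n_metO = n_metO)
}

oracle_cluster_count <- function(met, phospho, radius) {
  n <- 0L
  for (p in phospho) if (abs(met - p) <= radius) n <- n + 1L
  n
}

oracle_spatial_nearest <- function(met_xyz, mat) {
  # mat: matrix with one row (x, y, z) per acceptor
  best <- Inf
  for (i in seq_len(nrow(mat))) {
    d <- sqrt(sum((mat[i, ] - met_xyz)^2))
    if (d < best) best <- d
  }
  best
}

oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_hyper_upper <- function(k, K, N, n) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js) / choose(N, n))
}

oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}

oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_yates_chi2 <- function(x1, n1, x2, n2) {
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  N <- n1 + n2
  num <- N * (abs(a * d - b * c) - N / 2)^2
  den <- as.numeric(n1) * n2 * (a + c) * (b + d)
  chi2 <- num / den
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# -- fixtures ----------------------------------------------------------------

random_aa_string <- function(n, letters = c("A", "R", "N", "D", "C", "Q",
                                            "E", "G", "H", "I", "L", "K",
                                            "M", "F", "P", "S", "T", "W",
                                            "Y", "V")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# The four stress-granule phosphoproteins: printed 15-mer motifs embedded in
# alanine scaffolds so that the phosphoserine lands at its printed position.
stress_granule_fixture <- function() {
  tab <- tibble::tibble(
    accession = c("P05198", "Q14671", "Q99700", "Q8WWM7"),
    motif = c("LRAGLNCSTENMPIK", "HAEHQVRSMDELNHD",
              "QPSSTSESMDQLLNK", "TKDKFTDSAIAMNSK"),
    pser = c(219L, 124L, 814L, 211L),
    meto = c(223L, 125L, 815L, 215L),
    group = c("Acidophilic", "Acidophilic", "Acidophilic", "Basophilic")
  )
  seqs <- vapply(seq_len(nrow(tab)), function(i) {
    left <- strrep("A", tab$pser[i] - 8)
    paste0(left, tab$motif[i], strrep("A", 10))
  }, character(1))
  proteins <- protein_set(tab$accession, seqs)
  sites <- site_table(
    accession = c(tab$accession, tab$accession),
    position = c(tab$pser, tab$meto),
    residue = c(rep("S", 4), rep("M", 4)),
    kind = c(rep("phospho", 4), rep("sulfoxide", 4)),
    oxidized_fraction = c(rep(NA_real_, 4), rep(0.9, 4))
  )
  list(table = tab, proteins = proteins, sites = sites)
}

# A small deterministic proteome for I/O tests.
toy_proteome <- function() {
  protein_set(
    c("P1", "P2", "P3"),
    c("MASTYKMESDM", "KKSMTPYAAA", "MMMSSSTTTYYY"),
    c(100, 2000, NA)
  )
}
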