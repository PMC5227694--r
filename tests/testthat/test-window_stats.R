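test_that("count_window counts Met and MetO inside the +/-7 window", {
  # the Pumilio motif has exactly one Met, at P+1
  motif <- "HAEHQVRSMDELNHD"
  chars <- strsplit(motif, "")[[1]]
  res <- count_window(nchar(motif), 8, which(chars == "M"), integer(0))
  expect_equal(res$n_met, 1L)
  expect_equal(res$n_metO, 0L)

  # truncation at the N-terminus: only +1..+7 scanned
  res <- count_window(20, 1, c(1, 3, 9), c(3))
  expect_equal(res$n_met, 1L)   # position 3 only; 1 is the center, 9 beyond
  expect_equal(res$n_metO, 1L)

  # brute-force oracle over random sequences
  set.seed(14)
  for (i in 1:300) {
    L <- sample(10:60, 1)
    chars <- sample(c("A", "M", "S"), L, replace = TRUE,
                    prob = c(0.7, 0.15, 0.15))
    mets <- which(chars == "M")
    metO <- mets[runif(length(mets)) < 0.4]
    center <- sample(1:L, 1)
    got <- count_window(L, center, mets, metO)
    want <- oracle_window_count(chars, center, metO, 7)
    expect_identical(got$n_met, want$n_met)
    expect_identical(got$n_metO, want$n_metO)
  }
})

test_that("acceptor_windows agrees with per-window brute force", {
  set.seed(15)
  sim <- simulate_proteome(sim_config(n_proteins = 15, length_mean = 120,
                                      seed = 33))
  aw <- acceptor_windows(sim$proteins, sim$sites)
  metO <- sim$sites[sim$sites$kind == "sulfoxide", ]
  for (i in sample(nrow(aw), 50)) {
    acc <- aw$accession[i]
    chars <- strsplit(sim$proteins$sequence[
      sim$proteins$accession == acc], "")[[1]]
    oxs <- metO$position[metO$accession == acc]
    want <- oracle_window_count(chars, aw$acceptor_position[i], oxs, 7)
    expect_identical(aw$n_met[i], want$n_met)
    expect_identical(aw$n_metO[i], want$n_metO)
  }
  expect_true(all(aw$n_metO <= aw$n_met))
})

test_that("mean_per_site and the i.i.d. expectation agree", {
  w <- tibble::tibble(n_met = c(0L, 1L), n_metO = c(0L, 0L))
  expect_equal(mean_per_site(w)$mean_met, 0.5)
  expect_error(mean_per_site(w[0, ]), "empty")

  # i.i.d. composition: E[Met per full window] = 14 * f_M
  sim <- simulate_proteome(sim_config(n_proteins = 250, length_mean = 300,
                                      seed = 44))
  aw <- acceptor_windows(sim$proteins, sim$sites)
  full <- aw[aw$acceptor_position > 7, ]
  m <- mean_per_site(full)$mean_met
  expected <- 14 * 0.023
  se <- sqrt(expected / nrow(full))  # Poisson-scale bound
  expect_lt(abs(m - expected), 5 * se)
})

test_that("acceptor_null matches finite-population sampling theory", {
  set.seed(16)
  w <- tibble::tibble(n_met = rpois(3000, 0.4),
                      n_metO = 0L)
  # sample = population: the null is a point mass at the population mean
  nd <- acceptor_null(w, 3000, "n_met", n_samples = 50, seed = 3)
  expect_true(all(nd$values == mean(w$n_met)))

  k <- 400
  nd <- acceptor_null(w, k, "n_met", n_samples = 4000, seed = 3)
  pop_mean <- mean(w$n_met)
  pop_var <- var(w$n_met) * (3000 - 1) / 3000
  se_theory <- sqrt(pop_var / k * (3000 - k) / (3000 - 1))
  expect_lt(abs(mean(nd$values) - pop_mean), 4 * se_theory / sqrt(4000))
  expect_lt(abs(sd(nd$values) - se_theory), 0.1 * se_theory)
  expect_identical(nd$values, acceptor_null(w, k, "n_met", 4000, 3)$values)
  expect_error(acceptor_null(w, 4000, "n_met", 10, 1), "exceeds")
})

test_that("positional profile counts follow their definitions", {
  # 5 phosphosites, one with a MetO at +1 -> metO_per_500[+1] = 100
  seqs <- c("AAAAAAASMAAAAAA",  # S8, M9 oxidized
            "AAAAAAASAAAAAAA",
            "AAAAAAASAAAAAAA",
            "AAAAAAASAAAAAAA",
            "AAAAAAASAAAAAAA")
  prot <- protein_set(sprintf("Q%d", 1:5), seqs)
  sites <- site_table(
    accession = c(sprintf("Q%d", 1:5), "Q1"),
    position = c(rep(8, 5), 9),
    residue = c(rep("S", 5), "M"),
    kind = c(rep("phospho", 5), "sulfoxide"),
    oxidized_fraction = c(rep(NA, 5), 0.8)
  )
  pr <- positional_profile(prot, sites, "S")
  prof <- pr$profile
  expect_equal(prof$metO_per_500[prof$offset == 1], 500 * 1 / 5)
  expect_equal(prof$met_freq_percent[prof$offset == 1], 100 * 1 / 5)
  expect_equal(sum(prof$met_freq_percent[prof$offset != 1]), 0)
  expect_equal(pr$n_phosphosites, 5)

  # no methionine anywhere: all frequencies zero
  prot0 <- protein_set("Z1", "AAAAAAASAAAAAAA")
  sites0 <- site_table("Z1", 8, "S", "phospho")
  pr0 <- positional_profile(prot0, sites0, "S")
  expect_true(all(pr0$profile$met_freq_percent == 0))
  expect_true(all(pr0$profile$metO_per_500 == 0))
})

test_that("per-offset counts never double count a window's methionines", {
  set.seed(17)
  sim <- simulate_proteome(sim_config(n_proteins = 40, length_mean = 200,
                                      seed = 55))
  pr <- positional_profile(sim$proteins, sim$sites, "S", controls = FALSE)
  # total Met over offsets (recovered from truncation-aware denominators)
  aw <- acceptor_windows(sim$proteins, sim$sites)
  pser <- aw[aw$acceptor_residue == "S" & aw$is_phosphosite, ]
  # reconstruct per-offset counts: freq% * denom / 100; denominators are the
  # number of windows whose offset is inside the protein
  seqs <- setNames(sim$proteins$sequence, sim$proteins$accession)
  lens <- nchar(seqs)
  denom <- vapply(pr$profile$offset, function(off) {
    sum(pser$acceptor_position + off >= 1 &
          pser$acceptor_position + off <= lens[pser$accession])
  }, numeric(1))
  counts <- pr$profile$met_freq_percent * denom / 100
  expect_equal(sum(counts), sum(pser$n_met), tolerance = 1e-9)
})
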