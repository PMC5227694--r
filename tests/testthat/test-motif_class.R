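test_that("extract_window copies letters by offset and pads at termini", {
  # the eIF2-alpha stress-granule motif, embedded so pSer lands at 219
  fx <- stress_granule_fixture()
  seqs <- setNames(fx$proteins$sequence, fx$proteins$accession)
  expect_equal(extract_window(seqs[["P05198"]], 219), "LRAGLNCSTENMPIK")

  expect_equal(extract_window("SAAAAAAA", 1), "_______SAAAAAAA")
  expect_equal(extract_window("AAS", 3, halfwidth = 3), "_AAS___")

  # round-trip property: window letters match the sequence slice
  set.seed(18)
  for (i in 1:100) {
    L <- sample(8:40, 1)
    s <- random_aa_string(L)
    center <- sample(1:L, 1)
    w <- extract_window(s, center)
    for (off in -7:7) {
      p <- center + off
      expected <- if (p >= 1 && p <= L) substr(s, p, p) else "_"
      expect_equal(substr(w, 8 + off, 8 + off), expected)
    }
  }
})

test_that("the decision tree reproduces the stress-granule groups", {
  fx <- stress_granule_fixture()
  for (i in seq_len(nrow(fx$table))) {
    w <- extract_window(fx$proteins$sequence[i], fx$table$pser[i])
    expect_equal(fx$table$motif[i], w)
    expect_equal(classify_pser_motif(w), fx$table$group[i])
  }
})

test_that("rules fire in order with first match winning", {
  pad <- function(left, right) {
    paste0(strrep("A", 7 - nchar(left)), left, "S", right,
           strrep("A", 7 - nchar(right)))
  }
  # rule 1 beats everything: P at +1 even with acidic stretch after
  expect_equal(classify_pser_motif(pad("", "PDEDED")), "ProDirected")
  # rule 2 beats rule 3: >= 5 D/E in +1..+6 despite K at -3
  w <- "AAAAKAASEDEDEEA"
  expect_equal(classify_pser_motif(w), "Acidophilic")
  expect_equal(substr(w, 5, 5), "K")  # K sits at P-3
  # rule 3 beats rule 4: K at -3 with D at +2
  expect_equal(classify_pser_motif(pad("KAA", "ADAAAA")), "Basophilic")
  # rule 4 beats rule 5: D at +3 with two Ks upstream (none at -3)
  expect_equal(classify_pser_motif(pad("KAKA", "AAD")), "Acidophilic")
  # rule 5 needs two basic residues in -6..-1 (not at -3)
  expect_equal(classify_pser_motif(pad("KAKA", "")), "Basophilic")
  expect_equal(classify_pser_motif(pad("KAAA", "")), "Others")
  # boundary: D/E at +4..+6 only does not trigger rule 4
  expect_equal(classify_pser_motif(pad("", "AAADDE")), "Others")
  # rule 2 boundary: exactly 5 acidics within +1..+6
  expect_equal(classify_pser_motif(pad("", "DDEEDA")), "Acidophilic")
  # -7 and +7 are outside every rule's range
  expect_equal(classify_pser_motif("KAAAAAASAAAAAAD"), "Others")
})

test_that("the classifier is total, deterministic and PAD-blind", {
  # padded windows never crash and PAD never satisfies a rule
  expect_equal(classify_pser_motif("_______S_______"), "Others")
  expect_equal(classify_pser_motif("_______SP______"), "ProDirected")
  set.seed(19)
  alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")
  wins <- vapply(1:2000, function(i) {
    n_pad_l <- sample(0:3, 1); n_pad_r <- sample(0:3, 1)
    paste0(strrep("_", n_pad_l),
           paste(sample(alphabet, 7 - n_pad_l, replace = TRUE), collapse = ""),
           "S",
           paste(sample(alphabet, 7 - n_pad_r, replace = TRUE), collapse = ""),
           strrep("_", n_pad_r))
  }, character(1))
  cls <- classify_motifs(wins)
  expect_false(anyNA(cls))
  expect_identical(cls, classify_motifs(wins))
  expect_error(classify_pser_motif("AAAAAAATAAAAAAA"), "not an allowed")
  expect_equal(classify_pser_motif("AAAAAAATPAAAAAA",
                                   allowed_center = c("S", "T")),
               "ProDirected")
})

test_that("determinant position tallies match a per-offset scan", {
  tal <- tally_determinant_positions(c("sM", "sXXXM"))
  expect_equal(tal$n_motifs_with_met[tal$offset == 1], 1L)
  expect_equal(tal$n_motifs_with_met[tal$offset == 4], 1L)
  expect_equal(sum(tal$n_motifs_with_met), 2L)

  expect_true(all(tally_determinant_positions(character(0))$n_motifs_with_met == 0))
  expect_error(tally_determinant_positions("MXXA"), "exactly one acceptor")

  # oracle: count every pattern containing M at each offset
  set.seed(20)
  for (i in 1:50) {
    pats <- vapply(1:8, function(j) {
      left <- paste(sample(c("X", "M", "R"), sample(0:6, 1), replace = TRUE),
                    collapse = "")
      right <- paste(sample(c("X", "M", "E"), sample(0:6, 1), replace = TRUE),
                     collapse = "")
      paste0(left, "s", right)
    }, character(1))
    tal <- tally_determinant_positions(pats)
    for (off in c(-3, -1, 1, 2, 4)) {
      want <- sum(vapply(pats, function(p) {
        chars <- strsplit(p, "")[[1]]
        acc <- which(chars == "s")
        off >= 1 - acc && off <= length(chars) - acc &&
          chars[acc + off] == "M"
      }, logical(1)))
      expect_equal(tal$n_motifs_with_met[tal$offset == off], want)
    }
  }
})

test_that("class frequencies normalise within each subset", {
  w_pro <- "AAAAAAASPAAAAAA"
  cf <- class_frequencies(list(one = w_pro))
  expect_equal(cf$frequency[cf$class == "ProDirected"], 1)
  expect_equal(sum(cf$frequency), 1)

  set.seed(21)
  sim <- simulate_proteome(sim_config(n_proteins = 60, seed = 66))
  subs <- pser_window_subsets(sim$proteins, sim$sites)
  cf <- class_frequencies(subs)
  sums <- tapply(cf$frequency, cf$subset, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(class_frequencies(list(empty = character(0))), "empty subset")
})

test_that("acidic residues planted near MetO raise the acidophilic share", {
  # build pSer windows directly: the MetO-adjacent subset gets acidic
  # residues at +1..+3 twice as often
  set.seed(22)
  mk <- function(acidic) {
    right <- if (acidic) paste0("M", paste(sample(c("D", "E"), 6, TRUE),
                                           collapse = ""))
    else paste(sample(c("A", "G", "L", "M"), 7, TRUE), collapse = "")
    paste0(paste(sample(c("A", "G", "L", "V"), 7, TRUE), collapse = ""),
           "S", right)
  }
  with_meto <- vapply(1:200, function(i) mk(runif(1) < 0.7), character(1))
  background <- vapply(1:200, function(i) mk(runif(1) < 0.2), character(1))
  cf <- class_frequencies(list(meto_adjacent = with_meto,
                               background = background))
  f <- function(sub) cf$frequency[cf$subset == sub &
                                    cf$class == "Acidophilic"]
  expect_gt(f("meto_adjacent"), f("background"))
})
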