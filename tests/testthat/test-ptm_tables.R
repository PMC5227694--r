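test_that("FASTA and abundance loading builds a validated protein set", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "MASTYKMESDM",
               ">P2", "KKSMTPYAAA"), fa)
  ab <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tabundance", "P1\t150.5"), ab)

  prot <- suppressMessages(load_proteome(fa, ab))
  expect_equal(nrow(prot), 2)
  expect_equal(prot$accession, c("P1", "P2"))
  expect_equal(prot$abundance, c(150.5, NA))
  expect_equal(prot$length, c(11L, 10L))

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(load_proteome(empty), "no records")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">P1", "MA", ">P1", "MC"), dup)
  expect_error(load_proteome(dup), "duplicate accession")
})

test_that("protein_set enforces its invariants", {
  expect_error(protein_set("P1", ""), "length >= 1")
  expect_error(protein_set("P1", "MAZ"), "invalid residue")
  expect_error(protein_set(c("A", "A"), c("MA", "MC")), "duplicate")
  expect_error(protein_set("P1", "MA", abundance = -1), "> 0")
  expect_silent(protein_set("P1", "MAX"))  # X permitted
})

test_that("site loading validates positions, residues and kinds", {
  prot <- toy_proteome()
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "accession\tposition\tresidue\tkind\toxidized_fraction",
    "P1\t3\tS\tphospho\t",        # S at 3: accepted
    "P1\t2\tM\tsulfoxide\t0.5",   # A at 2: residue mismatch, dropped
    "PX\t1\tM\tsulfoxide\t0.5"    # unknown accession, dropped
  ), tsv)
  sites <- suppressWarnings(load_sites(tsv, prot))
  expect_equal(nrow(sites), 1)
  expect_equal(sites$position, 3L)
  w <- capture_warnings(load_sites(tsv, prot))
  expect_true(any(grepl("unknown accessions", w)))
  expect_true(any(grepl("residue/position", w)))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tposition\tresidue\tkind",
               "P1\t0\tM\tsulfoxide"), bad)
  expect_error(load_sites(bad, prot), "malformed|>= 1")

  badkind <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tposition\tresidue\tkind",
               "P1\t1\tM\tmethyl"), badkind)
  expect_error(load_sites(badkind, prot), "kind")
})

test_that("validation guarantees sequence[position] == residue and no duplicates", {
  prot <- toy_proteome()
  sites <- site_table(
    accession = c("P1", "P1", "P1"),
    position = c(3, 3, 7),
    residue = c("S", "S", "M"),
    kind = c("phospho", "phospho", "sulfoxide"),
    oxidized_fraction = c(NA, NA, 0.6)
  )
  out <- validate_sites(sites, prot)
  expect_equal(nrow(out), 2)  # duplicate collapsed
  seqs <- setNames(prot$sequence, prot$accession)
  expect_true(all(substr(seqs[out$accession], out$position,
                         out$position) == out$residue))
  # phospho on a non-acceptor is rejected
  bad <- site_table("P1", 6, "K", "phospho")
  expect_error(validate_sites(bad, prot), "does not match")
})

test_that("site tables round-trip through the TSV format", {
  prot <- toy_proteome()
  sites <- site_table(
    accession = c("P1", "P2", "P1"),
    position = c(3, 4, 7),
    residue = c("S", "M", "M"),
    kind = c("phospho", "sulfoxide", "sulfoxide"),
    oxidized_fraction = c(NA, 0.35, 0.8)
  )
  path <- tempfile(fileext = ".tsv")
  write_sites(sites, path)
  back <- load_sites(path, prot)
  key <- function(s) s[order(s$accession, s$position, s$kind), ]
  expect_equal(key(back), key(sites), ignore_attr = TRUE)
})

test_that("curate_metO keeps the 20% boundary and drops ambiguous rows", {
  sites <- site_table(
    accession = rep("P1", 4),
    position = c(1, 7, 11, 3),
    residue = c("M", "M", "M", "S"),
    kind = c(rep("sulfoxide", 3), "phospho"),
    oxidized_fraction = c(0.19, 0.20, 0.95, NA)
  )
  out <- curate_metO(sites)
  sulf <- out[out$kind == "sulfoxide", ]
  expect_equal(sort(sulf$oxidized_fraction), c(0.20, 0.95))
  expect_true(all(sulf$oxidized_fraction >= 0.20))
  # the phospho row is untouched
  expect_true("phospho" %in% out$kind)

  # all fractions absent -> empty sulfoxide result, warning
  amb <- site_table("P1", c(1, 7), "M", "sulfoxide")
  expect_warning(res <- curate_metO(amb), "ambiguous")
  expect_equal(nrow(res), 0)

  # min_fraction = 0 keeps every row with a fraction
  expect_equal(nrow(curate_metO(sites[1:3, ], min_fraction = 0)), 3)
  expect_error(curate_metO(sites, min_fraction = 1.5), "\\[0, 1\\]")
})
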