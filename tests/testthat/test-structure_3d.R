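test_that("ss_category groups the 8-letter DSSP alphabet as published", {
  expect_equal(ss_category("G"), "helix")
  expect_equal(ss_category("B"), "strand")
  expect_equal(ss_category("S"), "coil")
  expect_equal(ss_category(c("H", "G", "I", "E", "B", "T", "S", "C")),
               c("helix", "helix", "helix", "strand", "strand",
                 "coil", "coil", "coil"))
  expect_error(ss_category("Z"), "unknown DSSP")
})

test_that("spatial_nearest is the brute-force minimum with index tie-break", {
  acc <- tibble::tibble(residue_index = c(5L, 9L),
                        sx = c(3, 10), sy = c(4, 0), sz = c(0, 0))
  res <- spatial_nearest(c(0, 0, 0), acc)
  expect_equal(res$distance, 5)          # 3-4-5 triangle
  expect_equal(res$residue_index, 5L)

  res <- spatial_nearest(c(3, 4, 0), acc)
  expect_equal(res$distance, 0)

  # exact tie resolves to the lowest residue index
  tie <- tibble::tibble(residue_index = c(9L, 2L),
                        sx = c(1, -1), sy = 0, sz = 0)
  expect_equal(spatial_nearest(c(0, 0, 0), tie)$residue_index, 2L)

  # unresolved acceptors are skipped; none resolved -> NA
  nar <- tibble::tibble(residue_index = 1L, sx = NA_real_, sy = NA_real_,
                        sz = NA_real_)
  expect_true(is.na(spatial_nearest(c(0, 0, 0), nar)$distance))

  set.seed(23)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    acc <- tibble::tibble(residue_index = seq_len(n),
                          sx = rnorm(n), sy = rnorm(n), sz = rnorm(n))
    met <- rnorm(3)
    expect_equal(spatial_nearest(met, acc)$distance,
                 oracle_spatial_nearest(met, as.matrix(acc[, 2:4])),
                 tolerance = 1e-12)
  }
})

test_that("structures round-trip through PDB + DSSP text", {
  prot <- protein_set(c("S1", "S2"),
                      c("MKSTAYAMWLSTYMK", "AAMSTYAAAMAAK"))
  st <- simulate_structures(prot, seed = 8)
  dir <- tempfile("structs")
  mp <- write_structures(st, dir)
  mp$chain <- "A"
  mp$offset <- 0L
  rt <- read_structures(mp, prot)
  expect_equal(nrow(rt), nrow(st))
  expect_equal(rt$dssp, st$dssp)
  expect_false(any(rt$unresolved))
  # PDB stores 3 decimals
  expect_lt(max(abs(rt$bx - st$bx)), 1e-3)
  side <- st$aa %in% c("S", "T", "Y", "M")
  expect_lt(max(abs(rt$sx[side] - st$sx[side])), 1e-3)
  expect_true(all(is.na(rt$sx[!side])))
})

test_that("a methionine lacking its SD atom is excluded and logged", {
  prot <- protein_set("S1", "MKSTAYAMWLSTYMK")
  st <- simulate_structures(prot, seed = 8)
  dir <- tempfile("structs")
  mp <- write_structures(st, dir)
  # strip the SD atom of the first methionine from the PDB text
  lines <- readLines(mp$pdb_path[1])
  sd_lines <- grep("SD +MET A +1 ", lines)
  writeLines(lines[-sd_lines[1]], mp$pdb_path[1])
  mp$chain <- "A"; mp$offset <- 0L
  expect_message(rt <- read_structures(mp, prot), "lack the required")
  expect_true(rt$unresolved[rt$residue_index == 1])
  sites <- site_table("S1", c(3, 14), c("S", "M"),
                      c("phospho", "sulfoxide"), c(NA, 0.9))
  sd <- structure_distances(rt, prot, sites)
  expect_false(1L %in% sd$met_position)   # excluded from the analysis
  expect_true(14L %in% sd$met_position)
})

test_that("blank DSSP structure column reads as coil", {
  path <- tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition ====",
    "HEADER LINE",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M  H  extra columns here",
    "    2    2 A K     extra columns here",
    "    3    3 A S  E  extra"
  ), path)
  d <- read_dssp(path)
  expect_equal(d$dssp, c("H", "C", "E"))
  expect_equal(d$residue_index, 1:3)
  expect_error(suppressWarnings(read_dssp(tempfile())),
               "cannot open|not a DSSP")
})

test_that("sequence-distance results delegate to the primary-structure path", {
  set.seed(24)
  sim <- simulate_proteome(sim_config(n_proteins = 10, length_mean = 150,
                                      seed = 99))
  st <- simulate_structures(sim$proteins, seed = 3)
  sd <- structure_distances(st, sim$proteins, sim$sites)
  dt <- distance_tables(sim$proteins, sim$sites)
  seq_ref <- dt$records[dt$records$site_kind == "any_pSite", ]
  merged <- merge(sd, seq_ref, by = c("accession", "met_position"))
  expect_gt(nrow(merged), 0)
  expect_equal(merged$seq_dist, merged$distance)
  expect_equal(merged$met_oxidized.x, merged$met_oxidized.y)
  # spatial distances are symmetric non-negative by construction
  expect_true(all(sd$spatial_dist >= 0 | is.na(sd$spatial_dist)))
})

test_that("secondary-structure occupancy sums to one per oxidation status", {
  set.seed(25)
  sim <- simulate_proteome(sim_config(n_proteins = 12, length_mean = 150,
                                      seed = 98))
  st <- simulate_structures(sim$proteins, seed = 4)
  sd <- structure_distances(st, sim$proteins, sim$sites)
  props <- ss_proportions(sd)
  sums <- tapply(props$proportion, props$met_oxidized, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
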