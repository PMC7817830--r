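test_that("residue mass table is complete and physically ordered", {
  tab <- residue_masses()
  expect_setequal(tab$residue, strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]])
  expect_true(all(tab$monoisotopic > 0))
  expect_true(all(tab$monoisotopic < tab$average))
})

test_that("peptide_mass matches the summation oracle", {
  expect_equal(peptide_mass("GG"), oracle$gg_mono, tolerance = 1e-6)
  expect_equal(peptide_mass("IISKIENHEGVR"), oracle$backbone_mono,
               tolerance = 1e-7)
  # labels: empty label set is the zero-shift identity
  expect_identical(peptide_mass("PEPTIDE"),
                   peptide_mass("PEPTIDE", labels = as_label_tbl(NULL)))
  # label shift is additive
  expect_equal(peptide_mass("ACDK", labels = c("2" = 5)),
               peptide_mass("ACDK") + 5)
})

test_that("invalid sequences are rejected with the offending character", {
  expect_error(peptide_mass("PEPTIDEZ"), "Z")
  expect_error(peptide_mass(""), "non-empty")
  expect_error(digest("MKB3"), "B|3")
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(digest("MKRAAK")$peptide, c("MK", "R", "AAK"))
  expect_equal(digest("MKPR")$peptide, "MKPR")
  d <- digest("MKRAAK", missed_cleavages = 1)
  expect_true(all(c("MKR", "RAAK") %in% d$peptide))
})

test_that("PKM2 digestion yields the K270 backbone peptides", {
  pk <- read_fasta(pkm2_fasta())
  d0 <- digest(pk$sequence, 0)
  expect_true(all(c("IISK", "IENHEGVR") %in% d0$peptide))
  expect_false("IISKIENHEGVR" %in% d0$peptide)
  d1 <- digest(pk$sequence, 1)
  expect_true("IISKIENHEGVR" %in% d1$peptide)
  # independent oracle: regex split reproduces the 0-missed-cleavage list
  expect_equal(d0$peptide, oracle_digest(pk$sequence))
})

test_that("conjugate enumeration finds K270 and respects K-to-R loss", {
  pk <- read_fasta(pkm2_fasta())
  cj <- enumerate_conjugates(digest(pk$sequence, 2))
  hit <- cj[cj$protein_site == 270 & cj$backbone == "IISKIENHEGVR", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$link_pos, 4L)
  expect_equal(hit$neutral_mass, oracle$conjugate_mono, tolerance = 1e-7)
  # the conjugate backbone requires a missed cleavage at the modified K
  expect_gte(hit$missed_cleavages, 1L)
  # K270R: no conjugate at site 270
  mut <- pk$sequence
  substr(mut, 270, 270) <- "R"
  cj_mut <- enumerate_conjugates(digest(mut, 2))
  expect_false(270 %in% cj_mut$protein_site)
  # peptide without K gives an empty enumeration
  expect_equal(nrow(enumerate_conjugates(digest("AAAGR"))), 0)
})

test_that("conjugate mass decomposes into backbone plus branch residues", {
  bc <- k270_conjugate()
  expect_equal(conjugate_mass(bc),
               peptide_mass("IISKIENHEGVR") + oracle$branch_residue_sum,
               tolerance = 1e-7)
})

test_that("printed native and heavy transition m/z are reproduced", {
  fr <- fragment_conjugate(k270_conjugate(), max_charge = 3)
  pick <- function(fr, ser, idx, z) {
    fr$mz[fr$series == ser & fr$index == idx & fr$charge == z]
  }
  light <- c(pick(fr, "branch-y'", 2, 2), pick(fr, "branch-y'", 3, 2),
             pick(fr, "branch-y'", 5, 2), pick(fr, "backbone-b", 4, 3))
  expect_equal(light, unname(oracle$light), tolerance = 1e-6)
  hl <- k270_heavy_labels()
  bch <- branched_conjugate("IISKIENHEGVR", 4, protein_site = 270,
                            backbone_labels = hl$backbone,
                            branch_labels = hl$branch)
  frh <- fragment_conjugate(bch, max_charge = 3)
  heavy <- c(pick(frh, "branch-y'", 2, 2), pick(frh, "branch-y'", 3, 2),
             pick(frh, "branch-y'", 5, 2), pick(frh, "backbone-b", 4, 3))
  expect_equal(heavy, unname(oracle$heavy), tolerance = 1e-6)
  # after half-up rounding, all eight printed values agree to within 0.01
  expect_true(all(abs(round_half_up(light, 2) - oracle$printed_light) <=
                    0.01 + 1e-9))
  expect_equal(round_half_up(heavy, 2), unname(oracle$printed_heavy))
})

test_that("label shifts land only in fragments containing the residue", {
  hl <- k270_heavy_labels()
  bch <- branched_conjugate("IISKIENHEGVR", 4,
                            backbone_labels = hl$backbone,
                            branch_labels = hl$branch)
  fr0 <- fragment_conjugate(k270_conjugate(), max_charge = 2)
  fr1 <- fragment_conjugate(bch, max_charge = 2)
  # backbone-b3 precedes both labels: identical m/z
  b3 <- fr0$series == "backbone-b" & fr0$index == 3 & fr0$charge == 1
  expect_equal(fr1$mz[b3], fr0$mz[b3])
  # branch-b1 (E) precedes the branch Leu label: identical
  bb1 <- fr0$series == "branch-b" & fr0$index == 1 & fr0$charge == 1
  expect_equal(fr1$mz[bb1], fr0$mz[bb1])
  # branch-b2 contains the labeled Leu: shifted by exactly its increment
  bb2 <- fr0$series == "branch-b" & fr0$index == 2 & fr0$charge == 1
  expect_equal(fr1$mz[bb2] - fr0$mz[bb2], isotope_shift("L"))
})

test_that("diagnostic ion sets match the configured composition", {
  d19 <- diagnostic_ion_set(sumo1_remnant())
  expect_equal(nrow(d19), 19)
  expect_true(all(d19$series == "branch-b"))
  expect_equal(sum(d19$charge == 2), 1)  # only the appended b18^2+
  expect_equal(d19$mz[d19$index == 1 & d19$charge == 1], oracle$b1_E_mz,
               tolerance = 1e-6)
  d_qtgg <- diagnostic_ion_set("QTGG")
  expect_equal(nrow(d_qtgg), 3)
  expect_true(all(d_qtgg$charge == 1))
  expect_error(diagnostic_ion_set("Q"), "too short")
})

test_that("protein-level average mass matches the gel-scale expectation", {
  pk <- read_fasta(pkm2_fasta())
  expect_equal(round(peptide_mass(pk$sequence, "average") / 1000), 58)
})
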