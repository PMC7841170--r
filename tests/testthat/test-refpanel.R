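# refpanel: digestion, masses, diagnostic sites, peptide mapping, FASTA IO

test_that("digest reproduces the worked examples", {
  d <- digest("MKRTPEVDKR", 0)
  expect_equal(d$sequence, c("MK", "R", "TPEVDK", "R"))
  expect_equal(d$start, c(1L, 3L, 4L, 10L))

  expect_equal(digest("AKPGR", 0)$sequence, "AKPGR")  # K before P uncut

  d1 <- digest("TPEVDKEALEK", 1)
  expect_true(all(c("TPEVDK", "EALEK", "TPEVDKEALEK") %in% d1$sequence))
})

test_that("digest matches the brute-force oracle on random sequences", {
  set.seed(101)
  for (trial in 1:100) {
    seq <- random_protein_sequence(sample(1:50, 1))
    mm <- sample(0:2, 1)
    got <- digest(seq, mm)[, c("sequence", "start", "end", "missed_cleavages")]
    rownames(got) <- NULL
    expect_equal(got, oracle_digest(seq, mm))
  }
})

test_that("zero-missed peptides concatenate back to the full sequence", {
  set.seed(7)
  for (trial in 1:25) {
    seq <- random_protein_sequence(sample(5:60, 1))
    d <- digest(seq, 2)
    d0 <- d[d$missed_cleavages == 0L, ]
    expect_identical(paste(d0$sequence[order(d0$start)], collapse = ""), seq)
  }
})

test_that("digest rejects non-canonical residues with the position", {
  expect_error(digest("PEPTXDE", 0), "position 5")
  expect_error(digest("", 0), "empty")
})

test_that("peptide_mass agrees with independent residue summation", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-6)
  # independent hand summation: T+P+E+V+D+K + water
  tpevdk <- 101.04768 + 97.05276 + 129.04259 + 99.06841 + 115.02694 +
    128.09496 + 18.010565
  expect_equal(peptide_mass("TPEVDK"), tpevdk, tolerance = 1e-6)
})

test_that("modification deltas are additive and order-independent", {
  base <- peptide_mass("TPNVDK")
  de <- default_modifications()
  delta <- de$delta[de$mod == "deamidation"]
  expect_equal(peptide_mass("TPNVDK", list(position = 3, mod = "deamidation")),
               base + delta, tolerance = 1e-9)
  two <- data.frame(position = c(3, 6), mod = c("deamidation", "oxidation"))
  expect_equal(peptide_mass("TPNVDK", two),
               peptide_mass("TPNVDK", two[2:1, ]), tolerance = 1e-12)
  # incompatible residue errors naming both
  expect_error(peptide_mass("TPEVDK", list(position = 1, mod = "deamidation")),
               "deamidation.*T|T.*deamidation")
})

test_that("mass is additive over concatenation minus water", {
  set.seed(11)
  for (trial in 1:20) {
    a <- random_protein_sequence(sample(1:15, 1))
    b <- random_protein_sequence(sample(1:15, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("find_diagnostic_sites returns exactly the varying columns", {
  mk <- function(taxon, seq) reference_protein(paste0("P_", taxon), "BLG",
                                               taxon, seq)
  panel <- list(mk("Bos", "AADAA"), mk("Ovis", "AANAA"), mk("Capra", "AAKAA"))
  sites <- find_diagnostic_sites(panel)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$mature_position, 3)
  expect_equal(sites[[1]]$residue_to_taxa[["D"]], "Bos")
  expect_equal(sites[[1]]$residue_to_taxa[["N"]], "Ovis")
  expect_equal(sites[[1]]$residue_to_taxa[["K"]], "Capra")

  # identical sequences: no sites
  expect_length(find_diagnostic_sites(list(mk("Bos", "AADAA"),
                                           mk("Ovis", "AADAA"))), 0)
  # two taxa differing at two columns: exactly two sites (column-wise oracle)
  s2 <- find_diagnostic_sites(list(mk("Bos", "ADAEA"), mk("Ovis", "ANAQA")))
  expect_equal(vapply(s2, `[[`, 0, "mature_position"), c(2, 4))
  # symmetric under reordering
  s_rev <- find_diagnostic_sites(rev(panel))
  expect_equal(vapply(s_rev, `[[`, 0, "mature_position"),
               vapply(sites, `[[`, 0, "mature_position"))
  # unequal lengths: alignment error
  expect_error(find_diagnostic_sites(list(mk("Bos", "AA"), mk("Ovis", "AAA"))),
               "equal length")
})

test_that("map_peptide_position uses mature coordinates", {
  prot <- blg_of("Capra")
  hit <- map_peptide_position("TPEVDK", prot)
  expect_equal(hit$start, 66)
  expect_false(hit$in_signal)
  # planted common peptide at mature 143
  d <- digest(prot, 0)
  p143 <- d$sequence[d$start == 143][1]
  expect_equal(map_peptide_position(p143, prot)$start, 143)
  # absence is a valid result
  expect_null(map_peptide_position("WWWWWW", prot))
  # multiple occurrences warn, first reported
  dup <- reference_protein("DUP", "BLG", "Bos", "AAGLKAAGLK")
  expect_warning(h <- map_peptide_position("AGLK", dup), "2 times")
  expect_equal(h$start, 2)
  # signal-peptide occurrence flagged with non-positive start
  sig <- reference_protein("SIG", "BLG", "Bos", "MWFTGHAAAA",
                           mature_offset = 5L)
  h2 <- map_peptide_position("WFT", sig)
  expect_true(h2$in_signal)
  expect_lt(h2$start, 1)
})

test_that("panel FASTA round-trips through Biostrings-backed IO", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_panel_fasta(test_bundle$panel, path)
  back <- read_panel_fasta(path)
  expect_equal(length(back), length(test_bundle$panel))
  expect_equal(vapply(back, `[[`, "", "accession"),
               vapply(test_bundle$panel, `[[`, "", "accession"))
  i <- which(vapply(back, `[[`, "", "accession") == "BLG_CAPRA")
  expect_equal(back[[i]]$mature_offset, 16L)
  expect_equal(back[[i]]$protein_class, "BLG")
  expect_equal(back[[i]]$full_sequence, blg_of("Capra")$full_sequence)
})

test_that("taxonomy validation and lca behave on the packaged tree", {
  tx <- test_bundle$taxonomy
  expect_equal(lca("Bos", tx)$name, "Bos")
  expect_equal(lca(c("Bos", "Ovis"), tx), list(name = "Bovidae", rank = "family"))
  expect_equal(lca(c("Bos", "Ovis", "Camelus"), tx)$name, "Root")
  expect_error(lca("Equus", tx), "unknown taxon")
  bad <- tx; bad$parent[bad$name == "Bos"] <- "Bos"
  expect_error(validate_taxonomy(bad))
})
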