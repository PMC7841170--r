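# dairy_auth: FDR filter, deamidation-aware matching, LCA labels, the call

panel <- test_bundle$panel
tx <- test_bundle$taxonomy

test_that("FDR filter applies inclusive per-engine thresholds and drops decoys", {
  psms <- rbind(
    make_psm(spectrum_id = "a1", engine = "engine_A", q_value = 0.004),
    make_psm(spectrum_id = "a2", engine = "engine_A", q_value = 0.02),
    make_psm(spectrum_id = "a3", engine = "engine_A", q_value = 0.005),
    make_psm(spectrum_id = "b1", engine = "engine_B", q_value = 0.01),
    make_psm(spectrum_id = "b2", engine = "engine_B", q_value = 0.011),
    make_psm(spectrum_id = "d1", engine = "engine_A", q_value = 0.0001,
             is_decoy = TRUE))
  kept <- filter_psms_by_fdr(psms)
  expect_setequal(kept$spectrum_id, c("a1", "a3", "b1"))
  # idempotent
  expect_equal(filter_psms_by_fdr(kept), kept)
  # empty in, empty out
  expect_equal(nrow(filter_psms_by_fdr(psms[0, ])), 0L)
  # unknown engine errors
  bad <- make_psm(engine = "engine_C")
  expect_error(filter_psms_by_fdr(bad), "engine_C")
})

test_that("worked peptide examples resolve to the expected taxa", {
  # Capra-specific: the K at position 71 creates the short TPEVDK peptide
  m <- match_milk_peptide("TPEVDKEALEK", panel)
  expect_equal(unique(m$taxon), "Capra")
  expect_equal(unique(m$protein_class), "BLG")

  # D at 71 is ambiguous with deamidated N: Bovinae/Ovis disjunction
  ta <- taxon_assignment("TPEVDDEALEKFDK", panel, tx)
  expect_setequal(ta$compatible_taxa, c("Bos", "Bubalus", "Ovis"))
  expect_equal(ta$label, "Bovinae/Ovis")
  expect_equal(ta$resolution_rank, "family")

  # exact matching removes the Ovis branch
  exact <- match_milk_peptide("TPEVDDEALEKFDK", panel, deamidation_aware = FALSE)
  expect_setequal(unique(exact$taxon), c("Bos", "Bubalus"))

  # a conserved-region peptide is compatible with every panel taxon
  bos <- digest(blg_of("Bos"), 0)
  conserved <- bos$sequence[bos$start == 80 & nchar(bos$sequence) >= 6][1]
  all_taxa <- match_milk_peptide(conserved, panel)
  expect_setequal(unique(all_taxa$taxon),
                  c("Bos", "Bubalus", "Ovis", "Capra", "Camelus"))
  expect_error(match_milk_peptide("", panel), "empty")
})

test_that("deamidation-aware matching is a superset of exact matching", {
  pool <- digest(blg_of("Ovis"), 2)
  set.seed(3)
  for (seq in sample(pool$sequence[nchar(pool$sequence) >= 5], 25)) {
    exact <- match_milk_peptide(seq, panel, deamidation_aware = FALSE)
    aware <- match_milk_peptide(seq, panel, deamidation_aware = TRUE)
    key <- function(m) paste(m$taxon, m$protein_class)
    expect_true(all(key(exact) %in% key(aware)))
  }
})

test_that("lca of a union is an ancestor of both partial lcas", {
  leaves <- c("Bos", "Bubalus", "Ovis", "Capra", "Camelus")
  set.seed(5)
  for (trial in 1:30) {
    s1 <- sample(leaves, sample(1:3, 1))
    s2 <- sample(leaves, sample(1:3, 1))
    lu <- lca(union(s1, s2), tx)$name
    anc1 <- paleodairy:::lineage(lca(s1, tx)$name, tx)
    anc2 <- paleodairy:::lineage(lca(s2, tx)$name, tx)
    expect_true(lu %in% anc1 && lu %in% anc2)
  }
})

# identical sequences are grouped adjacently so that cycling engines A/B
# yields dual-engine support for every sequence
milk_evidence <- function(n_psms, sequences, engines = "engine_A") {
  seqs <- sort(rep_len(sequences, n_psms))
  make_psms(n_psms, individual_id = "i1", sample_id = "s1",
            peptide_sequence = seqs, engine = engines,
            protein_accession = "BLG_BOS")
}

p143_bos <- local({
  d <- digest(blg_of("Bos"), 0)
  d$sequence[d$start == 143][1]
})
p66_bos <- local({
  d <- digest(blg_of("Bos"), 0)
  d$sequence[d$start == 66][1]
})

test_that("the dairy-rule truth table holds", {
  # 4 PSMs, 2 unique sequences, >= 2 dual-engine -> positive
  a <- milk_evidence(4, c(p143_bos, p66_bos),
                     engines = c("engine_A", "engine_B"))
  expect_true(call_dairy("i1", a, panel)$positive)

  # 4 PSMs, 1 unique sequence not at 143 -> negative (neither OR branch)
  b <- milk_evidence(4, p66_bos, engines = c("engine_A", "engine_B"))
  cb <- call_dairy("i1", b, panel)
  expect_false(cb$positive)
  expect_false(cb$all_at_common)

  # 5 PSMs, 1 unique sequence, all at 143, dual-engine -> positive
  c5 <- milk_evidence(5, p143_bos, engines = c("engine_A", "engine_B"))
  cc <- call_dairy("i1", c5, panel)
  expect_true(cc$all_at_common)
  expect_true(cc$positive)

  # 4 PSMs, 2 unique, only one engine -> concordance clause fails
  d4 <- milk_evidence(4, c(p143_bos, p66_bos), engines = "engine_A")
  cd <- call_dairy("i1", d4, panel)
  expect_equal(cd$n_dual_engine, 0L)
  expect_false(cd$positive)

  # empty input -> negative with zero tallies
  ce <- call_dairy("i1", a[0, ], panel)
  expect_false(ce$positive)
  expect_equal(ce$n_milk_psms, 0L)

  # sequence-level concordance switch: one dual sequence is below the
  # minimum of two even though both of its PSM rows are dual-supported
  e <- make_psms(4, individual_id = "i1", sample_id = "s1",
                 peptide_sequence = c(p143_bos, p143_bos, p66_bos, p66_bos),
                 engine = c("engine_A", "engine_B", "engine_A", "engine_A"),
                 protein_accession = "BLG_BOS")
  expect_false(call_dairy("i1", e, panel,
                          dairy_rule(dual_unit = "sequence"))$positive)
  expect_true(call_dairy("i1", e, panel)$positive)  # default counts PSM rows
})

test_that("deleting PSMs never converts a negative call to positive", {
  set.seed(9)
  seq_pool <- c(p143_bos, p66_bos,
                digest(blg_of("Bos"), 0)$sequence[c(3, 5)])
  for (trial in 1:100) {
    n <- sample(1:8, 1)
    ev <- make_psms(n, individual_id = "i1",
                    sample_id = sample(c("s1", "s2"), n, replace = TRUE),
                    peptide_sequence = sample(seq_pool, n, replace = TRUE),
                    engine = sample(c("engine_A", "engine_B"), n, replace = TRUE),
                    protein_accession = "BLG_BOS")
    before <- call_dairy("i1", ev, panel)$positive
    keep <- sample(c(TRUE, FALSE), n, replace = TRUE)
    after <- call_dairy("i1", ev[keep, , drop = FALSE], panel)$positive
    expect_false(!before && after)
  }
})

test_that("blg_position_summary reports the recurrent-position percentage", {
  ev <- milk_evidence(52, c(rep(p143_bos, 30), rep(p66_bos, 22)))
  s <- blg_position_summary(ev, panel)
  expect_equal(s$n_at_common, 30L)
  expect_equal(s$n_total, 52L)
  expect_equal(s$pct_common, 57)  # 30/52 -> 57%
  expect_equal(sum(s$table$n_psms), 52L)

  # all PSMs at one position
  one <- blg_position_summary(milk_evidence(5, p143_bos), panel)
  expect_equal(one$pct_common, 100)

  # empty input: undefined fraction
  empty <- blg_position_summary(ev[0, ], panel)
  expect_true(is.na(empty$pct_common))

  # casein PSMs are excluded from the BLG table
  cas <- make_psm(protein_accession = "ALPH_alpha_s1_casein_BOS",
                  peptide_sequence = "XXXX")
  expect_equal(blg_position_summary(cas, panel)$n_total, 0L)
})

test_that("casein PSMs count toward the milk tally in the call", {
  cas_pool <- digest(Filter(function(p)
    p$protein_class == "beta_casein" && p$taxon == "Bos", panel)[[1]], 0)
  cas_seq <- cas_pool$sequence[nchar(cas_pool$sequence) >= 6][1]
  ev <- rbind(milk_evidence(3, c(p143_bos, p66_bos),
                            engines = c("engine_A", "engine_B")),
              make_psms(2, individual_id = "i1", sample_id = "s1",
                        peptide_sequence = cas_seq,
                        engine = c("engine_A", "engine_B"),
                        protein_accession = "BETA_beta_casein_BOS"))
  cl <- call_dairy("i1", ev, panel)
  expect_equal(cl$n_milk_psms, 5L)
  expect_true(cl$positive)
})
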