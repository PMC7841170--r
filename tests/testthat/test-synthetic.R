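# synthetic_data: planted structure is recovered, outputs are deterministic

test_that("the panel generator is byte-deterministic under a fixed seed", {
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_panel_fasta(simulate_reference_panel(seed = 5)$panel, f1)
  write_panel_fasta(simulate_reference_panel(seed = 5)$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed, different backbone
  f3 <- withr::local_tempfile(fileext = ".fasta")
  write_panel_fasta(simulate_reference_panel(seed = 6)$panel, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("planted diagnostic columns are exactly the recovered ones", {
  b <- simulate_reference_panel(taxa = c("Bos", "Ovis", "Capra"), seed = 12)
  sites <- find_diagnostic_sites(Filter(function(p) p$protein_class == "BLG",
                                        b$panel))
  expect_equal(vapply(sites, `[[`, 0L, "mature_position"),
               b$diagnostic_columns)
})

test_that("the planted N/D column makes the D peptide ambiguous", {
  b <- simulate_reference_panel(seed = 12)
  bos <- Filter(function(p) p$protein_class == "BLG" && p$taxon == "Bos",
                b$panel)[[1]]
  d <- digest(bos, 0)
  d_peptide <- d$sequence[d$start == 66][1]  # carries D at column 71
  aware <- match_milk_peptide(d_peptide, b$panel)
  expect_true(all(c("Bos", "Ovis") %in% aware$taxon))
  exact <- match_milk_peptide(d_peptide, b$panel, deamidation_aware = FALSE)
  expect_false("Ovis" %in% exact$taxon)
})

test_that("cohort PSM tables are deterministic and structurally valid", {
  spec <- cohort_spec(n_individuals = 5, consumers = 1:2, seed = 33)
  p1 <- simulate_cohort_psms(spec, test_bundle)
  p2 <- simulate_cohort_psms(spec, test_bundle)
  expect_identical(p1, p2)
  expect_true(all(p1$q_value >= 0 & p1$q_value <= 1))
  # decoy q-values bounded away from both FDR thresholds by default
  expect_true(all(p1$q_value[p1$is_decoy] > 0.01))
  # target q-values below their engine thresholds
  tgt <- p1[!p1$is_decoy, ]
  thr <- c(engine_A = 0.005, engine_B = 0.01)
  expect_true(all(tgt$q_value <= thr[tgt$engine]))
})

test_that("consumers yield positive calls and non-consumers none", {
  spec <- cohort_spec(n_individuals = 6, consumers = c(2, 5),
                      milk_psm_count = 6, dual_engine_prob = 1, seed = 44)
  psms <- simulate_cohort_psms(spec, test_bundle)
  acc <- vapply(test_bundle$panel, `[[`, "", "accession")
  cls <- vapply(test_bundle$panel, `[[`, "", "protein_class")
  filtered <- filter_psms_by_fdr(psms)
  milk <- filtered[cls[match(filtered$protein_accession, acc)] %in%
                     c("BLG", "alpha_s1_casein", "alpha_s2_casein",
                       "beta_casein", "kappa_casein"), ]
  for (ind in sprintf("IND%03d", 1:6)) {
    cl <- call_dairy(ind, milk[milk$individual_id == ind, ], test_bundle$panel)
    expect_equal(cl$positive, ind %in% c("IND002", "IND005"))
  }
  # non-consumers received zero milk PSMs at the source
  expect_equal(sort(unique(milk$individual_id)), c("IND002", "IND005"))
})

test_that("peak-list and isotope generators are seed-deterministic", {
  lib <- toy_marker_library()
  expect_identical(simulate_peaklist("Bos", lib, seed = 3),
                   simulate_peaklist("Bos", lib, seed = 3))
  i1 <- simulate_isotope_table(seed = 9)
  i2 <- simulate_isotope_table(seed = 9)
  expect_identical(i1, i2)
})

test_that("isotope drift is applied to samples and standards alike and undone", {
  iso <- simulate_isotope_table(drift = c(intercept = 0.5, slope = 1),
                                seed = 10)
  cal <- calibrate(iso$measurements, iso$standards)
  expect_equal(cal$measurements$calibrated_delta, iso$truth, tolerance = 1e-9)
  # identity drift: calibrated equals raw
  iso0 <- simulate_isotope_table(seed = 10)
  cal0 <- calibrate(iso0$measurements, iso0$standards)
  expect_equal(cal0$measurements$calibrated_delta,
               cal0$measurements$raw_delta, tolerance = 1e-9)
})

test_that("planted group means are recovered after drift correction", {
  groups <- default_isotope_groups()
  groups$n <- 50L
  iso <- simulate_isotope_table(groups, drift = c(intercept = 0.5, slope = 1),
                                seed = 11)
  cal <- calibrate(iso$measurements, iso$standards)
  s <- group_summary(cal$measurements, by = c("site", "taxon", "system"))
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    row <- s[s$site == g$site & s$taxon == g$taxon & s$system == g$system, ]
    expect_lt(abs(row$mean - g$mean), 3 * g$sd / sqrt(g$n))
  }
})
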