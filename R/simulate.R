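# Synthetic-data generation: toy reference panels, dual-engine PSM tables
# with planted oral/dietary/contaminant/decoy structure, MALDI peak lists
# and isotope tables. Everything is seeded and deterministic so the whole
# pipeline is testable without downloads.
#
# The toy beta-lactoglobulin orthologs are synthetic sequences, not real
# database entries, but reproduce the structural features the analysis
# depends on: a diagnostic column at mature position 71 carrying D (Bos,
# Bubalus), N (Ovis), K (Capra) and S (Camelus) -- so deamidation makes the
# D/N taxa ambiguous while the Capra K creates an extra cleavage site -- a
# second diagnostic column at 148, and a frequently recovered tryptic
# peptide starting at mature position 143.

# backbone alphabet: no C (fixed-mod bookkeeping), no K/R (cleavage is
# planted explicitly), no P (never blocks a planted cleavage site)
BACKBONE_ALPHABET <- c("A", "D", "E", "F", "G", "H", "I", "L", "M", "N",
                       "Q", "S", "T", "V", "W", "Y")

PANEL_TAXA <- c("Bos", "Bubalus", "Ovis", "Capra", "Camelus")

# residue carried at the two planted diagnostic columns, per taxon
BLG_DIAGNOSTIC <- list(
  `71`  = c(Bos = "D", Bubalus = "D", Ovis = "N", Capra = "K", Camelus = "S"),
  `148` = c(Bos = "L", Bubalus = "L", Ovis = "L", Capra = "I", Camelus = "V"))

#' Packaged toy taxonomy
#'
#' Small rooted tree over the milk panel taxa (genus up to infraorder) plus
#' host and oral-microbe genera. Bovinae covers Bos and Bubalus, Caprinae
#' covers Ovis and Capra, both under Bovidae and the infraorder Pecora;
#' Camelus sits apart under Camelidae.
#'
#' @return Taxonomy data.frame (`name`, `rank`, `parent`).
#' @export
toy_taxonomy <- function() {
  tx <- data.frame(
    name = c("Root", "Pecora", "Bovidae", "Bovinae", "Caprinae",
             "Bos", "Bubalus", "Ovis", "Capra", "Camelidae", "Camelus",
             "Homo", "Streptococcus", "Actinomyces", "Rothia",
             "Fusobacterium", "Neisseria"),
    rank = c("root", "infraorder", "family", "subfamily", "subfamily",
             "genus", "genus", "genus", "genus", "family", "genus",
             "genus", "genus", "genus", "genus", "genus", "genus"),
    parent = c(NA, "Root", "Pecora", "Bovidae", "Bovidae",
               "Bovinae", "Bovinae", "Caprinae", "Caprinae", "Root",
               "Camelidae", "Root", "Root", "Root", "Root", "Root", "Root"),
    stringsAsFactors = FALSE)
  validate_taxonomy(tx)
}

random_backbone <- function(n) {
  paste(sample(BACKBONE_ALPHABET, n, replace = TRUE), collapse = "")
}

# protein built as consecutive segments of (segment_len - 1) backbone
# residues closed by K or R, so every zero-missed tryptic peptide has a
# known, uniform length
segmented_sequence <- function(n_segments, segment_len = 12L) {
  segs <- vapply(seq_len(n_segments), function(i) {
    paste0(random_backbone(segment_len - 1L), sample(c("K", "R"), 1L))
  }, "")
  paste(segs, collapse = "")
}

#' Simulate the reference panel, taxonomy and oral-signature reference
#'
#' Builds aligned toy beta-lactoglobulin orthologs for the requested taxa
#' (default Bos, Bubalus, Ovis, Capra, Camelus) differing exactly at the
#' planted diagnostic columns, the four casein classes per taxon, oral
#' signature proteins, host inflammatory proteins, common contaminants, and
#' reversed-sequence decoys. Identical seed gives byte-identical output.
#'
#' @param taxa Milk taxa to include (>= 2, subset of the toy taxonomy).
#' @param n_oral_proteins Number of oral-signature proteins.
#' @param n_contaminants Number of contaminant proteins.
#' @param seed Random seed.
#' @return List: `panel` (list of [reference_protein()]), `taxonomy`,
#'   `ossd` (accession/category data.frame), `diagnostic_columns`.
#' @export
simulate_reference_panel <- function(taxa = PANEL_TAXA, n_oral_proteins = 8L,
                                     n_contaminants = 3L, seed = 1L) {
  if (length(taxa) < 2L) stop("need >= 2 taxa")
  stopifnot(all(taxa %in% PANEL_TAXA))
  set.seed(seed)
  tx <- toy_taxonomy()

  # --- beta-lactoglobulin: shared 162-residue mature backbone -------------
  blg_len <- 162L
  bb <- strsplit(random_backbone(blg_len), "", fixed = TRUE)[[1]]
  cuts <- c(8L, 18L, 29L, 41L, 53L, 91L, 103L, 115L, 127L)
  bb[cuts] <- rep(c("K", "R"), length.out = length(cuts))
  bb[65L] <- "K"
  bb[66:79] <- strsplit("TPEVD?EALEKFDK", "", fixed = TRUE)[[1]]
  bb[142L] <- "K"
  bb[143:157] <- strsplit("VYVEE?NDQSLAMTR", "", fixed = TRUE)[[1]]
  signal <- "MKCLLLALALTCGAQA"  # 16-residue signal peptide, shared

  panel <- list()
  for (t in taxa) {
    aa <- bb
    aa[71L] <- BLG_DIAGNOSTIC[["71"]][[t]]
    aa[148L] <- BLG_DIAGNOSTIC[["148"]][[t]]
    panel[[length(panel) + 1L]] <- reference_protein(
      accession = paste0("BLG_", toupper(t)), protein_class = "BLG",
      taxon = t, full_sequence = paste0(signal, paste(aa, collapse = "")),
      mature_offset = nchar(signal))
  }

  # --- caseins: one shared backbone per class, diagnostic column 30 -------
  casein_classes <- c("alpha_s1_casein", "alpha_s2_casein", "beta_casein",
                      "kappa_casein")
  cas_res <- stats::setNames(c("G", "A", "S", "T", "V")[seq_along(PANEL_TAXA)],
                             PANEL_TAXA)
  for (cc in casein_classes) {
    cas_bb <- strsplit(random_backbone(84L), "", fixed = TRUE)[[1]]
    cas_bb[c(9L, 20L, 31L, 42L, 53L, 64L, 75L)] <-
      rep(c("K", "R"), length.out = 7L)
    cas_sig <- random_backbone(15L)
    for (t in taxa) {
      aa <- cas_bb
      aa[30L] <- cas_res[[t]]
      panel[[length(panel) + 1L]] <- reference_protein(
        accession = paste0(toupper(substr(cc, 1, 4)), "_", cc, "_", toupper(t)),
        protein_class = cc, taxon = t,
        full_sequence = paste0(cas_sig, paste(aa, collapse = "")),
        mature_offset = 15L)
    }
  }

  # --- oral signature, host, contaminant entries --------------------------
  oral_taxa <- c("Streptococcus", "Actinomyces", "Rothia", "Fusobacterium",
                 "Neisseria")
  ossd <- data.frame(accession = character(), category = character(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_oral_proteins)) {
    acc <- sprintf("ORAL_%02d", i)
    panel[[length(panel) + 1L]] <- reference_protein(
      accession = acc, protein_class = "oral_signature",
      taxon = oral_taxa[(i - 1L) %% length(oral_taxa) + 1L],
      full_sequence = segmented_sequence(10L))
    ossd <- rbind(ossd, data.frame(accession = acc, category = "oral_microbe"))
  }
  for (i in 1:2) {
    acc <- sprintf("HOST_%02d", i)
    panel[[length(panel) + 1L]] <- reference_protein(
      accession = acc, protein_class = "human_host", taxon = "Homo",
      full_sequence = segmented_sequence(9L))
    ossd <- rbind(ossd,
                  data.frame(accession = acc, category = "human_inflammatory"))
  }
  for (i in seq_len(n_contaminants)) {
    acc <- sprintf("CONT_%02d", i)  # keratin-like handling contaminants
    panel[[length(panel) + 1L]] <- reference_protein(
      accession = acc, protein_class = "contaminant", taxon = "Homo",
      full_sequence = segmented_sequence(8L))
    ossd <- rbind(ossd, data.frame(accession = acc, category = "contaminant"))
  }

  # --- reversed decoys of the milk entries --------------------------------
  milk <- Filter(function(p) p$protein_class %in% MILK_CLASSES, panel)
  for (p in milk[seq_len(min(5L, length(milk)))]) {
    panel[[length(panel) + 1L]] <- reference_protein(
      accession = paste0("DECOY_", p$accession), protein_class = "decoy",
      taxon = p$taxon,
      full_sequence = paste(rev(strsplit(p$full_sequence, "",
                                         fixed = TRUE)[[1]]), collapse = ""))
  }

  list(panel = panel, taxonomy = tx, ossd = ossd,
       diagnostic_columns = c(71L, 148L))
}

#' Cohort specification for the PSM simulator
#'
#' Defaults describe the simulated study world used throughout the tests:
#' a 40-individual cohort with one calculus sample each, eight dairy
#' consumers with guaranteed evidence (six milk PSMs, both engines), 30%
#' deamidation of N/Q sites, 10% non-specific cleavage (inside the range
#' reported for degraded calculus), and decoy q-values bounded away from the
#' FDR thresholds unless `decoy_leak` is set.
#'
#' @param n_individuals Cohort size.
#' @param samples_per_individual Calculus samples per individual.
#' @param consumers Integer indices of dairy-consuming individuals.
#' @param planted_taxon Milk taxon per consumer (recycled).
#' @param oral_positive Logical per individual: does its calculus carry an
#'   oral signature (non-positive samples are built to fail screening).
#' @param n_oral_proteins Oral-signature protein groups per positive sample.
#' @param milk_psm_count First-engine milk PSMs per consumer sample.
#' @param deamidation_prob Per-site N/Q deamidation probability.
#' @param nonspecific_prob Per-PSM probability of a non-specific terminus.
#' @param dual_engine_prob Probability a milk PSM is also reported by the
#'   second engine.
#' @param decoy_rate Decoy PSMs as a fraction of target PSMs.
#' @param decoy_leak If TRUE decoy q-values may fall below the FDR
#'   thresholds (adversarial mode); by default they are bounded away.
#' @param seed Random seed.
#' @return `cohort_spec` list.
#' @export
cohort_spec <- function(n_individuals = 40L, samples_per_individual = 1L,
                        consumers = 1:8,
                        planted_taxon = c("Capra", "Bos", "Ovis"),
                        oral_positive = rep(TRUE, n_individuals),
                        n_oral_proteins = 5L, milk_psm_count = 6L,
                        deamidation_prob = 0.3, nonspecific_prob = 0.1,
                        dual_engine_prob = 1.0, decoy_rate = 0.1,
                        decoy_leak = FALSE, seed = 1L) {
  probs <- c(deamidation_prob, nonspecific_prob, dual_engine_prob, decoy_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(consumers) && (max(consumers) > n_individuals || min(consumers) < 1)) {
    stop("consumer indices outside 1..n_individuals")
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    samples_per_individual = as.integer(samples_per_individual),
    consumers = as.integer(consumers),
    planted_taxon = rep_len(planted_taxon, max(length(consumers), 1L)),
    oral_positive = rep_len(oral_positive, n_individuals),
    n_oral_proteins = as.integer(n_oral_proteins),
    milk_psm_count = as.integer(milk_psm_count),
    deamidation_prob = deamidation_prob,
    nonspecific_prob = nonspecific_prob,
    dual_engine_prob = dual_engine_prob,
    decoy_rate = decoy_rate, decoy_leak = decoy_leak,
    seed = as.integer(seed)), class = "cohort_spec")
}

# draw deamidation modifications for the N/Q sites of a sequence
draw_deamidation <- function(sequence, prob) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sites <- which(aa %in% c("N", "Q"))
  hit <- sites[stats::runif(length(sites)) < prob]
  if (length(hit) == 0L) return("")
  paste(sprintf("%d:deamidation", hit), collapse = ";")
}

# truncate a tryptic peptide at the C terminus so that it classifies as
# semi-tryptic against its parent; k chosen so the new terminus is not K/R
truncate_nonspecific <- function(sequence) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (k in 1:3) {
    n <- length(aa) - k
    if (n >= 5L && !aa[n] %in% c("K", "R")) {
      return(paste(aa[1:n], collapse = ""))
    }
  }
  sequence
}

#' Simulate dual-engine PSM tables for a cohort
#'
#' For each sample draws oral-signature, host, contaminant and decoy PSMs;
#' dairy consumers additionally receive `milk_psm_count` milk PSMs from the
#' planted taxon's digested peptides (at least two unique sequences, with
#' the recurrent position-143 peptide over-represented), each independently
#' also reported by the second engine with `dual_engine_prob`. Deamidation
#' and non-specific termini are injected at the configured rates. Target
#' q-values are drawn below the engine FDR thresholds and decoy q-values
#' above them (unless `decoy_leak`).
#'
#' @param spec A [cohort_spec()].
#' @param panel_bundle Output of [simulate_reference_panel()].
#' @return PSM data.frame (both engines, all samples) with the standard
#'   columns; `sample_id` is `"<individual>_s<k>"`.
#' @export
simulate_cohort_psms <- function(spec, panel_bundle) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  panel <- panel_bundle$panel
  acc <- vapply(panel, `[[`, "", "accession")
  cls <- vapply(panel, `[[`, "", "protein_class")
  ptax <- vapply(panel, `[[`, "", "taxon")

  # peptide pools (sequence, start, accession) per source class
  pool_for <- function(idx, max_missed = 0L) {
    do.call(rbind, lapply(idx, function(j) {
      d <- digest(panel[[j]], max_missed)
      d <- d[nchar(d$sequence) >= 6L, , drop = FALSE]
      if (nrow(d) == 0L) return(NULL)
      data.frame(sequence = d$sequence, start = d$start,
                 accession = acc[j], stringsAsFactors = FALSE)
    }))
  }
  oral_pools <- lapply(which(cls == "oral_signature"), function(j) pool_for(j))
  names(oral_pools) <- acc[cls == "oral_signature"]
  host_pool <- pool_for(which(cls == "human_host"))
  cont_pool <- pool_for(which(cls == "contaminant"))
  decoy_pool <- pool_for(which(cls == "decoy"))
  milk_pool_for <- function(taxon) {
    blg <- which(cls == "BLG" & ptax == taxon)
    cas <- which(cls %in% setdiff(MILK_CLASSES, "BLG") & ptax == taxon)
    list(blg = pool_for(blg, max_missed = 1L), casein = pool_for(cas))
  }

  q_target <- function(engine, n) {
    if (engine == "engine_A") stats::runif(n, 0, 0.004) else stats::runif(n, 0, 0.009)
  }
  q_decoy <- function(n) {
    if (spec$decoy_leak) stats::runif(n, 0, 0.05) else stats::runif(n, 0.05, 0.5)
  }

  rows <- list()
  spectrum_counter <- c(engine_A = 0L, engine_B = 0L)
  emit <- function(sample_id, individual_id, sequence, accession, engine,
                   q, decoy = FALSE) {
    spectrum_counter[[engine]] <<- spectrum_counter[[engine]] + 1L
    mods <- if (decoy) "" else draw_deamidation(sequence, spec$deamidation_prob)
    if (!decoy && stats::runif(1) < spec$nonspecific_prob) {
      trunc <- truncate_nonspecific(sequence)
      if (nchar(trunc) < nchar(sequence)) {
        # drop deamidation calls beyond the new terminus
        m <- parse_modifications(mods)
        mods <- format_modifications(m[m$position <= nchar(trunc), , drop = FALSE])
        sequence <- trunc
      }
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, individual_id = individual_id,
      spectrum_id = sprintf("%s_S%06d", engine, spectrum_counter[[engine]]),
      peptide_sequence = sequence, modifications = mods,
      protein_accession = accession, engine = engine,
      score = round(stats::runif(1, if (decoy) 100 else 250,
                                 if (decoy) 300 else 600), 1),
      q_value = q, is_decoy = decoy, stringsAsFactors = FALSE)
  }

  consumer_taxon <- stats::setNames(spec$planted_taxon[seq_along(spec$consumers)],
                                    spec$consumers)
  for (ind in seq_len(spec$n_individuals)) {
    individual_id <- sprintf("IND%03d", ind)
    for (s in seq_len(spec$samples_per_individual)) {
      sample_id <- sprintf("%s_s%d", individual_id, s)
      # oral signature PSMs
      if (spec$oral_positive[ind]) {
        use <- sample(names(oral_pools), min(spec$n_oral_proteins,
                                             length(oral_pools)))
        for (a in use) {
          pool <- oral_pools[[a]]
          picks <- pool[sample(nrow(pool), min(3L, nrow(pool))), , drop = FALSE]
          for (i in seq_len(nrow(picks))) {
            emit(sample_id, individual_id, picks$sequence[i], a, "engine_A",
                 q_target("engine_A", 1))
          }
        }
      } else {
        # degraded/handled sample: a single weakly supported oral group
        pool <- oral_pools[[sample(names(oral_pools), 1L)]]
        emit(sample_id, individual_id, pool$sequence[1], pool$accession[1],
             "engine_A", q_target("engine_A", 1))
      }
      # host + contaminant background
      for (i in sample(nrow(host_pool), 4L)) {
        emit(sample_id, individual_id, host_pool$sequence[i],
             host_pool$accession[i], "engine_A", q_target("engine_A", 1))
      }
      for (i in sample(nrow(cont_pool), 4L)) {
        emit(sample_id, individual_id, cont_pool$sequence[i],
             cont_pool$accession[i], "engine_A", q_target("engine_A", 1))
      }
      # milk evidence for consumers
      if (ind %in% spec$consumers) {
        pools <- milk_pool_for(consumer_taxon[[as.character(ind)]])
        blg <- pools$blg
        p143 <- blg[blg$start == 143L & nchar(blg$sequence) == 15L, , drop = FALSE]
        pdiag <- blg[blg$start == 66L, , drop = FALSE]
        pdiag <- pdiag[which.max(nchar(pdiag$sequence)), , drop = FALSE]
        others <- rbind(blg[!(rownames(blg) %in%
                              rownames(rbind(p143, pdiag))), , drop = FALSE],
                        pools$casein)
        for (k in seq_len(spec$milk_psm_count)) {
          pick <- if (k == 1L) p143
                  else if (k == 2L) pdiag
                  else if (stats::runif(1) < 0.55) p143
                  else others[sample(nrow(others), 1L), , drop = FALSE]
          qa <- q_target("engine_A", 1)
          emit(sample_id, individual_id, pick$sequence[1], pick$accession[1],
               "engine_A", qa)
          if (stats::runif(1) < spec$dual_engine_prob) {
            emit(sample_id, individual_id, pick$sequence[1], pick$accession[1],
                 "engine_B", q_target("engine_B", 1))
          }
        }
      }
      # decoys
      n_targets <- sum(vapply(rows, function(r) r$sample_id == sample_id,
                              logical(1)))
      n_decoys <- round(spec$decoy_rate * n_targets)
      if (n_decoys > 0L) {
        for (i in sample(nrow(decoy_pool), min(n_decoys, nrow(decoy_pool)))) {
          emit(sample_id, individual_id, decoy_pool$sequence[i],
               decoy_pool$accession[i], "engine_A", q_decoy(1), decoy = TRUE)
        }
      }
    }
  }
  psms <- do.call(rbind, rows)
  rownames(psms) <- NULL
  validate_psms(psms)
}

#' Packaged toy ZooMS marker library
#'
#' Named placeholder collagen markers for Bos, Ovis and Capra: one mass
#' shared across taxa plus taxon-specific masses, in the typical MALDI-TOF
#' marker range. Real marker masses are user-supplied data.
#'
#' @return data.frame `taxon`, `marker_name`, `mass`.
#' @export
toy_marker_library <- function() {
  rbind(
    data.frame(taxon = "Bos", marker_name = paste0("m", 1:6),
               mass = c(1105.58, 1208.72, 1427.70, 1580.80, 2131.10, 2792.45)),
    data.frame(taxon = "Ovis", marker_name = paste0("m", 1:6),
               mass = c(1105.58, 1180.65, 1427.70, 1550.76, 2111.05, 2883.50)),
    data.frame(taxon = "Capra", marker_name = paste0("m", 1:6),
               mass = c(1105.58, 1180.65, 1439.72, 1550.76, 2163.09, 2883.50)))
}

#' Simulate a MALDI peak list for a taxon
#'
#' Emits the taxon's marker masses with Gaussian jitter plus uniform noise
#' peaks placed at least twice the matching tolerance away from every
#' library marker (of any taxon).
#'
#' @param taxon Taxon in the library; `NA` gives a pure-noise peak list.
#' @param library Marker library data.frame.
#' @param n_noise_peaks Number of noise peaks.
#' @param mass_jitter_sd SD of marker mass jitter (Da).
#' @param tolerance Matching tolerance the noise avoids (Da).
#' @param mz_range Range for noise peaks.
#' @param seed Random seed.
#' @return A [peaklist()].
#' @export
simulate_peaklist <- function(taxon, library, n_noise_peaks = 15L,
                              mass_jitter_sd = 0.05, tolerance = 0.2,
                              mz_range = c(800, 3000), seed = 1L) {
  set.seed(seed)
  mz <- numeric(); intensity <- numeric()
  if (!is.na(taxon)) {
    if (!taxon %in% library$taxon) stop(sprintf("taxon '%s' not in library", taxon))
    m <- library$mass[library$taxon == taxon]
    mz <- m + stats::rnorm(length(m), 0, mass_jitter_sd)
    intensity <- stats::runif(length(m), 3000, 10000)
  }
  all_markers <- library$mass
  n_placed <- 0L
  while (n_placed < n_noise_peaks) {
    cand <- stats::runif(1, mz_range[1], mz_range[2])
    if (all(abs(cand - all_markers) > 2 * tolerance)) {
      mz <- c(mz, cand)
      intensity <- c(intensity, stats::runif(1, 500, 3000))
      n_placed <- n_placed + 1L
    }
  }
  peaklist(sprintf("sim_%s", ifelse(is.na(taxon), "blank", taxon)), mz, intensity)
}

#' Default isotope group means for the simulator
#'
#' The planted world mirrors the archaeological setting: human bone collagen
#' d15N well above associated Bos/Capra fauna (trophic enrichment), C4-range
#' collagen d13C, and variable enamel d18O.
#'
#' @return data.frame `site`, `taxon`, `material`, `system`, `mean`, `sd`, `n`.
#' @export
default_isotope_groups <- function() {
  data.frame(
    site = c("Lukenya Hill", "Lukenya Hill", "Molo Cave", "Molo Cave",
             "Lukenya Hill", "Lukenya Hill", "Lukenya Hill", "Molo Cave"),
    taxon = c("human", "Bos", "human", "Bos", "human", "Bos", "human", "human"),
    material = c("collagen", "collagen", "collagen", "collagen",
                 "collagen", "collagen", "enamel", "enamel"),
    system = c("d15N", "d15N", "d15N", "d15N", "d13C", "d13C", "d18O", "d18O"),
    mean = c(12.7, 8.0, 11.6, 7.0, -7.5, -7.0, -1.4, -2.0),
    sd = c(0.5, 0.5, 0.5, 0.5, 0.8, 0.8, 1.2, 1.2),
    n = c(6L, 4L, 5L, 4L, 6L, 4L, 6L, 6L),
    stringsAsFactors = FALSE)
}

#' Default certified standards
#'
#' Certified delta values of the international standards used for collagen
#' and carbonate calibration (IAEA-CH-6, IAEA-N-2, USGS40, NBS 18, IAEA-603).
#'
#' @return data.frame `name`, `system`, `certified`.
#' @export
default_isotope_standards <- function() {
  data.frame(
    name = c("IAEA-CH-6", "USGS40", "IAEA-N-2", "USGS40",
             "NBS18", "IAEA-603"),
    system = c("d13C", "d13C", "d15N", "d15N", "d18O", "d18O"),
    certified = c(-10.80, -26.38, 20.3, 4.5, -23.2, -2.37),
    stringsAsFactors = FALSE)
}

#' Simulate an isotope measurement run with instrument drift
#'
#' Gaussian draws per group; an affine instrument drift (delta_measured =
#' intercept + slope * delta_true) is applied to samples and standards
#' alike, so [calibrate()] must undo it exactly in expectation.
#'
#' @param groups Group table ([default_isotope_groups()]).
#' @param standards Certified standards ([default_isotope_standards()]).
#' @param drift c(intercept, slope) of the instrument transform.
#' @param seed Random seed.
#' @return List: `measurements` (with `raw_delta` = drifted values),
#'   `standards` (with `measured`), `truth` (undrifted sample deltas).
#' @export
simulate_isotope_table <- function(groups = default_isotope_groups(),
                                   standards = default_isotope_standards(),
                                   drift = c(intercept = 0, slope = 1),
                                   seed = 1L) {
  set.seed(seed)
  apply_drift <- function(x) drift[[1]] + drift[[2]] * x
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    true <- stats::rnorm(g$n, g$mean, g$sd)
    data.frame(specimen_id = sprintf("%s_%s_%s_%02d",
                                     gsub(" ", "", g$site), g$taxon, g$system,
                                     seq_len(g$n)),
               taxon = g$taxon, site = g$site, material = g$material,
               system = g$system, raw_delta = apply_drift(true),
               true_delta = true, source = "this_study",
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  st <- standards
  st$measured <- apply_drift(st$certified)
  truth <- m$true_delta
  m$true_delta <- NULL
  list(measurements = m, standards = st, truth = truth)
}
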