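# End-to-end orchestration mirroring the study design: oral-signature gate
# -> engine-specific FDR filter -> per-individual dairy call -> preservation
# QC -> cohort summaries. Samples failing the screen are excluded from
# dietary calls but retained in QC output.

#' Run the calculus authentication pipeline
#'
#' @param psms PSM data.frame (both engines, all samples).
#' @param panel Reference panel (list of [reference_protein()]).
#' @param tx Taxonomy data.frame.
#' @param ossd Oral signature reference data.frame.
#' @param threshold [screen_threshold()].
#' @param engine_thresholds Per-engine FDR thresholds
#'   (see [filter_psms_by_fdr()]).
#' @param rule [dairy_rule()].
#' @param min_sites Deamidation sufficiency threshold for QC.
#' @param deamidation_aware Use deamidation-aware peptide matching.
#' @param verbose Log stage counts to the console.
#' @return A `cohort_report` list: `screening`, `qc`, `dairy_calls`,
#'   `assignments`, `blg_positions`, `tallies`.
#' @export
run_pipeline <- function(psms, panel, tx, ossd,
                         threshold = screen_threshold(),
                         engine_thresholds = c(engine_A = 0.005, engine_B = 0.01),
                         rule = dairy_rule(), min_sites = 10L,
                         deamidation_aware = TRUE, verbose = FALSE) {
  psms <- validate_psms(psms)
  say <- function(...) if (verbose) message(sprintf(...))
  samples <- unique(psms$sample_id)
  sample_to_individual <- vapply(samples, function(s) {
    unique(psms$individual_id[psms$sample_id == s])[1]
  }, "")
  say("stage 1/4 screening: %d samples, %d PSMs", length(samples), nrow(psms))

  # --- stage 1: oral signature screen -------------------------------------
  screen_results <- lapply(samples, function(s) {
    screen_sample(psms[psms$sample_id == s, , drop = FALSE], ossd, threshold)
  })
  screening <- do.call(rbind, lapply(screen_results, function(r) {
    data.frame(sample_id = r$sample_id,
               individual_id = sample_to_individual[[r$sample_id]],
               n_oral_protein_groups = r$n_oral_protein_groups,
               n_host_protein_groups = r$n_host_protein_groups,
               n_contaminant_groups = r$n_contaminant_groups,
               passed = r$passed, stringsAsFactors = FALSE)
  }))
  passing_samples <- screening$sample_id[screening$passed]
  say("  %d samples passed", length(passing_samples))

  # --- stage 2: QC on all samples (screen failures retained here) ---------
  qc <- do.call(rbind, lapply(samples, function(s) {
    r <- qc_report(psms[psms$sample_id == s & !psms$is_decoy, , drop = FALSE],
                   panel, min_sites)
    data.frame(sample_id = s, n_psms = r$n_psms,
               fraction_nonspecific = r$fraction_nonspecific,
               n_deamidation_sites_NQ = r$n_deamidation_sites_NQ,
               fraction_deamidated = r$fraction_deamidated,
               sufficient_sites = r$sufficient_sites, stringsAsFactors = FALSE)
  }))

  # --- stage 3: FDR filter + dairy calls (screened samples only) ----------
  gated <- psms[psms$sample_id %in% passing_samples, , drop = FALSE]
  filtered <- filter_psms_by_fdr(gated, engine_thresholds)
  acc <- vapply(panel, `[[`, "", "accession")
  cls <- vapply(panel, `[[`, "", "protein_class")
  milk <- filtered[cls[match(filtered$protein_accession, acc)] %in%
                     MILK_CLASSES, , drop = FALSE]
  say("stage 3/4 dairy: %d milk PSMs after FDR filter", nrow(milk))

  individuals <- unique(sample_to_individual[passing_samples])
  calls <- lapply(individuals, function(ind) {
    call_dairy(ind, milk[milk$individual_id == ind, , drop = FALSE], panel, rule)
  })
  dairy_calls <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(individual_id = cl$individual_id, n_milk_psms = cl$n_milk_psms,
               n_unique_sequences = cl$n_unique_sequences,
               n_dual_engine = cl$n_dual_engine,
               all_at_common = cl$all_at_common, positive = cl$positive,
               stringsAsFactors = FALSE)
  }))
  if (is.null(dairy_calls)) {
    dairy_calls <- data.frame(individual_id = character(),
                              n_milk_psms = integer(),
                              n_unique_sequences = integer(),
                              n_dual_engine = integer(),
                              all_at_common = logical(), positive = logical())
  }

  # per-peptide taxonomic assignments for the evidence
  uniq <- unique(milk[, c("individual_id", "peptide_sequence", "modifications")])
  assignments <- do.call(rbind, lapply(seq_len(nrow(uniq)), function(i) {
    ta <- taxon_assignment(uniq$peptide_sequence[i], panel, tx,
                           parse_modifications(uniq$modifications[i]),
                           deamidation_aware)
    if (is.null(ta)) return(NULL)
    data.frame(individual_id = uniq$individual_id[i],
               peptide_sequence = ta$peptide_sequence, label = ta$label,
               lca_name = ta$lca_name, resolution_rank = ta$resolution_rank,
               protein_classes = paste(ta$protein_classes, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(assignments)) {
    assignments <- data.frame(individual_id = character(),
                              peptide_sequence = character(),
                              label = character(), lca_name = character(),
                              resolution_rank = character(),
                              protein_classes = character())
  }

  blg <- blg_position_summary(milk, panel, rule$common_position)

  # --- stage 4: cohort tallies (recomputable from the row-level tables) ---
  scr <- summarize_screening(screen_results,
                             stats::setNames(unname(sample_to_individual),
                                             names(sample_to_individual)))
  milk_samples <- unique(milk$sample_id)
  pos_ind <- dairy_calls$individual_id[dairy_calls$positive]
  tallies <- list(
    n_samples = scr$n_samples,
    n_samples_passed = scr$n_samples_passed,
    n_individuals_total = scr$n_individuals_total,
    n_individuals_passed = scr$n_individuals_passed,
    pct_individuals_passed = scr$pct_individuals_passed,
    n_samples_with_milk = length(milk_samples),
    n_individuals_with_milk = length(unique(milk$individual_id)),
    n_samples_authenticated = length(unique(
      milk$sample_id[milk$individual_id %in% pos_ind])),
    n_individuals_authenticated = length(pos_ind),
    pct_blg_at_common = blg$pct_common)
  say("stage 4/4 summary: %d individuals authenticated",
      tallies$n_individuals_authenticated)

  structure(list(screening = screening, qc = qc, dairy_calls = dairy_calls,
                 assignments = assignments, blg_positions = blg$table,
                 tallies = tallies),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(paste0("<cohort_report> %d samples (%d individuals): %d samples",
                     " passed screening (%d%% of individuals); %d individuals",
                     " authenticated for dairy\n"),
              t$n_samples, t$n_individuals_total, t$n_samples_passed,
              t$pct_individuals_passed, t$n_individuals_authenticated))
  invisible(x)
}

#' Write a cohort report
#'
#' Emits a machine-readable JSON rendering (round-trips losslessly through
#' [read_report()]) and human-readable tab-separated tables.
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed).
#' @param formats Any of `"json"`, `"tsv"`.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, formats = c("json", "tsv")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    for (nm in c("screening", "qc", "dairy_calls", "assignments",
                 "blg_positions")) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(report[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
    }
    p <- file.path(dir, "tallies.tsv")
    utils::write.table(data.frame(key = names(report$tallies),
                                  value = unlist(report$tallies)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a JSON cohort report
#' @param path `report.json` written by [write_report()].
#' @return A `cohort_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  structure(x, class = "cohort_report")
}
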