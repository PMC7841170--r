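# Oral-signature screening: decide per calculus sample whether the proteome
# carries the oral signature expected of authentic dental calculus, gating
# all downstream dietary claims. The screen works on presence/absence of
# accession-level protein groups, not quantification.

#' Screening threshold configuration
#'
#' The published pass threshold lives in supplementary material, so it is a
#' named configuration value here: a sample passes when at least
#' `min_oral_groups` distinct oral-signature protein groups are supported by
#' at least `min_peptides_per_group` distinct peptide sequences each.
#'
#' @param min_oral_groups Minimum distinct oral-signature protein groups.
#' @param min_peptides_per_group Minimum distinct peptides per group.
#' @return Named list.
#' @export
screen_threshold <- function(min_oral_groups = 3L, min_peptides_per_group = 2L) {
  list(min_oral_groups = as.integer(min_oral_groups),
       min_peptides_per_group = as.integer(min_peptides_per_group))
}

#' Screen one sample against the oral signature reference
#'
#' Tallies distinct non-decoy protein groups per reference category
#' (oral microbe / host inflammatory / contaminant). Contaminant-only samples
#' never pass. Peptide- and spectrum-level tallies are reported alongside the
#' group tallies, but the pass rule uses protein groups.
#'
#' @param psms PSM data.frame for a single sample.
#' @param ossd Oral signature reference ([read_ossd()]).
#' @param threshold [screen_threshold()].
#' @return A `screen_result` list: `sample_id`, `n_oral_protein_groups`,
#'   `n_host_protein_groups`, `n_contaminant_groups`, `n_oral_peptides`,
#'   `n_oral_spectra`, `passed`, `threshold_used`.
#' @export
screen_sample <- function(psms, ossd, threshold = screen_threshold()) {
  if (nrow(psms) == 0L) {
    return(structure(list(sample_id = NA_character_,
                          n_oral_protein_groups = 0L, n_host_protein_groups = 0L,
                          n_contaminant_groups = 0L, n_oral_peptides = 0L,
                          n_oral_spectra = 0L, passed = FALSE,
                          threshold_used = threshold),
                     class = "screen_result"))
  }
  sample_id <- unique(psms$sample_id)
  if (length(sample_id) != 1L) stop("screen_sample expects PSMs from one sample")
  psms <- psms[!psms$is_decoy, , drop = FALSE]
  cat_of <- ossd$category[match(psms$protein_accession, ossd$accession)]

  group_tally <- function(category) {
    sub <- psms[!is.na(cat_of) & cat_of == category, , drop = FALSE]
    if (nrow(sub) == 0L) return(0L)
    per_group <- tapply(sub$peptide_sequence, sub$protein_accession,
                        function(x) length(unique(x)))
    sum(per_group >= threshold$min_peptides_per_group)
  }

  oral <- psms[!is.na(cat_of) & cat_of == "oral_microbe", , drop = FALSE]
  n_oral <- group_tally("oral_microbe")
  res <- list(sample_id = sample_id,
              n_oral_protein_groups = n_oral,
              n_host_protein_groups = group_tally("human_inflammatory"),
              n_contaminant_groups = group_tally("contaminant"),
              n_oral_peptides = length(unique(oral$peptide_sequence)),
              n_oral_spectra = nrow(oral),
              passed = n_oral >= threshold$min_oral_groups,
              threshold_used = threshold)
  structure(res, class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %s: oral=%d host=%d contaminant=%d -> %s\n",
              x$sample_id, x$n_oral_protein_groups, x$n_host_protein_groups,
              x$n_contaminant_groups, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Cohort-level screening summary
#'
#' An individual passes when at least one of its samples passes. The
#' percentage of individuals passing is rounded to the nearest integer.
#'
#' @param results List of `screen_result`.
#' @param sample_to_individual Named character vector mapping sample_id to
#'   individual_id; every screened sample must be mapped.
#' @param n_individuals_total Denominator for the percentage; defaults to the
#'   number of distinct mapped individuals.
#' @return List: `n_samples`, `n_samples_passed`, `n_individuals_passed`,
#'   `n_individuals_total`, `pct_individuals_passed`.
#' @export
summarize_screening <- function(results, sample_to_individual,
                                n_individuals_total = NULL) {
  sample_ids <- vapply(results, `[[`, "", "sample_id")
  unmapped <- setdiff(sample_ids[!is.na(sample_ids)], names(sample_to_individual))
  if (length(unmapped)) {
    stop("unmapped sample(s): ", paste(unmapped, collapse = ", "))
  }
  passed <- vapply(results, `[[`, logical(1), "passed")
  indiv <- sample_to_individual[sample_ids]
  if (is.null(n_individuals_total)) {
    n_individuals_total <- length(unique(sample_to_individual))
  }
  n_ind_pass <- length(unique(indiv[passed]))
  list(n_samples = length(results),
       n_samples_passed = sum(passed),
       n_individuals_passed = n_ind_pass,
       n_individuals_total = n_individuals_total,
       pct_individuals_passed = round(100 * n_ind_pass / n_individuals_total))
}
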