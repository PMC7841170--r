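# Dairy authentication: engine-specific FDR filtering, deamidation-aware
# matching of observed peptides to the milk reference panel, taxonomic
# labelling, and the per-individual multi-criterion dairy call.

#' Filter PSMs at engine-specific FDR thresholds
#'
#' Keeps exactly the non-decoy PSMs whose q-value is less than or equal to
#' their engine's threshold (inclusive). Idempotent.
#'
#' @param psms PSM data.frame.
#' @param engine_thresholds Named numeric vector of per-engine peptide-FDR
#'   thresholds in \[0, 1\]; defaults to 0.005 for `engine_A` and 0.01 for
#'   `engine_B` (the two engines report FDR differently, hence the asymmetry).
#' @return Filtered PSM data.frame.
#' @export
filter_psms_by_fdr <- function(psms,
                               engine_thresholds = c(engine_A = 0.005,
                                                     engine_B = 0.01)) {
  if (any(engine_thresholds < 0 | engine_thresholds > 1)) {
    stop("thresholds must lie in [0, 1]")
  }
  if (nrow(psms) == 0L) return(psms)
  unknown <- setdiff(unique(psms$engine), names(engine_thresholds))
  if (length(unknown)) {
    stop("PSM(s) with unknown engine: ", paste(unknown, collapse = ", "))
  }
  keep <- !psms$is_decoy & psms$q_value <= engine_thresholds[psms$engine]
  psms[keep, , drop = FALSE]
}

# deamidation collapses N to D and Q to E; applying the collapse to both the
# observed and the reference sequence makes matching blind to the ambiguity
deamidation_collapse <- function(sequence) chartr("NQ", "DE", sequence)

# apply deamidation modifications recorded for a DB-matched sequence, giving
# the as-measured residue string
apply_deamidation <- function(sequence, mods) {
  if (is.null(mods) || nrow(mods) == 0L) return(sequence)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  de <- mods$position[mods$mod == "deamidation"]
  aa[de] <- chartr("NQ", "DE", aa[de])
  paste(aa, collapse = "")
}

# digest every milk-class protein of the panel once; cached per call site
milk_peptide_index <- function(panel, max_missed = 2L) {
  milk <- Filter(function(p) p$protein_class %in% MILK_CLASSES, panel)
  idx <- lapply(milk, function(p) {
    d <- digest(p, max_missed)
    data.frame(taxon = p$taxon, protein_class = p$protein_class,
               accession = p$accession, sequence = d$sequence,
               start = d$start, stringsAsFactors = FALSE)
  })
  do.call(rbind, idx)
}

#' Match an observed milk peptide against the reference panel
#'
#' Requires full coverage and full homology: the observed sequence must equal
#' a tryptic (or missed-cleavage) peptide of a panel milk protein exactly.
#' Under `deamidation_aware = TRUE` an observed D additionally matches a
#' reference N and an observed E a reference Q at any position, reflecting
#' that deamidation makes those pairs indistinguishable in ancient samples.
#'
#' @param peptide_sequence Observed peptide (DB-matched residue string).
#' @param panel Reference panel (list of [reference_protein()]).
#' @param observed_mods Optional modification data.frame (`position`, `mod`);
#'   recorded deamidations are applied before matching.
#' @param deamidation_aware Collapse N/D and Q/E when matching (default TRUE).
#' @param max_missed Missed cleavages allowed in the panel digest (>= 2
#'   recommended, matching search settings).
#' @return data.frame of matches: `taxon`, `protein_class`, `accession`,
#'   `start` (mature position in the matched protein); zero rows when the
#'   peptide matches no panel protein.
#' @export
match_milk_peptide <- function(peptide_sequence, panel, observed_mods = NULL,
                               deamidation_aware = TRUE, max_missed = 2L) {
  if (!nzchar(peptide_sequence)) stop("empty peptide sequence")
  obs <- apply_deamidation(peptide_sequence, observed_mods)
  idx <- milk_peptide_index(panel, max_missed)
  if (is.null(idx) || nrow(idx) == 0L) return(idx)
  hit <- if (deamidation_aware) {
    deamidation_collapse(idx$sequence) == deamidation_collapse(obs)
  } else {
    idx$sequence == obs
  }
  res <- idx[hit, , drop = FALSE]
  res <- res[!duplicated(res[, c("taxon", "protein_class")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Taxonomic assignment of one milk peptide
#'
#' Wraps [match_milk_peptide()] with the composite label ("Bovinae/Ovis"
#' style, fixed panel order) and the lowest common ancestor, whose rank is
#' the reporting resolution (species up to infraorder/root).
#'
#' @inheritParams match_milk_peptide
#' @param tx Taxonomy data.frame.
#' @return List: `peptide_sequence`, `compatible_taxa`, `label`, `lca_name`,
#'   `resolution_rank`, `protein_classes`; `NULL` if the peptide matches no
#'   milk protein.
#' @export
taxon_assignment <- function(peptide_sequence, panel, tx, observed_mods = NULL,
                             deamidation_aware = TRUE, max_missed = 2L) {
  m <- match_milk_peptide(peptide_sequence, panel, observed_mods,
                          deamidation_aware, max_missed)
  if (is.null(m) || nrow(m) == 0L) return(NULL)
  panel_taxa <- unique(vapply(
    Filter(function(p) p$protein_class %in% MILK_CLASSES, panel), `[[`, "", "taxon"))
  taxa <- unique(m$taxon)
  node <- lca(taxa, tx)
  list(peptide_sequence = peptide_sequence,
       compatible_taxa = intersect(panel_taxa, taxa),
       label = label_taxa(taxa, tx, panel_taxa),
       lca_name = node$name,
       resolution_rank = node$rank,
       protein_classes = unique(m$protein_class))
}

# mature-chain start of a PSM's peptide on its reported parent (falling back
# to any milk protein of the panel); NA when unmappable
psm_start_positions <- function(psms, panel) {
  acc <- vapply(panel, `[[`, "", "accession")
  vapply(seq_len(nrow(psms)), function(i) {
    j <- match(psms$protein_accession[i], acc)
    candidates <- if (!is.na(j)) panel[j] else
      Filter(function(p) p$protein_class %in% MILK_CLASSES, panel)
    for (p in candidates) {
      hit <- suppressWarnings(map_peptide_position(psms$peptide_sequence[i], p))
      if (!is.null(hit)) return(hit$start)
    }
    NA_integer_
  }, integer(1))
}

#' Dairy-rule configuration
#'
#' @param min_psms Minimum milk PSMs (default 4).
#' @param min_unique_sequences Minimum unique peptide sequences (default 2);
#'   alternatively all PSMs may start at `common_position`.
#' @param common_position The recurrent peptide start that may substitute for
#'   sequence diversity (default 143, the most frequently recovered
#'   beta-lactoglobulin peptide position).
#' @param min_dual_engine Minimum PSMs whose (sample, sequence) pair was
#'   reported by both engines (default 2).
#' @param dual_unit `"psm"` counts qualifying PSM rows; `"sequence"` counts
#'   distinct dual-engine (sample, sequence) pairs instead.
#' @return Named list.
#' @export
dairy_rule <- function(min_psms = 4L, min_unique_sequences = 2L,
                       common_position = 143L, min_dual_engine = 2L,
                       dual_unit = c("psm", "sequence")) {
  list(min_psms = as.integer(min_psms),
       min_unique_sequences = as.integer(min_unique_sequences),
       common_position = as.integer(common_position),
       min_dual_engine = as.integer(min_dual_engine),
       dual_unit = match.arg(dual_unit))
}

#' Per-individual dairy authentication call
#'
#' An individual is called positive when, over the FDR-filtered milk PSMs of
#' its oral-signature-passing samples: (1) at least `min_psms` milk PSMs are
#' present; (2) at least `min_unique_sequences` unique sequences are present
#' OR every milk PSM starts at the recurrent position (default 143); and
#' (3) at least `min_dual_engine` PSMs have their (sample, sequence) pair
#' reported by both engines.
#'
#' @param individual_id Identifier.
#' @param milk_psms Milk-protein PSMs of this individual (post-FDR, from
#'   screened samples only). Zero rows give a negative call.
#' @param panel Reference panel (for start-position mapping).
#' @param rule [dairy_rule()].
#' @return A `dairy_call` list: tallies, `all_at_common`, `positive`, and the
#'   `evidence` data.frame of contributing PSMs with mapped starts.
#' @export
call_dairy <- function(individual_id, milk_psms, panel, rule = dairy_rule()) {
  if (nrow(milk_psms) == 0L) {
    return(structure(list(individual_id = individual_id, n_milk_psms = 0L,
                          n_unique_sequences = 0L, n_dual_engine = 0L,
                          all_at_common = FALSE, positive = FALSE,
                          rule = rule, evidence = milk_psms),
                     class = "dairy_call"))
  }
  starts <- psm_start_positions(milk_psms, panel)
  n_psms <- nrow(milk_psms)
  n_unique <- length(unique(milk_psms$peptide_sequence))
  all_at_common <- all(!is.na(starts)) && all(starts == rule$common_position)

  pair <- paste(milk_psms$sample_id, milk_psms$peptide_sequence, sep = "\r")
  engines_per_pair <- tapply(milk_psms$engine, pair, function(e) length(unique(e)))
  dual_pairs <- names(engines_per_pair)[engines_per_pair >= 2L]
  n_dual <- if (rule$dual_unit == "psm") sum(pair %in% dual_pairs)
            else length(dual_pairs)

  positive <- n_psms >= rule$min_psms &&
    (n_unique >= rule$min_unique_sequences || all_at_common) &&
    n_dual >= rule$min_dual_engine

  evidence <- milk_psms
  evidence$start <- starts
  structure(list(individual_id = individual_id, n_milk_psms = n_psms,
                 n_unique_sequences = n_unique, n_dual_engine = n_dual,
                 all_at_common = all_at_common, positive = positive,
                 rule = rule, evidence = evidence),
            class = "dairy_call")
}

#' @export
print.dairy_call <- function(x, ...) {
  cat(sprintf("<dairy_call> %s: %d PSMs, %d unique, %d dual-engine -> %s\n",
              x$individual_id, x$n_milk_psms, x$n_unique_sequences,
              x$n_dual_engine, if (x$positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' Beta-lactoglobulin start-position summary
#'
#' Counts BLG-class PSMs per mapped mature-chain start and reports the
#' fraction at the recurrent position as a rounded percentage.
#'
#' @param milk_psms Milk PSM data.frame.
#' @param panel Reference panel.
#' @param common_position Position of interest (default 143).
#' @param include_unmapped Include unmappable PSMs in the denominator
#'   (default TRUE; they appear in the table under start `NA`).
#' @return List: `table` (data.frame `start`, `n_psms`), `n_at_common`,
#'   `n_total`, `pct_common` (integer percent, truncated in the reporting
#'   style that prints 30/52 as 57\%; `NA` for empty input).
#' @export
blg_position_summary <- function(milk_psms, panel, common_position = 143L,
                                 include_unmapped = TRUE) {
  acc <- vapply(panel, `[[`, "", "accession")
  cls <- vapply(panel, `[[`, "", "protein_class")
  blg <- milk_psms[cls[match(milk_psms$protein_accession, acc)] %in% "BLG", ,
                   drop = FALSE]
  if (nrow(blg) == 0L) {
    return(list(table = data.frame(start = integer(), n_psms = integer()),
                n_at_common = 0L, n_total = 0L, pct_common = NA_real_))
  }
  starts <- psm_start_positions(blg, panel)
  tab <- as.data.frame(table(start = starts, useNA = "ifany"),
                       stringsAsFactors = FALSE)
  names(tab) <- c("start", "n_psms")
  tab$start <- suppressWarnings(as.integer(tab$start))
  n_common <- sum(starts == common_position, na.rm = TRUE)
  denom <- if (include_unmapped) length(starts) else sum(!is.na(starts))
  list(table = tab, n_at_common = n_common, n_total = denom,
       pct_common = if (denom > 0) trunc(100 * n_common / denom) else NA_real_)
}
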