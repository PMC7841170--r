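# Preservation / damage metrics: cleavage-specificity fractions and bulk
# deamidation rates with a site-sufficiency gate. Elevated non-specific
# cleavage and deamidation both indicate degradation of ancient proteins;
# when too few N/Q sites are observed the deamidation rate is withheld
# rather than reported on an unstable denominator.

#' Classify the cleavage specificity of one PSM
#'
#' A terminus is specific iff the residue preceding the boundary is K or R
#' not followed by P, or the boundary is a protein terminus. Both termini
#' specific gives `tryptic`, one `semi`, neither `nontryptic`.
#'
#' When the peptide occurs at several positions in the parent, the most
#' specific context is reported (search engines localise a peptide to its
#' best-supported site).
#'
#' @param peptide_sequence Peptide (DB-matched residue string).
#' @param protein Parent [reference_protein()].
#' @return One of `"tryptic"`, `"semi"`, `"nontryptic"`.
#' @export
classify_cleavage <- function(peptide_sequence, protein) {
  full <- protein$full_sequence
  hits <- gregexpr(peptide_sequence, full, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    stop(sprintf("peptide '%s' not found in %s", peptide_sequence,
                 protein$accession))
  }
  aa <- strsplit(full, "", fixed = TRUE)[[1]]
  rank <- c(nontryptic = 0L, semi = 1L, tryptic = 2L)
  best <- "nontryptic"
  for (start in as.integer(hits)) {
    end <- start + nchar(peptide_sequence) - 1L
    n_spec <- start == 1L ||
      (aa[start - 1L] %in% c("K", "R") && aa[start] != "P")
    c_spec <- end == length(aa) ||
      (aa[end] %in% c("K", "R") && aa[end + 1L] != "P")
    cls <- if (n_spec && c_spec) "tryptic"
           else if (n_spec || c_spec) "semi" else "nontryptic"
    if (rank[cls] > rank[best]) best <- cls
    if (best == "tryptic") break
  }
  best
}

#' Annotate PSMs with cleavage classes
#'
#' @param psms PSM data.frame.
#' @param panel Reference panel (parents looked up by accession; PSMs whose
#'   parent is absent or whose sequence is not locatable in the panel's
#'   version of the parent, e.g. decoys, get `NA`).
#' @return `psms` with a `cleavage_class` column.
#' @export
annotate_cleavage <- function(psms, panel) {
  acc <- vapply(panel, `[[`, "", "accession")
  psms$cleavage_class <- vapply(seq_len(nrow(psms)), function(i) {
    j <- match(psms$protein_accession[i], acc)
    if (is.na(j)) return(NA_character_)
    tryCatch(classify_cleavage(psms$peptide_sequence[i], panel[[j]]),
             error = function(e) NA_character_)
  }, character(1))
  psms
}

#' Fraction of non-specific cleavage
#'
#' (semi + nontryptic) / total over PSMs with a known cleavage class.
#'
#' @param psms PSM data.frame with `cleavage_class` filled
#'   ([annotate_cleavage()]).
#' @return Real in \[0, 1\]; `NA` for empty input.
#' @export
nonspecific_fraction <- function(psms) {
  cls <- psms$cleavage_class[!is.na(psms$cleavage_class)]
  if (length(cls) == 0L) return(NA_real_)
  sum(cls %in% c("semi", "nontryptic")) / length(cls)
}

#' Bulk deamidation rate with sufficiency gate
#'
#' Counts N and Q occurrences across the PSM peptide sequences and the
#' fraction of those carrying a recorded deamidation modification, separately
#' per residue and pooled. When fewer than `min_sites` sites are observed the
#' rate is withheld (`NA`) and `sufficient` is FALSE -- small denominators
#' make rates statistically incomparable.
#'
#' @param psms PSM data.frame (sequences plus `modifications` strings).
#' @param min_sites Minimum observed sites to report a rate (default 10,
#'   giving a binomial SE of at most ~0.16).
#' @return data.frame with rows `N`, `Q`, `pooled` and columns `n_sites`,
#'   `n_deamidated`, `rate`, `sufficient`.
#' @export
deamidation_rate <- function(psms, min_sites = 10L) {
  count_sites <- function(residue) {
    n_sites <- 0L; n_de <- 0L
    for (i in seq_len(nrow(psms))) {
      aa <- strsplit(psms$peptide_sequence[i], "", fixed = TRUE)[[1]]
      at <- which(aa == residue)
      n_sites <- n_sites + length(at)
      mods <- parse_modifications(psms$modifications[i])
      n_de <- n_de + sum(mods$position %in% at & mods$mod == "deamidation")
    }
    c(n_sites, n_de)
  }
  nN <- count_sites("N"); nQ <- count_sites("Q")
  rows <- rbind(N = nN, Q = nQ, pooled = nN + nQ)
  out <- data.frame(residue = rownames(rows), n_sites = rows[, 1],
                    n_deamidated = rows[, 2], stringsAsFactors = FALSE)
  out$sufficient <- out$n_sites >= as.integer(min_sites)
  out$rate <- ifelse(out$sufficient & out$n_sites > 0,
                     out$n_deamidated / out$n_sites, NA_real_)
  rownames(out) <- NULL
  out[, c("residue", "n_sites", "n_deamidated", "rate", "sufficient")]
}

#' Per-sample preservation report
#'
#' @param psms PSM data.frame for one sample.
#' @param panel Reference panel.
#' @param min_sites Deamidation sufficiency threshold.
#' @return List: `sample_id`, `n_psms`, `fraction_nonspecific`,
#'   `fraction_semi`, `fraction_nontryptic`, `n_deamidation_sites_NQ`,
#'   `fraction_deamidated` (NA when insufficient), `sufficient_sites`.
#' @export
qc_report <- function(psms, panel, min_sites = 10L) {
  sample_id <- if (nrow(psms)) unique(psms$sample_id)[1] else NA_character_
  psms <- annotate_cleavage(psms, panel)
  cls <- psms$cleavage_class[!is.na(psms$cleavage_class)]
  de <- deamidation_rate(psms, min_sites)
  pooled <- de[de$residue == "pooled", ]
  list(sample_id = sample_id,
       n_psms = nrow(psms),
       fraction_nonspecific = nonspecific_fraction(psms),
       fraction_semi = if (length(cls)) mean(cls == "semi") else NA_real_,
       fraction_nontryptic = if (length(cls)) mean(cls == "nontryptic") else NA_real_,
       n_deamidation_sites_NQ = pooled$n_sites,
       fraction_deamidated = pooled$rate,
       sufficient_sites = pooled$sufficient)
}
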