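# ZooMS peptide-mass-fingerprint matching: identify fragmentary bone by
# comparing picked MALDI peak lists against a library of taxon-diagnostic
# collagen marker masses. Peak picking is upstream; this module consumes
# two-column (m/z, intensity) peak lists.

#' Match reference markers to observed peaks
#'
#' Each marker is matched to the nearest peak within the mass tolerance;
#' each peak may satisfy at most one marker per taxon. Ties (two peaks
#' equidistant from a marker) are broken toward the lower-m/z peak. Markers
#' are processed in ascending reference mass.
#'
#' @param pl Peak list ([peaklist()] / [read_peaklist()]).
#' @param markerset data.frame `marker_name`, `mass` for one taxon.
#' @param tolerance Match window in Da (> 0; default 0.2, a typical
#'   linear-mode MALDI-TOF marker window).
#' @return data.frame `marker_name`, `reference_mass`, `matched_mz`,
#'   `mass_error` (peak - reference); unmatched markers are absent. Empty
#'   peak list gives an empty match table.
#' @export
match_markers <- function(pl, markerset, tolerance = 0.2) {
  if (tolerance <= 0) stop("tolerance must be positive")
  empty <- data.frame(marker_name = character(), reference_mass = numeric(),
                      matched_mz = numeric(), mass_error = numeric())
  peaks <- pl$peaks
  if (nrow(peaks) == 0L || nrow(markerset) == 0L) return(empty)
  used <- rep(FALSE, nrow(peaks))
  markerset <- markerset[order(markerset$mass), , drop = FALSE]
  out <- empty
  for (i in seq_len(nrow(markerset))) {
    err <- peaks$mz - markerset$mass[i]
    cand <- which(!used & abs(err) <= tolerance)
    if (length(cand) == 0L) next
    # nearest first; among equidistant candidates the lower m/z (= lower
    # index, peaks are sorted) wins
    best <- cand[order(abs(err[cand]), peaks$mz[cand])][1]
    used[best] <- TRUE
    out <- rbind(out, data.frame(marker_name = markerset$marker_name[i],
                                 reference_mass = markerset$mass[i],
                                 matched_mz = peaks$mz[best],
                                 mass_error = err[best]))
  }
  rownames(out) <- NULL
  out
}

#' Rank candidate taxa for a peak list
#'
#' Taxa are ordered by matched-marker count (descending), ties broken by the
#' summed absolute mass error (ascending). Taxa with fewer than `min_markers`
#' matches are reported but flagged as no identification; when no taxon
#' reaches the threshold the specimen is unidentified (the expected outcome
#' for blanks).
#'
#' @param pl Peak list.
#' @param library Marker library data.frame (`taxon`, `marker_name`, `mass`).
#' @param tolerance Match window in Da.
#' @param min_markers Minimum matched markers for an identification
#'   (default 2).
#' @return List: `ranking` (data.frame `taxon`, `n_matched`, `n_markers`,
#'   `sum_abs_error`, `identified`) and `identification` (top identified
#'   taxon or `NA`).
#' @export
rank_taxa <- function(pl, library, tolerance = 0.2, min_markers = 2L) {
  if (nrow(library) == 0L) stop("empty marker library")
  taxa <- unique(library$taxon)
  rows <- lapply(taxa, function(tx) {
    ms <- library[library$taxon == tx, c("marker_name", "mass")]
    m <- match_markers(pl, ms, tolerance)
    data.frame(taxon = tx, n_matched = nrow(m), n_markers = nrow(ms),
               sum_abs_error = sum(abs(m$mass_error)),
               stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$n_matched, ranking$sum_abs_error), ,
                     drop = FALSE]
  ranking$identified <- ranking$n_matched >= as.integer(min_markers)
  rownames(ranking) <- NULL
  list(ranking = ranking,
       identification = if (any(ranking$identified))
         ranking$taxon[ranking$identified][1] else NA_character_)
}
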