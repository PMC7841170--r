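# Reference panel: milk / oral / contaminant protein sequences with taxonomy,
# in-silico tryptic digestion, diagnostic-site discovery and peptide mapping.
#
# Coordinate convention: 1-based, inclusive, on the mature chain. The signal
# peptide (first `mature_offset` residues of `full_sequence`) is excluded, so
# mature position 1 is full_sequence[mature_offset + 1]. This is the numbering
# under which the classic beta-lactoglobulin variant positions (71, 148) and
# the common peptide start at 143 are meaningful.

PROTEIN_CLASSES <- c("BLG", "alpha_s1_casein", "alpha_s2_casein", "beta_casein",
                     "kappa_casein", "oral_signature", "human_host",
                     "contaminant", "decoy")
MILK_CLASSES <- c("BLG", "alpha_s1_casein", "alpha_s2_casein", "beta_casein",
                  "kappa_casein")

#' Construct a reference protein record
#'
#' @param accession Unique identifier.
#' @param protein_class One of `BLG`, `alpha_s1_casein`, `alpha_s2_casein`,
#'   `beta_casein`, `kappa_casein`, `oral_signature`, `human_host`,
#'   `contaminant`, `decoy`.
#' @param taxon Taxon name, resolvable in the accompanying taxonomy.
#' @param full_sequence Amino-acid sequence (canonical codes, gaps `-` allowed
#'   for pre-aligned panels).
#' @param mature_offset Number of signal-peptide residues to skip; mature
#'   position 1 corresponds to `full_sequence[mature_offset + 1]`.
#' @return A `reference_protein` object (named list).
#' @export
reference_protein <- function(accession, protein_class, taxon, full_sequence,
                              mature_offset = 0L) {
  protein_class <- match.arg(protein_class, PROTEIN_CLASSES)
  mature_offset <- as.integer(mature_offset)
  aa <- strsplit(full_sequence, "", fixed = TRUE)[[1]]
  bad <- which(!aa %in% c(names(residue_masses()), "-"))
  if (length(bad)) {
    stop(sprintf("%s: non-canonical residue '%s' at position %d",
                 accession, aa[bad[1]], bad[1]))
  }
  if (mature_offset < 0L || mature_offset >= nchar(full_sequence)) {
    stop(sprintf("%s: mature_offset %d out of range", accession, mature_offset))
  }
  structure(list(accession = accession, protein_class = protein_class,
                 taxon = taxon, full_sequence = full_sequence,
                 mature_offset = mature_offset),
            class = "reference_protein")
}

#' Mature-chain sequence of a reference protein
#' @param protein A [reference_protein()].
#' @return Character scalar (signal peptide stripped).
#' @export
mature_sequence <- function(protein) {
  substring(protein$full_sequence, protein$mature_offset + 1L)
}

#' @export
print.reference_protein <- function(x, ...) {
  cat(sprintf("<reference_protein> %s [%s] taxon=%s length=%d mature_offset=%d\n",
              x$accession, x$protein_class, x$taxon,
              nchar(x$full_sequence), x$mature_offset))
  invisible(x)
}

# cleavage boundaries of a sequence under the classical trypsin rule:
# cut C-terminal to K/R unless the next residue is P; termini always count.
trypsin_boundaries <- function(aa) {
  n <- length(aa)
  internal <- which(aa[-n] %in% c("K", "R") & aa[-1] != "P")
  c(0L, internal, n)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, with up to
#' `max_missed` internal uncut sites. Protein termini count as valid cleavage
#' boundaries. When a [reference_protein()] is supplied, the mature chain is
#' digested and `start`/`end` are mature-chain coordinates.
#'
#' @param protein A [reference_protein()] or a plain sequence string.
#' @param max_missed Maximum internal missed cleavages (>= 0).
#' @return data.frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, `n_term_context`, `c_term_context` (flanking residue
#'   or `"-"` at a protein terminus), sorted by (start, length).
#' @examples
#' digest("MKRTPEVDKR", 0)$sequence  # MK, R, TPEVDK, R
#' digest("AKPGR", 0)$sequence       # AKPGR (K before P is not cleaved)
#' @export
digest <- function(protein, max_missed = 2L) {
  seqstr <- if (inherits(protein, "reference_protein")) {
    mature_sequence(protein)
  } else protein
  if (!nzchar(seqstr)) stop("empty sequence")
  max_missed <- as.integer(max_missed)
  if (max_missed < 0L) stop("max_missed must be >= 0")
  aa <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  bad <- which(!aa %in% names(residue_masses()))
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  b <- trypsin_boundaries(aa)
  nb <- length(b)
  out <- vector("list", 0L)
  k <- 0L
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + max_missed)) {
      start <- b[i] + 1L
      end <- b[j]
      k <- k + 1L
      out[[k]] <- data.frame(
        sequence = paste(aa[start:end], collapse = ""),
        start = start, end = end,
        missed_cleavages = j - i - 1L,
        n_term_context = if (start == 1L) "-" else aa[start - 1L],
        c_term_context = if (end == length(aa)) "-" else aa[end + 1L],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end - res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Discover taxon-diagnostic alignment columns
#'
#' Given pre-aligned orthologs of one protein class (equal length, gap `-`
#' allowed), returns every column at which at least two taxa carry different
#' residues, with the residue-to-taxa mapping. Fully conserved columns are
#' absent. Column numbers are mature-chain positions (the alignment is over
#' mature chains).
#'
#' @param aligned_panel List of [reference_protein()] sharing a protein class.
#' @return List of `diagnostic_site` records: `protein_class`,
#'   `mature_position`, `residue_to_taxa` (named list residue -> character
#'   vector of taxa).
#' @export
find_diagnostic_sites <- function(aligned_panel) {
  if (length(aligned_panel) < 2L) stop("need >= 2 aligned sequences")
  cls <- unique(vapply(aligned_panel, `[[`, "", "protein_class"))
  if (length(cls) != 1L) stop("panel mixes protein classes")
  seqs <- vapply(aligned_panel, mature_sequence, "")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length (alignment error)")
  }
  taxa <- vapply(aligned_panel, `[[`, "", "taxon")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  sites <- list()
  for (col in seq_len(ncol(mat))) {
    residues <- mat[, col]
    if (length(unique(residues)) < 2L) next
    mapping <- split(taxa, residues)
    sites[[length(sites) + 1L]] <- structure(
      list(protein_class = cls, mature_position = col,
           residue_to_taxa = mapping),
      class = "diagnostic_site")
  }
  sites
}

#' Locate a peptide on a reference protein
#'
#' Exact substring search over the full sequence, reported in mature-chain
#' coordinates. Occurrences that begin inside the signal peptide get a
#' non-positive start and `in_signal = TRUE`.
#'
#' @param peptide_sequence Peptide to locate.
#' @param protein A [reference_protein()].
#' @return `NULL` when absent; otherwise a list with `start` (1-based mature
#'   position of the first occurrence), `in_signal`, and `n_occurrences`. A
#'   warning is raised when the peptide occurs more than once.
#' @export
map_peptide_position <- function(peptide_sequence, protein) {
  if (!nzchar(peptide_sequence)) stop("empty peptide sequence")
  hits <- gregexpr(peptide_sequence, protein$full_sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NULL)
  if (length(hits) > 1L) {
    warning(sprintf("peptide '%s' occurs %d times in %s; first occurrence reported",
                    peptide_sequence, length(hits), protein$accession))
  }
  start_full <- as.integer(hits[1])
  start_mature <- start_full - protein$mature_offset
  list(start = start_mature, in_signal = start_mature < 1L,
       n_occurrences = length(hits))
}
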