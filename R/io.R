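# Readers and writers for the plain-text formats the pipeline exchanges:
# panel FASTA with key=value header fields, engine PSM tables, the oral
# signature reference, peak lists and isotope tables.

#' Write a reference panel to FASTA
#'
#' Headers carry `class=`, `taxon=` and `mature_offset=` key=value fields
#' after the accession; sequences are wrapped at 80 columns.
#'
#' @param panel List of [reference_protein()].
#' @param path Output file.
#' @export
write_panel_fasta <- function(panel, path) {
  seqs <- Biostrings::AAStringSet(vapply(panel, `[[`, "", "full_sequence"))
  names(seqs) <- vapply(panel, function(p) {
    sprintf("%s class=%s taxon=%s mature_offset=%d",
            p$accession, p$protein_class, p$taxon, p$mature_offset)
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a reference panel from FASTA
#'
#' @param path FASTA file written by [write_panel_fasta()] (accession is the
#'   first header token; `class`, `taxon`, `mature_offset` parsed from
#'   key=value fields, defaulting to `contaminant`/`unknown`/0).
#' @return List of [reference_protein()].
#' @export
read_panel_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    tokens <- strsplit(header, "\\s+")[[1]]
    kv <- tokens[grepl("=", tokens, fixed = TRUE)]
    fields <- stats::setNames(
      sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    reference_protein(
      accession = tokens[1],
      protein_class = if ("class" %in% names(fields)) fields[["class"]] else "contaminant",
      taxon = if ("taxon" %in% names(fields)) fields[["taxon"]] else "unknown",
      full_sequence = as.character(seqs[[i]]),
      mature_offset = if ("mature_offset" %in% names(fields))
        as.integer(fields[["mature_offset"]]) else 0L)
  })
}

PSM_COLUMNS <- c("sample_id", "individual_id", "spectrum_id", "peptide_sequence",
                 "modifications", "protein_accession", "engine", "score",
                 "q_value", "is_decoy")

#' Read a PSM table
#'
#' Tab-separated engine export with the documented header (both engine
#' dialects are normalised to the same columns by the writer). Validates
#' q-values and the one-PSM-per-spectrum-per-engine invariant.
#'
#' @param path File path.
#' @return data.frame with the columns in `PSM_COLUMNS`.
#' @export
read_psm_table <- function(path) {
  psms <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            na.strings = c("NA"))
  missing <- setdiff(PSM_COLUMNS, names(psms))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
  }
  psms$modifications[is.na(psms$modifications)] <- ""
  validate_psms(psms)
}

#' Validate a PSM data frame
#' @param psms data.frame with the standard PSM columns.
#' @return The validated data.frame.
#' @export
validate_psms <- function(psms) {
  if (any(psms$q_value < 0 | psms$q_value > 1)) stop("q_value outside [0, 1]")
  # spectrum identifiers are scoped to a sample's acquisition run
  key <- paste(psms$sample_id, psms$engine, psms$spectrum_id)
  if (anyDuplicated(key)) {
    stop("a spectrum maps to more than one PSM within an engine")
  }
  psms$is_decoy <- as.logical(psms$is_decoy)
  psms
}

#' Write a PSM table
#' @param psms PSM data.frame.
#' @param path Output file.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms[, PSM_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# modifications are serialised as "pos:mod;pos:mod" in the PSM table
parse_modifications <- function(modstring) {
  if (is.na(modstring) || !nzchar(modstring)) {
    return(data.frame(position = integer(), mod = character()))
  }
  parts <- strsplit(strsplit(modstring, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[[`, "", 1L)),
             mod = vapply(parts, `[[`, "", 2L), stringsAsFactors = FALSE)
}

format_modifications <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  paste(sprintf("%d:%s", mods$position, mods$mod), collapse = ";")
}

#' Read the oral signature reference
#'
#' Two-column tab-separated table: `accession`, `category` (one of
#' `oral_microbe`, `human_inflammatory`, `contaminant`).
#'
#' @param path File path.
#' @return data.frame `accession`, `category`.
#' @export
read_ossd <- function(path) {
  ossd <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "category") %in% names(ossd)))
  ok <- c("oral_microbe", "human_inflammatory", "contaminant")
  if (!all(ossd$category %in% ok)) {
    stop("unknown OSSD category: ", paste(setdiff(ossd$category, ok), collapse = ", "))
  }
  if (anyDuplicated(ossd$accession)) stop("OSSD categories must be disjoint per accession")
  ossd
}

#' Write the oral signature reference
#' @param ossd data.frame `accession`, `category`.
#' @param path Output file.
#' @export
write_ossd <- function(ossd, path) {
  utils::write.table(ossd, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MALDI peak list
#'
#' Two-column whitespace/tab-separated text (m/z, intensity), one file per
#' specimen; comment lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param specimen_id Identifier; defaults to the file name without extension.
#' @return List with `specimen_id` and `peaks` (data.frame `mz`, `intensity`,
#'   sorted ascending by m/z).
#' @export
read_peaklist <- function(path, specimen_id = NULL) {
  if (is.null(specimen_id)) {
    specimen_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("mz", "intensity"))
  peaklist(specimen_id, tab$mz, tab$intensity)
}

#' Construct a peak list
#' @param specimen_id Identifier.
#' @param mz Peak m/z values (> 0).
#' @param intensity Intensities (arbitrary units).
#' @return Peak-list object (`specimen_id`, `peaks` sorted by m/z).
#' @export
peaklist <- function(specimen_id, mz, intensity) {
  if (any(mz <= 0)) stop("m/z must be positive")
  o <- order(mz)
  structure(list(specimen_id = specimen_id,
                 peaks = data.frame(mz = mz[o], intensity = intensity[o])),
            class = "peaklist")
}

#' Write a peak list
#' @param pl Peak list ([peaklist()]).
#' @param path Output file.
#' @export
write_peaklist <- function(pl, path) {
  utils::write.table(pl$peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ZooMS marker library
#'
#' Tab-separated table: `taxon`, `marker_name`, `mass` (Da). Marker names
#' must be unique within a taxon.
#'
#' @param path File path.
#' @return data.frame `taxon`, `marker_name`, `mass`.
#' @export
read_marker_library <- function(path) {
  lib <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "marker_name", "mass") %in% names(lib)))
  if (anyDuplicated(paste(lib$taxon, lib$marker_name))) {
    stop("marker names must be unique within a taxon")
  }
  lib
}

#' Read an isotope measurement table
#'
#' Tab-separated with columns `specimen_id`, `taxon`, `site`, `material`
#' (`collagen` or `enamel`), `system` (`d13C`, `d15N`, `d18O`), `raw_delta`
#' (permil) and optionally `source` (e.g. `this_study` vs `published`).
#'
#' @param path File path.
#' @return data.frame of measurements.
#' @export
read_isotope_table <- function(path) {
  m <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  needed <- c("specimen_id", "taxon", "site", "material", "system", "raw_delta")
  missing <- setdiff(needed, names(m))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  if (!all(m$system %in% c("d13C", "d15N", "d18O"))) stop("unknown isotope system")
  if (!all(m$material %in% c("collagen", "enamel"))) stop("unknown material")
  if (!"source" %in% names(m)) m$source <- "this_study"
  m
}

#' Read a standards table for isotope calibration
#'
#' Tab-separated: `name`, `system`, `certified`, `measured` (permil).
#'
#' @param path File path.
#' @return data.frame of standards.
#' @export
read_standards_table <- function(path) {
  s <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "system", "certified", "measured") %in% names(s)))
  s
}
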