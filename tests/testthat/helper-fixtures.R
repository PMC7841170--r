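# Shared fixtures: an independent brute-force digestion oracle, a cached
# simulated panel bundle, and compact PSM row constructors.

# Brute-force digestion oracle: enumerate every substring whose boundaries
# satisfy the cleavage rule and whose internal cleavage-site count is within
# the missed-cleavage budget. Independent of digest()'s boundary-walk.
oracle_digest <- function(seq, max_missed) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(aa)
  is_boundary <- function(i) {
    i == 0L || i == n || (aa[i] %in% c("K", "R") && aa[i + 1L] != "P")
  }
  out <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (!is_boundary(s - 1L) || !is_boundary(e)) next
      internal <- 0L
      if (e > s) {
        internal <- sum(vapply(s:(e - 1L), function(i) {
          aa[i] %in% c("K", "R") && aa[i + 1L] != "P"
        }, logical(1)))
      }
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(aa[s:e], collapse = ""), start = s, end = e,
        missed_cleavages = internal, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end - df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_protein_sequence <- function(len) {
  paste(sample(names(paleodairy::residue_masses()), len, replace = TRUE),
        collapse = "")
}

# one simulated bundle shared across the suite (deterministic)
test_bundle <- simulate_reference_panel(seed = 42)

blg_of <- function(taxon, bundle = test_bundle) {
  Filter(function(p) p$protein_class == "BLG" && p$taxon == taxon,
         bundle$panel)[[1]]
}

# compact PSM row constructor with sensible defaults
make_psm <- function(sample_id = "s1", individual_id = "i1",
                     spectrum_id = NULL, peptide_sequence = "TPEVDK",
                     modifications = "", protein_accession = "BLG_CAPRA",
                     engine = "engine_A", score = 400, q_value = 0.001,
                     is_decoy = FALSE) {
  if (is.null(spectrum_id)) {
    spectrum_id <- sprintf("sp%09.0f", stats::runif(1, 0, 1e9))
  }
  data.frame(sample_id = sample_id, individual_id = individual_id,
             spectrum_id = spectrum_id, peptide_sequence = peptide_sequence,
             modifications = modifications,
             protein_accession = protein_accession, engine = engine,
             score = score, q_value = q_value, is_decoy = is_decoy,
             stringsAsFactors = FALSE)
}

# n PSMs with per-row overrides given as vectors
make_psms <- function(n, ...) {
  args <- list(...)
  do.call(rbind, lapply(seq_len(n), function(i) {
    row_args <- lapply(args, function(v) v[[(i - 1L) %% length(v) + 1L]])
    row_args$spectrum_id <- sprintf("sp%03d_%s_%s", i,
                                    row_args$sample_id %||% "s1",
                                    row_args$engine %||% "engine_A")
    do.call(make_psm, row_args)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
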