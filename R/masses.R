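# Monoisotopic mass bookkeeping for peptides and their modifications.

#' Monoisotopic residue masses
#'
#' Standard monoisotopic masses (Da) of the 20 canonical amino-acid residues
#' (i.e. the in-chain residue mass, water excluded).
#'
#' @return Named numeric vector, one entry per one-letter code.
#' @export
residue_masses <- function() {
  c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
    H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
}

# monoisotopic mass of H2O
MASS_WATER <- 18.010565

#' Default modification table
#'
#' Unimod monoisotopic deltas for the variable and fixed modifications the
#' pipeline understands. `residues` lists the compatible one-letter codes;
#' `"n-term"` marks modifications restricted to position 1. The table is an
#' editable data frame so non-default chemistry can be supplied to
#' [peptide_mass()].
#'
#' @return data.frame with columns `mod`, `delta` (Da), `residues`
#'   (comma-separated compatible residues or `n-term`).
#' @export
default_modifications <- function() {
  data.frame(
    mod = c("carbamidomethyl", "deamidation", "oxidation",
            "phosphorylation", "pyro-glu-Q", "pyro-glu-E", "acetyl-nterm"),
    delta = c(57.021464, 0.984016, 15.994915,
              79.966331, -17.026549, -18.010565, 42.010565),
    residues = c("C", "N,Q", "M,K", "S,T", "Q", "E", "n-term"),
    stringsAsFactors = FALSE
  )
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus water plus modification deltas. Additive and
#' order-independent in the modification list.
#'
#' @param sequence Peptide sequence (canonical one-letter codes).
#' @param modifications `NULL`, or a data.frame/list with elements `position`
#'   (1-based) and `mod` (name in the modification table).
#' @param mod_table Modification table, see [default_modifications()].
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")                        # 75.03203
#' peptide_mass("TPEVDK", list(position = 5, mod = "oxidation")) # errors: D
#' @export
peptide_mass <- function(sequence, modifications = NULL,
                         mod_table = default_modifications()) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(aa) == 0L) stop("empty peptide sequence")
  rm <- residue_masses()
  bad <- which(!aa %in% names(rm))
  if (length(bad)) {
    stop(sprintf("non-canonical residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  mass <- sum(rm[aa]) + MASS_WATER
  if (is.null(modifications)) return(unname(mass))
  mods <- as.data.frame(modifications)
  if (nrow(mods) == 0L) return(unname(mass))
  for (i in seq_len(nrow(mods))) {
    pos <- as.integer(mods$position[i])
    name <- as.character(mods$mod[i])
    row <- mod_table[mod_table$mod == name, , drop = FALSE]
    if (nrow(row) == 0L) stop(sprintf("unknown modification '%s'", name))
    if (pos < 1L || pos > length(aa)) {
      stop(sprintf("modification position %d outside peptide", pos))
    }
    allowed <- strsplit(row$residues, ",", fixed = TRUE)[[1]]
    if (identical(allowed, "n-term")) {
      if (pos != 1L) {
        stop(sprintf("'%s' is N-terminal only (got position %d)", name, pos))
      }
    } else if (!aa[pos] %in% allowed) {
      stop(sprintf("modification '%s' incompatible with residue '%s' at %d",
                   name, aa[pos], pos))
    }
    mass <- mass + row$delta
  }
  unname(mass)
}
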