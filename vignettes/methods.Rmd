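---
title: "Methods: authenticating milk proteins in ancient dental calculus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: authenticating milk proteins in ancient dental calculus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodairy)
```

## The problem

Proteins trapped in mineralising dental plaque survive for millennia, and a
handful of them — the whey protein β-lactoglobulin (BLG) above all — are
diagnostic of milk consumption. But ancient calculus from hot climates and
handled museum collections is a hostile substrate: proteomes are small,
damaged, and easily contaminated. A dietary claim therefore needs three
independent lines of defence, which this package implements as a strictly
ordered pipeline: (i) evidence that the sample is an authentic oral
proteome at all, (ii) statistical control of peptide-spectrum-match (PSM)
error via per-engine FDR thresholds and dual-engine concordance, and
(iii) conservative taxonomic assignment that accounts for the chemistry of
ancient protein damage.

## Coordinates and the reference panel

All peptide positions are 1-based, inclusive, on the **mature chain**: the
signal peptide (the first `mature_offset` residues of the database entry) is
excluded. This is the only numbering under which the classic BLG landmarks
are meaningful — the species-variant sites at positions 71 and 148 and the
recurrent tryptic peptide starting at 143. Whether historical reports used
mature or precursor numbering is not always stated; mature-chain numbering
is our recorded convention (`dairy_rule(common_position = 143)`), a
configuration constant rather than a claim about any one publication.

The panel covers BLG plus the four caseins for *Bos*, *Bubalus*, *Ovis*,
*Capra* and *Camelus* — camel included so that "no evidence of camel milk"
is a checkable outcome, not an omission. Panel orthologs are supplied
pre-aligned (equal length); multiple-sequence alignment is deliberately out
of scope. Decoy entries are carried but can never contribute oral or
dietary evidence.

## Digestion and masses

Trypsin cleaves C-terminal to K or R except before P, with protein termini
as valid boundaries; `digest()` enumerates all peptides with up to
`max_missed` internal uncut sites (searches are run at 2). The test suite
holds `digest()` to exact agreement with an independent brute-force
enumeration on random sequences. Monoisotopic masses are standard residue
tables plus water; modification deltas (carbamidomethyl, deamidation
+0.984016 Da, oxidation, phosphorylation, pyro-Glu, N-terminal acetyl) are
Unimod values kept in an editable table (`default_modifications()`) rather
than hard-coded.

## Oral-signature screening

The screen tallies distinct non-decoy protein groups per reference category
(oral microbe / host inflammatory / contaminant) at accession level — no
parsimony clustering, since the gate needs presence/absence rather than
quantification. The published numeric pass threshold lives in supplementary
material we do not ship, so the threshold is a named configuration value:
**≥ 3 oral-signature groups with ≥ 2 distinct peptides each**, recorded in
every `ScreenResult` so a published value can be swapped in. Whether the
original rule counted proteins, peptides or spectra is also not stated in
main text: all three tallies are computed and exposed; the default rule uses
protein groups. Screening is a hard gate — dairy calls are computed only
for passing samples — but failing samples are retained in QC output.

## The dairy call

Per individual, pooling all screened samples (a per-sample mode exists
behind `dual_unit`/caller choice, since the original per-individual vs
per-sample pooling is not stated):

* ≥ 4 milk PSMs (caseins count together with BLG; the protein class is
  retained per PSM so BLG-only analyses remain possible);
* ≥ 2 unique peptide sequences, **or** every milk PSM starts at the
  recurrent position 143 — the published minimal case "all four PSMs
  starting at position 143" generalised to "all PSMs" when there are more;
* ≥ 2 PSMs whose (sample, sequence) pair appears in both engines' filtered
  outputs. We read "at least two of which were identified in both engines"
  at the PSM level because the sentence attaches to PSMs; counting distinct
  dual sequences instead is available as `dairy_rule(dual_unit =
  "sequence")`. Note the two readings can genuinely disagree: one dual
  sequence contributes two qualifying PSM rows.

FDR thresholds are inclusive (q = 0.01 passes engine B's 1% cut) and
engine-specific (0.5% vs 1%) because the engines report FDR differently.
The monotone-evidence property — deleting PSMs can never turn a negative
call positive — is verified by randomised deletion trials.

## Deamidation-aware taxonomy

Asparagine deamidates to aspartate and glutamine to glutamate in ancient
proteins, so an observed D is indistinguishable from an ancestral
deamidated N. Matching therefore collapses N→D and Q→E on **both** the
observed and reference sequences; Q→E is included symmetrically because
both search configurations list deamidation of both residues as variable
modifications. Deamidation-aware matching is provably a superset of exact
matching. Matches require full identity and full coverage against the
digested panel — no partial or homology matching (no remote database
search; the panel is local and explicit).

Compatible-taxa sets are reported two ways: the lowest common ancestor
(whose rank, species up to infraorder, is the resolution statement) and a
composite label that collapses fully covered clades, joined "/" in fixed
panel order — `{Bos, Bubalus, Ovis}` prints as "Bovinae/Ovis", finer than
its strict LCA (Bovidae).

## Preservation QC

A peptide terminus is *specific* iff the boundary follows K/R-not-before-P
or is a protein terminus; both specific → tryptic, one → semi, none →
non-tryptic, and the headline metric is the pooled semi+non-tryptic
fraction (published ranges pool the two; we also report them separately).
When a peptide occurs at several positions in its parent the most specific
context is used, which is also what makes "every digest product is tryptic"
an exact invariant. Bulk deamidation is a pooled rate over observed N/Q
sites, per residue and combined, and is **withheld** below `min_sites = 10`
observed sites (binomial SE would exceed ~0.16) — mirroring the practice of
declining comparison on too-few sites rather than modelling site-resolved
deamidation kinetics, which is out of scope.

## Isotopes

δ = (R_sample/R_standard − 1) × 1000, in ‰. Calibration is an
ordinary-least-squares line from measured to certified standard values per
isotope system (≥ 2 standards, non-zero spread) — the standard two-/
multi-point normalisation; the functional form is our choice since none is
published, and the identity and exact-two-point properties are tested.
Group summaries report means to 1 decimal ‰ (conventional precision), and
the trophic offset human − fauna δ¹⁵N is flagged against a configurable
3–5‰ window (the conventional collagen spacing; the window is
configuration, not a claim). Measurements carry a `source` tag so cohorts
can be summarised with or without previously published values. Collagen
quality indicators (C:N, yield) are not modelled.

## ZooMS

Markers match the nearest peak within ±0.2 Da (a typical linear-mode
MALDI-TOF window; no tolerance is published, so it is a default, not a
constant), one peak per marker per taxon, ties broken toward the lower m/z.
Taxa are ranked by matched-marker count, then summed |mass error|; below
`min_markers = 2` the result is "no identification" — the expected outcome
for blanks. Match counts are monotone in tolerance. Peak picking and
spectral processing are upstream; the shipped marker library is a named
synthetic placeholder, with real masses supplied as user data.

## The synthetic world

The generator's defaults are the stated test world, fixed once:

* 40 individuals, 1 sample each, 8 consumers with 6 first-engine milk PSMs,
  `dual_engine_prob = 1` — evidence guaranteed above rule thresholds;
* deamidation probability 0.30 per N/Q site, non-specific cleavage 0.10 per
  PSM (inside the degraded-calculus ranges), decoy rate 0.10;
* decoy q-values drawn from [0.05, 0.5], bounded away from both FDR
  thresholds, so zero false positives is a guarantee of the rule, not luck;
  `decoy_leak = TRUE` is an adversarial mode for robustness probing;
* toy BLG orthologs share a seeded backbone and differ *only* at planted
  columns 71 (D/D/N/K/S across Bos/Bubalus/Ovis/Capra/Camelus) and 148, so
  diagnostic-site discovery must recover exactly {71, 148}; the single
  D/N/K column reproduces both the deamidation ambiguity (Bovinae/Ovis)
  and the goat-specific extra cleavage site (TPEVDK…) in one structure;
* sequences are synthetic, not database entries; loaders accept real FASTA.

What a green test does establish: the decision logic, its thresholds, its
monotonicity and its determinism. What it does not: real spectra are not
simulated (no fragment ions), engine score distributions are stylised, and
real calculus proteomes are vastly more diverse — cohort-level counts from
any particular study are only reproducible from that study's deposited
tables, which is why acceptance here is property-based.

## Numerical and reporting choices

* Integer percentages: cohort individual-level percentages round to
  nearest; the BLG recurrent-position percentage truncates, reproducing the
  convention that prints 30/52 as 57%.
* `match_markers` tie-break (lower m/z) and `lca` leaf-to-root intersection
  are deterministic; all generators are byte-reproducible under a seed.
* Degenerate inputs: empty PSM sets give negative calls with zero tallies;
  empty peak lists give empty match sets; deamidation rates on < 10 sites
  are NA by design; a singleton taxon set is its own LCA.

## Known limitations

No spectrum rescoring, no parsimony protein inference, no thermal-age or
site-wise deamidation modelling, no radiocarbon work, no MSA construction,
and no claim that the synthetic cohort calibrates real-world sensitivity —
it verifies logic, not biology.
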