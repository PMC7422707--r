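---
title: "Mapping FAM20C phosphosites on MEPE: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping FAM20C phosphosites on MEPE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepephos)
```

## The problem

Matrix extracellular phosphoglycoprotein (MEPE) is a 508-residue secreted
SIBLING protein of bone and teeth whose C-terminal acidic serine- and
aspartate-rich motif (ASARM) regulates mineralization in a
phosphorylation-dependent way. The Golgi kinase FAM20C phosphorylates
secreted proteins, canonically at Ser-x-Glu (and at Ser-x-pSer once a
downstream serine is phosphorylated). Establishing which MEPE residues
FAM20C can phosphorylate requires stitching together several desk-scale
computations around the mass-spectrometry evidence:

1. modelling the recombinant constructs actually expressed (mature chain +
   linker-myc-linker-His6 tags, with K509A/K515A substitutions that remove
   two tryptic sites so the ASARM survives digestion as one peptide);
2. in-silico tryptic digestion with missed cleavages;
3. theoretical peptide masses and phospho-ladder arithmetic for intact-mass
   MALDI spectra;
4. assignment of observed peaks to phosphate counts, with an alkaline
   phosphatase (ALP) control;
5. motif classification of every serine;
6. collation of peptide-level LC-MS/MS evidence into a residue-level site
   map with ambiguity handling, spectral-count-based major-site calls and
   headline totals; and
7. conservation of each phosphosite across an aligned mammalian ortholog
   family.

`mepephos` implements each step as a data-frame-first function, and
`reproduce()` chains them end to end over packaged fixtures.

## Coordinate conventions

All analysis positions use **mature-chain numbering** (1--508), 1-based and
inclusive, matching how phosphosites and peptide spans are reported.
Chains carry a `numbering_offset` so that fragments (e.g. the ASARM span
489--508) keep their printed coordinates. Tag residues are outside the
mature chain; the assembled construct's coordinate table gives each residue
both a segment-local index (`myc` position 3, say) and a continuous printed
position that extends past 508 — the latter is how the K509A and K515A
substitutions are addressed. Tag phosphosites are tracked but excluded from
mature-chain totals.

## Digestion

Trypsin specificity is modelled as cleavage C-terminal to Lys/Arg, blocked
by a following Pro. `trypsin_digest()` enumerates every peptide with 0 to
`max_missed` internal missed cleavages (default 2, the modelled search
setting). Ragged N-terminal variants (peptides starting at 36 vs 37) arise
naturally from missed cleavages; semi-tryptic products are not modelled
because the search space being reproduced is fully tryptic. Three
invariants pin the implementation down: the 0-missed products tile the
chain; every m-missed peptide is the concatenation of m+1 adjacent 0-missed
products; and the full enumeration equals a brute-force oracle on random
sequences.

## Masses

Residue monomer masses (monoisotopic and average), one water per peptide
and one proton for MH+ are summed directly. The phosphate increment is
79.96633 Da (monoisotopic) / 79.9799 Da (average). The package defaults to
**average MH+** for MALDI comparisons: a ~4.8 kDa peptide in linear-mode
MALDI is observed as its average protonated mass, and the computed average
MH+ of the mutant C-terminal 45-mer is 4838.8 Da, matching the reported
intact mass, whereas the monoisotopic value is ~2.7 Da lighter. Tests
verify the mass path against an independent atomic-composition oracle
(element counts times atomic masses).

## Ladder assignment

`assign_phospho_ladder()` matches each observed peak to the nearest rung of
`base + k * 79.98`. The default tolerance is **0.1% of m/z** (~5 Da at
5 kDa), chosen for externally calibrated linear-mode spectra whose
observed-vs-theoretical offsets here are 1.6--3.3 Da; tightening the
tolerance can only lose assignments (a tested monotonicity). A peak
equidistant between rungs takes the lower count — conservative phosphate
counting. The ALP control (`dephospho_control()`) passes only when the
untreated spectrum has at least one k > 0 peak and the treated spectrum's
assigned peaks are all k = 0; we additionally require the treated spectrum
to actually show the unmodified species rather than passing vacuously on an
empty list. Intensities are carried but unused by default (`intensity_floor`
is opt-in) because fixture traces do not print intensity values.

## Motif rules

* `scan_canonical()`: Ser at n, Glu at n+2.
* `scan_extended()`: smallest fixed point of "add Ser at n when n+2 is in
  the set", seeded with the canonical matches plus any supplied
  phosphosites. The iteration is monotone and bounded, hence terminates;
  it is also idempotent at the fixed point and monotone in its seed (both
  property-tested).
* `scan_sxd()`: Ser at n, Asp at n+2 — a secondary acceptor motif known
  from osteopontin.
* `scan_acidic_context()`: Ser with at least one Asp/Glu at n+5..n+7. This
  generalizes the SxQxxDEE-type motif, whose acidic tail is the critical
  determinant; the known examples (S56, S436) do not carry the literal
  motif, so the lenient window rule is the default and `require_q` /
  `require_all_acidic` raise strictness. Positions beyond the terminus
  simply cannot match; no padding is applied.

Threonine scanning is opt-in (`include_thr`): the motif analysis in this
system is serine-centred, and the observed phosphothreonines do not sit in
Ser-x-Glu context.

## Evidence collation

Each evidence row is a phosphopeptide with one or more phospho events. An
**ambiguous either-or pair** ("103|104") is one event, one site unit, and
contributes exactly one site to every total; Ser/Thr tallies are therefore
reported as ranges (20--21 Ser, 1--2 Thr for the packaged table) and never
resolved arbitrarily. Aggregated spectral counts take the **maximum** over
rows containing a site because the per-row counts already accumulate all
peptides containing that residue; summing would double-count sites that
appear on both single- and doubly-phosphorylated rows. The major-site
threshold defaults to 20 spectral counts, which cleanly separates the four
high-count sites (counts 20--39) from the rest (at most 7); it is a plain
argument, not a fitted quantity.

`merge_maldi()` lifts the region-level ladder result onto the site map:
when the ladder maximum, minus phosphates attributed to tag serines (one,
for the observed myc-tag site), covers every serine of the region, all
region serines are marked phosphorylated at region-level resolution
("assumed" status — the ladder counts phosphates, it does not localize
them). Otherwise the map is left unchanged with a note. Tag phosphates are
reported separately and excluded from the grand total, which is how
22 LC-MS/MS sites + 9 ASARM serines = 31 mature-chain residues.

## Conservation

`site_conservation()` maps a reference position through the gapped
alignment and counts identical residues at that column. The denominator
**includes the reference** (14 for the study's mammalian panel): the
reported percentages are integer roundings of k/14 (93 = 13/14, 79 = 11/14,
...), not k/13. The match rule is exact identity — an aligned Thr does not
count for a Ser site, and a gap is a non-match. Rounding is half-away-from-
zero; banker's rounding never differs on k/14 but the choice is made
explicit in code.

## Synthetic data

The generators produce inputs with the statistical structure each stage
assumes, under integer seeds with no time-based state:

* `gen_protein()` plants Ser-x-Glu / Ser-x-Asp motifs on a serine-free
  background, so the planted occurrences are provably the only matches —
  collision-freedom by construction rather than by rejection sampling.
* `gen_ortholog_family()` substitutes columns independently at probability
  `p_sub` (default family size 14, the study's panel size). There is no
  phylogeny and no indel process: it exercises the conservation arithmetic,
  not sequence evolution, and conservation estimates recover `100(1 - p)`
  within binomial error.
* `gen_peaklist()` places rungs at `base + k*79.98` with Gaussian mass
  noise (σ = 0.3 Da default, well inside the 2 Da test tolerance and the
  ~80 Da rung spacing) plus Poisson-rate uniform noise peaks.
* `gen_evidence_table()` reports true sites on genuine tryptic peptides of
  the chain, with negative-binomial spectral counts (mean 6, size 0.6 by
  default — overdispersed like the real table's many 1--7 counts and few
  20--39) and adjacent-acceptor ambiguity at a configurable rate.

Passing tests on synthetic data therefore show that the arithmetic and the
bookkeeping are right under the stated noise models; they do not show
robustness to chimeric spectra, co-eluting peptides, isotope-envelope
overlap or alignment error, none of which the generators emulate.

## Problem sizes and determinism

The packaged analysis is desk-scale: a 45-residue construct tail, a 23-row
evidence table, two-peak and one-peak MALDI fixtures. Property tests use
random sequences up to length 200, families of 14, and tens of seeds —
sizes chosen so the whole suite runs in seconds while still exercising
every branch. `reproduce()` is fully deterministic (no randomness anywhere
in the fixture path) and running it twice yields identical reports.

## Known limitations

* The full 508-residue mature MEPE sequence is not packaged (no accession
  was deposited with the study's printed material); whole-chain motif scans
  and real ortholog conservation require the user to supply UniProt
  sequences (Q9NQ76 and the 14 ortholog accessions). The packaged pipeline
  covers every number that is computable from printed sequences and the
  evidence transcription.
* Fragment-ion (MS/MS) scoring, site-localization probabilities, isotope
  envelopes, charge states above 1, peak picking from raw traces and
  digestion kinetics are out of scope; expect values and ppm errors from
  the upstream search are carried as metadata only.
* The count of C-terminal-peptide serines conforming to Ser-x-Glu/pSer is
  sometimes quoted as four, but a direct scan of the printed 45-mer finds
  three canonical matches (489-region positions 493 and 502, plus one in
  the myc epitope) and no propagation route to a fourth from those seeds;
  the package reports what the scanners find and does not hard-code a
  count.
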