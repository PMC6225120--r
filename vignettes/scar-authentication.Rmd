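---
title: "Designing and simulating multiplex SCAR assays from barcode panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating multiplex SCAR assays from barcode panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarmux)
library(dplyr)
```

## The problem

Processed herbal material — dried, sliced roots in particular — cannot be
identified morphologically, and closely related species are routinely sold
as substitutes for the official drug. A DNA-barcode locus such as the
nuclear ribosomal internal transcribed spacer (ITS) separates such species
cleanly, but full-length barcoding requires sequencing every sample, and
amplifying a ~700 bp fragment from degraded commercial DNA often fails.

A multiplex SCAR (sequence-characterized amplified region) assay sidesteps
both problems. From an alignment of species-labeled barcode sequences one
finds *diagnostic sites* — columns fixed within one species and absent from
all others — anchors species-specific primers on them, and chooses one
primer pair per species so that the products have clearly different sizes.
A single PCR with all pairs then reads out species identity, and the
contamination of a mixture, as the *sizes of the bands on a gel*: no
sequencing at all. `scarmux` implements this design procedure and an
in-silico PCR engine to verify and apply the resulting panel.

## Models and procedures

### Distances: the Kimura 2-parameter model

Between two aligned rows we count, over the `L` sites where both rows carry
an unambiguous base (*pairwise deletion* of gapped or ambiguous sites), the
proportion of transitions `P` (A↔G, C↔T) and transversions `Q`. The K2P
distance is

d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),

in substitutions per site. Pairwise deletion (rather than dropping every
column with any gap) preserves signal when the alignment contains a single
indel column, which is exactly the regime of near-identical barcodes. When
the log arguments are non-positive the distance is undefined and the
package raises a saturation error rather than producing `NaN` — saturated
pairs should never occur between congeners at a barcode locus, so they
indicate bad input.

Per-species variability summaries (`summarize_variability()`) report the
mean ± SD of K2P over within-species pairs and over pairs crossing species
boundaries, with the outgroup excluded; SD is taken over the set of
pairwise distances. These are the numbers a barcode-gap argument rests on.

### Trees: neighbor-joining with column-bootstrap support

The package builds neighbor-joining trees from the K2P matrix (negative NJ
branch-length estimates are clamped to zero) and assesses each species'
monophyly as a *bipartition* question on the unrooted tree: do the species'
samples sit on one side of some internal edge? Support is the percentage of
trees, rebuilt from alignments resampled column-wise with replacement, that
recover the bipartition. NJ on K2P distances is deterministic, fast and —
for panels whose species are separated by tens of fixed differences —
yields the same monophyly conclusions a likelihood tree would; model-based
tree search is deliberately out of scope. An all-identical panel has no
resolution at all, and monophyly is reported as `NA` rather than a
meaningless `TRUE`.

### Diagnostic sites

A column is a substitution site for species X iff (i) every X sample
carries the same unambiguous base, (ii) that base occurs in no other
sample, and (iii) *no* sample in the column carries a gap or ambiguity
code. Three consequences are worth spelling out:

* Samples outside X need not agree among themselves, so with three or more
  species one column can be diagnostic for two species at once.
* An IUPAC ambiguity anywhere disqualifies the column for everyone — a
  conservative choice, since a primer anchored on an uncertain base is an
  uncertain marker.
* The whole-column gap-free requirement keeps indel columns out of the
  substitution tally. A species-exclusive insertion is otherwise
  indistinguishable from a substitution site (base in the target, no base
  elsewhere) and would be counted twice — once as an indel event and once
  as a substitution.

Indel events are maximal runs of columns gapped in all target samples and
ungapped in all others (or the inverse), counted once per run, so a 3-bp
deletion is one event, not three sites.

### Primer design and the size ladder

Primer candidates are windows of the species consensus whose 3′ terminus
sits on a diagnostic site. Because a diagnostic site's base occurs in *no*
non-target sample, this guarantees a 3′-terminal mismatch against every
non-target species — the mismatch position that most strongly blocks
extension. Defaults (all tunable through `design_constraints()`):

| parameter | default | why |
|---|---|---|
| primer length | 18–25 nt | standard specific-PCR range |
| product size | 100–400 bp | short products amplify from degraded DNA |
| Tm | 58–72 °C | compatible with stringent two-step annealing |
| GC | 40–70 % | avoids weak and structure-prone extremes |
| 3′ diagnostic anchor | ≥1 in last 3 nt | extension-blocking specificity |
| total mismatches vs each non-target | ≥2 | belt-and-braces specificity |
| panel size gap | ≥40 bp | bands resolvable on 1.5–2 % agarose |

Melting temperatures use the Wallace rule for oligos of ≤14 nt and the
SantaLucia (1998) unified nearest-neighbor parameters above that, with the
entropic salt correction; concentrations default to 500 nM oligo and 50 mM
monovalent salt. Candidate footprints must be uniform within the species —
a primer that sits on an intra-species polymorphism would amplify only some
authentic samples — and candidates are ranked by diagnostic sites covered,
then Tm centrality, then position.

Panel assembly (`select_multiplex_panel()`) brute-forces the cartesian
product of each species' achievable product sizes and keeps the combination
maximizing the *minimum pairwise gap*, breaking ties toward smaller total
size and then species order. The winning combination is accepted only after
the in-silico PCR closed loop passes: at zero mismatches, every sample of
the target species yields exactly one product of the predicted size and
every other sample yields none. If no combination reaches the required gap
the error reports the best achievable gap instead of silently relaxing it.

### In-silico PCR and lane classification

`find_binding_sites()` scans both strands; a site qualifies iff total
mismatches are within budget *and* the 3′-terminal `clamp_len` bases match
exactly. `simulate_multiplex()` emits an amplicon for every forward/reverse
site combination with the forward 3′ end upstream of the reverse 3′ end,
in either orientation — including cross-pair products between different
primer pairs, which are flagged rather than hidden because they are a real
multiplex design risk. Coordinates are 0-based half-open with primers
included in the product, so a template built as
`forward + 215-nt spacer + revcomp(reverse)` with 22-nt primers yields
exactly 22 + 215 + 22 = 259 bp.

Two engine parameterizations are exposed deliberately: zero mismatches for
design verification (the design must be airtight against its own training
samples) and a small mismatch budget with the clamp for surveying unseen
query material, since the mismatch tolerance of the wet assay is an
empirical property the sequences alone cannot fix.

Lane classification assigns each band to the unique panel species within
±3 bp (panels whose sizes are closer than twice this tolerance are rejected
as ambiguous at configuration time) and calls the sample `authentic`,
`adulterant_detected`, `mixed`, `no_amplification`, or `unexplained_bands`.
Band intensity is modeled only as the count of distinct co-migrating
amplicons; quantitative intensity is a DNA-quality effect outside
computational scope.

## The synthetic panel generator

`simulate_panel()` exists so that every stage is testable against *planted
ground truth*. Its defaults emulate the data regime of a three-species ITS
study: a 690-column alignment carrying 15 sequences (7 + 4 + 4), 18/10/16
fixed species-specific substitutions, one 1-bp species-exclusive insertion
in the third species (making its barcode 690 bp against 689), and a 0.001
per-site private polymorphism rate. Planted substitution states are
transitions with probability ½ so both channels of the K2P model are
exercised. Two "landing zones" (columns 140–240 and 380–480, standing in
for ITS1 and ITS2 around the conserved 5.8S gene) are each guaranteed at
least three of every species' planted sites so a short two-sided design is
always possible.

Three generator rules make exact truth recovery provable rather than merely
likely: planted features never overlap and indel runs are separated by at
least one free column (so runs cannot merge); polymorphisms never land on a
planted column and each alignment column hosts at most one; and
single-sample species receive no polymorphisms, since a private variant in
a one-sample species is mathematically indistinguishable from a fixed
species difference. With two species only, every fixed difference is
legitimately diagnostic for *both* sides, so recovered-equals-planted holds
for panels of three or more species — which is what the tests use.

What the generator does *not* emulate: sequencing error, chimeras, paralog
heterogeneity of ribosomal arrays, length-heteroplasmy, or realistic
phylogenetic correlation of the background sequence (the ancestor is
i.i.d. uniform). Passing the closed loops therefore demonstrates the
correctness of the machinery, not the field performance of any particular
primer set on real material.

```{r pipeline}
sim <- simulate_panel(panel_config(seed = 42))
diag <- scan_diagnostic_sites(sim$aligned)
diagnostic_counts(diag)

cands <- bind_rows(lapply(diag$taxa, function(tx)
  enumerate_candidates(sim$aligned, diag, tx)))
panel <- select_multiplex_panel(cands, sim$aligned)
glance(panel)

gel <- simulate_multiplex(sim$unaligned, panel, pcr_params(max_mismatch = 0))
classify_lane(gel, panel, authentic = "spA") |> count(status)
```

## Numerical and degenerate-input choices

* Progressive alignment seeds with the best-scoring pair, then accretes the
  sequence nearest to the profile, aligning it against a consensus in which
  every profile column is represented by its majority non-gap base. This
  keeps minority-insertion columns from being collapsed and re-opened,
  which would pad the alignment; on the default synthetic panels the
  realignment returns exactly 690 columns. Ties in guide order fall back to
  input order, making output deterministic.
* Consensus ties (equal base counts) resolve alphabetically; all scans and
  summaries are invariant to record order up to row ordering of results.
* Distances are undefined (error, or `NA` inside a matrix with a warning)
  rather than silently clamped; reports round to 4 decimals only at the
  output boundary.
* Bootstrap replicates whose resampled matrix contains an undefined
  distance are skipped and support is computed over the effective
  replicates.
* The test and acceptance workloads run the full pipeline on 15×690
  panels — the study-scale problem size — which keeps the complete suite
  around two minutes on a single core.

## Command line

The same pipeline is scriptable through `scar_cli()` / the `inst/cli/scarmux`
launcher: `simulate-panel`, `align`, `distances`, `scan`, `design`, `pcr`,
`classify`. All parameters arrive as flags (each subcommand logs its full
flag set and package version to standard error for provenance), outputs are
plain TSV/JSON/Newick/FASTA, and every subcommand is a pure function of its
inputs and seed.

## Known limitations

* Primer thermodynamic screening stops at Tm/GC and the 3′ diagnostic
  anchor; hairpins and primer-dimers beyond that are not modeled.
* The in-silico engine treats amplification as binary site-matching; no
  efficiency, competition or intensity modeling.
* Maximum-likelihood tree inference and substitution-model selection are
  out of scope; NJ monophyly is the supported phylogenetic check.
* The mismatch tolerance of a real assay must be calibrated against wet
  controls; the survey-mode defaults are engineering choices.
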