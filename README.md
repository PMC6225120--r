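# scarmux

Species authentication of processed biological material — dried herbal
roots being the canonical case — by **multiplex SCAR assay design and
simulation** from DNA-barcode panels.

Given a species-labeled panel of barcode sequences (ITS or any locus),
`scarmux`:

1. aligns them (progressive pairwise-then-merge alignment for
   near-identical barcodes);
2. summarises intra- and inter-species divergence under the **Kimura
   2-parameter model**, `d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with
   pairwise deletion of gapped/ambiguous sites, and checks each species'
   monophyly on a neighbor-joining tree with column-bootstrap support;
3. scans the alignment for **diagnostic sites** — columns fixed within one
   species and absent from all others (substitutions), and
   species-exclusive gap runs (indel events);
4. designs **species-specific primer pairs** anchored so that a diagnostic
   site sits in the 3′-terminal bases (guaranteeing an extension-blocking
   mismatch against every non-target species) and assembles a multiplex
   panel whose product sizes form a gel-resolvable ladder (≥40 bp apart by
   default);
5. runs **in-silico multiplex PCR** (mismatch budget + 3′ clamp,
   both strands, cross-pair artifacts flagged) and classifies each query
   sample's virtual gel lane as `authentic`, `adulterant_detected`,
   `mixed`, `no_amplification` or `unexplained_bands`.

A synthetic panel generator with planted ground truth
(`simulate_panel()`) makes the whole pipeline testable end to end, and a
command-line interface (`scar_cli()`, launcher in `inst/cli/scarmux`)
exposes every stage as a subcommand: `simulate-panel`, `align`,
`distances`, `scan`, `design`, `pcr`, `classify`.

All user-facing functions are data-frame-first and return tibbles, with
`tidy()`, `glance()` and `autoplot()` methods for the richer result
objects, so the package composes naturally with dplyr/ggplot2 workflows.

## Worked example

The package ships the published three-species *Angelica* primer panel
(`inst/extdata/angelica_panel.tsv`): pairs for the official
*A. dahurica* group and its two common adulterants, with distinct product
sizes. Here we build a synthetic test template carrying the *A. anomala*
marker region — forward primer, 215-nt spacer, reverse-complemented
reverse primer — and run the full three-pair multiplex against it:

```r
library(scarmux)

panel <- read_primer_panel(system.file("extdata", "angelica_panel.tsv",
                                       package = "scarmux"))
panel
#> # A tibble: 3 × 6
#>   taxon      forward_name forward             reverse_name reverse expected_size
#>   <chr>      <chr>        <chr>               <chr>        <chr>           <int>
#> 1 A_dahurica ADA-F        ATCGGCGTCTTTCCAAAA… ADA-R        GCACAA…           183
#> 2 A_anomala  AAN-F        AAAATCATTCAGGCGCGG… AAN-R        AAACCG…           259
#> 3 A_japonica AJA-F        GGCCACTCCTGGGTGGCC… AJA-R        CGGGAG…           309

tpl <- pair_template(panel$forward[2], panel$reverse[2],
                     spacer_len = 215, seed = 1, screen = panel)
gel <- simulate_multiplex(tibble::tibble(id = "market_sample", seq = tpl),
                          panel, pcr_params(max_mismatch = 0))
tidy(gel)
#> # A tibble: 1 × 3
#>   sample         size count
#>   <chr>         <int> <int>
#> 1 market_sample   259     1

classify_lane(gel, panel, authentic = "A_dahurica")
#> # A tibble: 1 × 4
#>   sample        taxa_detected n_bands status
#>   <chr>         <chr>           <int> <chr>
#> 1 market_sample A_anomala           1 adulterant_detected
```

The single 259 bp band is the *A. anomala* product size — exactly
`22 + 215 + 22` — and since the authentic drug is the *A. dahurica* group,
the sample is called an adulterant. Designing a fresh panel from scratch
works the same way on any labeled alignment:

```r
sim   <- simulate_panel(panel_config(seed = 42))      # or your own FASTA + sheet
diag  <- scan_diagnostic_sites(sim$aligned)
cands <- dplyr::bind_rows(lapply(diag$taxa, function(tx)
           enumerate_candidates(sim$aligned, diag, tx)))
newp  <- select_multiplex_panel(cands, sim$aligned)   # verified by in-silico PCR
```

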