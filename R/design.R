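#' Constraints for SCAR primer and panel design
#'
#' Defaults target short, gel-resolvable species-specific amplicons: primers
#' of 18-25 nt with melting temperature 58-72 C and GC 40-70%, products of
#' 100-400 bp (short targets still amplify from the degraded DNA of
#' processed herbal material), at least one diagnostic mismatch against
#' every non-target taxon within the 3 terminal 3'-bases, at least 2 total
#' mismatches against every non-target, and panel products separated by at
#' least 40 bp so bands resolve on an agarose gel.
#'
#' @param primer_len Integer range `c(min, max)` of primer lengths (nt).
#' @param amplicon Range `c(min, max)` of product sizes (bp).
#' @param tm Melting-temperature range (Celsius).
#' @param gc GC-content range (fraction).
#' @param clamp_len Length of the 3'-terminal window the diagnostic anchor
#'   must fall in.
#' @param min_clamp_diag Minimum diagnostic mismatches vs every non-target
#'   within the 3' window.
#' @param min_total_mismatch Minimum total mismatches vs every non-target
#'   consensus over the primer footprint.
#' @param min_size_gap Minimum pairwise difference between panel product
#'   sizes (bp).
#' @param min_spacer Minimum columns between forward and reverse footprints
#'   when no region annotation is given.
#' @param region_forward,region_reverse Optional 0-based half-open alignment
#'   column intervals the forward / reverse primers must lie in (e.g. the
#'   ITS1 and ITS2 regions).
#' @return A `scar_constraints` list.
#' @export
design_constraints <- function(primer_len = c(18, 25), amplicon = c(100, 400),
                               tm = c(58, 72), gc = c(0.40, 0.70),
                               clamp_len = 3, min_clamp_diag = 1,
                               min_total_mismatch = 2, min_size_gap = 40,
                               min_spacer = 20,
                               region_forward = NULL, region_reverse = NULL) {
  stopifnot(primer_len[1] <= primer_len[2], amplicon[1] <= amplicon[2],
            tm[1] <= tm[2], gc[1] <= gc[2],
            amplicon[2] >= amplicon[1] + min_size_gap)
  structure(list(primer_len = primer_len, amplicon = amplicon, tm = tm,
                 gc = gc, clamp_len = clamp_len,
                 min_clamp_diag = min_clamp_diag,
                 min_total_mismatch = min_total_mismatch,
                 min_size_gap = min_size_gap, min_spacer = min_spacer,
                 region_forward = region_forward,
                 region_reverse = region_reverse),
            class = "scar_constraints")
}

# per-taxon consensus row and validity flags over alignment columns
taxon_profiles <- function(seqs) {
  taxa <- unique(seqs$taxon)
  mat <- seq_matrix(seqs)
  setNames(map(taxa, function(tx) {
    sub <- mat[seqs$taxon == tx, , drop = FALSE]
    uniform <- apply(sub, 2, function(col) length(unique(col)) == 1)
    cons <- consensus_chars(sub)
    list(cons = cons, uniform = uniform,
         clean = uniform & cons %in% SCAR_BASES,
         pos_u = cumsum(cons != "-"))
  }), taxa)
}

#' Enumerate species-specific primer candidates for one taxon
#'
#' Candidates are windows of the taxon consensus (majority base per column)
#' whose 3' terminus sits on a diagnostic substitution site, guaranteeing a
#' 3'-terminal mismatch against every non-target taxon. Footprints must be
#' uniform within the taxon (no intra-taxon polymorphism and no gaps),
#' satisfy the length/Tm/GC constraints, carry at least
#' `min_total_mismatch` differences against every non-target consensus, and
#' lie inside the annotated region for their strand if one is given.
#'
#' @param seqs Aligned sequence tibble with `id`, `taxon`, `seq` (outgroup
#'   taxa, if any, should be dropped first, matching the diagnostics scan).
#' @param diagnostics A `scar_diagnostics` from [scan_diagnostic_sites()].
#' @param taxon Taxon to design for.
#' @param constraints A [design_constraints()] list.
#' @return Tibble of candidates sorted by (diagnostic sites covered desc,
#'   closeness of Tm to mid-range asc, start column asc): `taxon`, `strand`
#'   (`+` forward / `-` reverse), `sequence` (5'->3'), `start`/`end`
#'   (0-based half-open alignment columns), `length`, `tm`, `gc`, `n_diag`,
#'   `anchor3`. Empty if the taxon has no diagnostic substitution sites.
#' @export
enumerate_candidates <- function(seqs, diagnostics, taxon,
                                 constraints = design_constraints()) {
  check_aligned(seqs)
  check_taxon_column(seqs)
  if (!taxon %in% diagnostics$taxa) {
    scar_abort(sprintf("taxon %s not present in diagnostics", taxon),
               class = "scar_partition")
  }
  empty <- tibble(taxon = character(), strand = character(),
                  sequence = character(), start = integer(), end = integer(),
                  length = integer(), tm = numeric(), gc = numeric(),
                  n_diag = integer(), anchor3 = logical())
  dsub <- diagnostics$sites |>
    filter(.data$taxon == !!taxon, .data$kind == "substitution")
  if (nrow(dsub) == 0) return(empty)
  dcols <- dsub$column + 1L                    # 1-based alignment columns

  prof <- taxon_profiles(seqs)
  me <- prof[[taxon]]
  others <- prof[setdiff(names(prof), taxon)]
  nc <- length(me$cons)
  cl <- constraints$clamp_len

  # mismatch indicator vs each non-target consensus, per column
  mm <- map(others, function(o) me$cons != o$cons | o$cons == "-")

  eval_window <- function(s, e, strand) {
    if (s < 1 || e > nc) return(NULL)
    idx <- s:e
    if (!all(me$clean[idx])) return(NULL)
    region <- if (strand == "+") constraints$region_forward else constraints$region_reverse
    if (!is.null(region) && !(s - 1 >= region[1] && e <= region[2])) return(NULL)
    clamp_idx <- if (strand == "+") max(s, e - cl + 1):e else s:min(e, s + cl - 1)
    ok_mm <- all(map_lgl(mm, function(v)
      sum(v[idx]) >= constraints$min_total_mismatch &&
        sum(v[clamp_idx]) >= constraints$min_clamp_diag))
    if (!ok_mm) return(NULL)
    raw <- paste(me$cons[idx], collapse = "")
    sq <- if (strand == "+") raw else dna_revcomp(raw)
    gcv <- gc_fraction(sq)
    if (gcv < constraints$gc[1] || gcv > constraints$gc[2]) return(NULL)
    tmv <- melting_temperature(sq)
    if (tmv < constraints$tm[1] || tmv > constraints$tm[2]) return(NULL)
    nd <- sum(dcols >= s & dcols <= e)
    tibble(taxon = taxon, strand = strand, sequence = sq,
           start = s - 1L, end = e, length = e - s + 1L,
           tm = tmv, gc = gcv, n_diag = nd,
           anchor3 = any(dcols >= clamp_idx[1] & dcols <= clamp_idx[length(clamp_idx)]))
  }

  lens <- constraints$primer_len[1]:constraints$primer_len[2]
  cands <- list()
  for (d in dcols) {
    for (off in 0:(cl - 1)) {
      for (L in lens) {
        e_f <- d + off                         # forward: 3' end at column e_f
        cands[[length(cands) + 1]] <- eval_window(e_f - L + 1, e_f, "+")
        s_r <- d - off                         # reverse: 3' end at column s_r
        cands[[length(cands) + 1]] <- eval_window(s_r, s_r + L - 1, "-")
      }
    }
  }
  out <- bind_rows(cands)
  if (nrow(out) == 0) return(empty)
  out <- distinct(out, .data$strand, .data$start, .data$end, .keep_all = TRUE)
  tm_mid <- mean(constraints$tm)
  arrange(out, desc(.data$n_diag), abs(.data$tm - tm_mid), .data$start)
}

#' Pick one product size per taxon maximizing the minimum pairwise gap
#'
#' Exhaustive search over the cartesian product of the per-taxon size
#' options. Combinations are ranked by minimum pairwise gap (descending),
#' then total product size (ascending), then the size vector in taxon order;
#' all sizes in a combination must be distinct.
#'
#' @param size_sets Named list (taxon -> integer vector of candidate product
#'   sizes).
#' @param min_gap Required minimum pairwise gap (bp).
#' @return Tibble of feasible combinations (best first) with one column per
#'   taxon plus `min_gap` and `total`. Raises an infeasibility error listing
#'   the best achievable gap when no combination reaches `min_gap`.
#' @export
choose_panel_sizes <- function(size_sets, min_gap = 40) {
  stopifnot(length(size_sets) >= 2, !is.null(names(size_sets)))
  grid <- expand.grid(map(size_sets, unique), KEEP.OUT.ATTRS = FALSE)
  gaps <- apply(grid, 1, function(sz) min(dist(as.numeric(sz))))
  totals <- rowSums(grid)
  ord <- do.call(order, c(list(-gaps, totals), as.list(grid)))
  grid <- grid[ord, , drop = FALSE]
  gaps <- gaps[ord]; totals <- totals[ord]
  keep <- gaps >= min_gap & gaps > 0
  if (!any(keep)) {
    scar_abort(sprintf(
      "no size combination reaches a %d bp gap (best achievable: %d bp)",
      min_gap, as.integer(max(gaps))),
      class = "scar_infeasible", best_gap = max(gaps))
  }
  out <- as_tibble(grid[keep, , drop = FALSE])
  out$min_gap <- gaps[keep]
  out$total <- totals[keep]
  out
}

# all (forward, reverse) pairings of a taxon's candidates with their
# predicted product size on the taxon consensus
pair_candidates <- function(cands, profile, constraints, max_each = 60) {
  fwd <- head(filter(cands, .data$strand == "+"), max_each)
  rev <- head(filter(cands, .data$strand == "-"), max_each)
  if (nrow(fwd) == 0 || nrow(rev) == 0) return(NULL)
  fwd$f_rank <- seq_len(nrow(fwd))
  rev$r_rank <- seq_len(nrow(rev))
  pairs <- tidyr::crossing(
    rename(select(fwd, "sequence", "start", "end", "f_rank"),
           forward = "sequence", f_start = "start", f_end = "end"),
    rename(select(rev, "sequence", "start", "end", "r_rank"),
           reverse = "sequence", r_start = "start", r_end = "end")
  ) |>
    filter(.data$f_end + constraints$min_spacer <= .data$r_start)
  if (nrow(pairs) == 0) return(NULL)
  pairs$size <- profile$pos_u[pairs$r_end] - profile$pos_u[pairs$f_start + 1L] + 1L
  pairs <- filter(pairs, .data$size >= constraints$amplicon[1],
                  .data$size <= constraints$amplicon[2])
  if (nrow(pairs) == 0) return(NULL)
  # best-ranked pair per distinct size
  pairs |>
    arrange(.data$f_rank + .data$r_rank, .data$f_rank) |>
    distinct(.data$size, .keep_all = TRUE)
}

#' Assemble a multiplex SCAR panel from per-taxon candidates
#'
#' Pairs each taxon's forward and reverse candidates, picks one pair per
#' taxon so that product sizes form a ladder maximizing the minimum pairwise
#' gap (ties: smaller total size, then taxon order), and verifies the chosen
#' panel by in-silico multiplex PCR against every input sample: exactly one
#' product of the predicted size on the taxon's own samples, none on any
#' other sample, at zero mismatches. Combinations failing verification are
#' discarded and the next-ranked one is tried.
#'
#' @param candidates Row-bound [enumerate_candidates()] output for all taxa.
#' @param seqs The aligned, taxon-labeled sequences the design is based on.
#' @param constraints A [design_constraints()] list.
#' @param verify Set `FALSE` to skip the in-silico PCR verification.
#' @param max_combos Maximum ranked size combinations to try verifying.
#' @return A `scar_panel` tibble (taxon, primer names, sequences, expected
#'   size) with the achieved minimum gap in `attr(, "min_gap")`.
#' @export
select_multiplex_panel <- function(candidates, seqs,
                                   constraints = design_constraints(),
                                   verify = TRUE, max_combos = 50) {
  check_aligned(seqs)
  check_taxon_column(seqs)
  taxa <- unique(candidates$taxon)
  if (length(taxa) < 2) {
    scar_abort("panel selection needs candidates for at least 2 taxa",
               class = "scar_degenerate_input")
  }
  prof <- taxon_profiles(seqs)
  pairs_by_taxon <- setNames(map(taxa, function(tx) {
    p <- pair_candidates(filter(candidates, .data$taxon == tx),
                         prof[[tx]], constraints)
    if (is.null(p)) {
      scar_abort(sprintf("no feasible primer pair for taxon %s", tx),
                 class = "scar_infeasible")
    }
    p
  }), taxa)

  combos <- choose_panel_sizes(map(pairs_by_taxon, "size"),
                               min_gap = constraints$min_size_gap)
  combos <- head(combos, max_combos)

  build <- function(combo) {
    rows <- map(taxa, function(tx) {
      p <- pairs_by_taxon[[tx]]
      p <- p[p$size == combo[[tx]], ][1, ]
      tibble(taxon = tx, forward = p$forward, reverse = p$reverse,
             expected_size = as.integer(p$size))
    })
    new_scar_panel(bind_rows(rows), min_gap = combo$min_gap)
  }

  for (i in seq_len(nrow(combos))) {
    panel <- build(combos[i, ])
    if (!verify || panel_verifies(panel, seqs)) return(panel)
  }
  scar_abort("no size-feasible panel passed in-silico PCR verification",
             class = "scar_infeasible")
}

# zero-mismatch closed loop: one product of the predicted size on targets,
# zero products on non-targets
panel_verifies <- function(panel, seqs) {
  params <- pcr_params(max_mismatch = 0)
  templates <- mutate(seqs, seq = ungap(.data$seq))
  gel <- simulate_multiplex(templates, panel, params)
  for (i in seq_len(nrow(templates))) {
    lane <- filter(gel$lanes, .data$sample == templates$id[i])
    expect <- panel$expected_size[panel$taxon == templates$taxon[i]]
    if (length(expect) == 1) {
      if (!(nrow(lane) == 1 && lane$size == expect && lane$count == 1)) return(FALSE)
    } else if (nrow(lane) != 0) {
      return(FALSE)
    }
  }
  TRUE
}

#' @export
tidy.scar_panel <- function(x, ...) {
  seqs <- as.vector(rbind(x$forward, x$reverse))
  tibble(
    taxon = rep(x$taxon, each = 2),
    primer = as.vector(rbind(x$forward_name, x$reverse_name)),
    direction = rep(c("forward", "reverse"), nrow(x)),
    sequence = seqs,
    length = nchar(seqs),
    product_size = rep(x$expected_size, each = 2)
  )
}

#' @export
glance.scar_panel <- function(x, ...) {
  gap <- attr(x, "min_gap")
  if (is.null(gap) || is.na(gap)) {
    gap <- if (nrow(x) >= 2) min(dist(x$expected_size)) else NA_real_
  }
  tibble(n_taxa = nrow(x), min_size_gap = as.numeric(gap),
         total_size = sum(x$expected_size))
}
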