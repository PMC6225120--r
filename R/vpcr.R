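#' Parameters for the in-silico PCR engine
#'
#' @param max_mismatch Maximum total mismatches tolerated per primer binding
#'   site. Use 0 for design verification; a small budget (e.g. 2) models the
#'   tolerance of a survey assay on unseen variants.
#' @param clamp_len Number of 3'-terminal primer bases that must match the
#'   template exactly (the 3' clamp required for polymerase extension).
#' @param max_product_len Longest product emitted (bp).
#' @param size_tolerance Band-to-taxon matching tolerance for lane
#'   classification (bp).
#' @return A `scar_pcr_params` list.
#' @export
pcr_params <- function(max_mismatch = 0, clamp_len = 3,
                       max_product_len = 2000, size_tolerance = 3) {
  stopifnot(max_mismatch >= 0, clamp_len >= 0, size_tolerance >= 0)
  structure(list(max_mismatch = max_mismatch, clamp_len = clamp_len,
                 max_product_len = max_product_len,
                 size_tolerance = size_tolerance),
            class = "scar_pcr_params")
}

#' Find primer binding sites on a template
#'
#' Scans both strands. A site qualifies iff its total mismatch count is at
#' most `max_mismatch` and its `clamp_len` 3'-terminal bases match the
#' template exactly. Overlapping sites are all reported. The primer is given
#' 5'->3' as synthesized; a minus-strand site means the primer binds the
#' minus strand, i.e. its reverse complement occurs on the plus strand.
#'
#' @param template A gap-free template sequence string.
#' @param primer Unambiguous primer sequence, 5'->3'.
#' @param params A [pcr_params()] list.
#' @param strand_mode `"both"`, `"plus"` or `"minus"`.
#' @return Tibble `strand`, `start`, `end` (1-based inclusive plus-strand
#'   span of the footprint), `three_prime` (plus-strand position of the
#'   primer's 3' end), `mismatches`.
#' @export
find_binding_sites <- function(template, primer, params = pcr_params(),
                               strand_mode = c("both", "plus", "minus")) {
  strand_mode <- match.arg(strand_mode)
  template <- toupper(template)
  primer <- toupper(primer)
  if (grepl("-", template, fixed = TRUE)) {
    scar_abort("template must be gap-free", class = "scar_format")
  }
  if (grepl("[^ACGT]", primer)) {
    scar_abort("primer must be unambiguous A/C/G/T", class = "scar_format")
  }
  empty <- tibble(strand = character(), start = integer(), end = integer(),
                  three_prime = integer(), mismatches = integer())
  np <- nchar(primer)
  if (np > nchar(template)) return(empty)
  subj <- Biostrings::DNAString(template)
  cl <- min(params$clamp_len, np)

  scan <- function(query, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(query), subj,
                                     max.mismatch = params$max_mismatch,
                                     with.indels = FALSE)
    if (length(hits) == 0) return(NULL)
    starts <- Biostrings::start(hits)
    qch <- strsplit(query, "", fixed = TRUE)[[1]]
    tch <- strsplit(template, "", fixed = TRUE)[[1]]
    rows <- map(starts, function(s) {
      frag <- tch[s:(s + np - 1)]
      mm <- which(frag != qch)
      clamp_idx <- if (strand == "+") (np - cl + 1):np else seq_len(cl)
      if (cl > 0 && any(mm %in% clamp_idx)) return(NULL)
      tibble(strand = strand, start = s, end = s + np - 1L,
             three_prime = if (strand == "+") s + np - 1L else s,
             mismatches = length(mm))
    })
    bind_rows(rows)
  }
  out <- bind_rows(
    if (strand_mode %in% c("both", "plus")) scan(primer, "+"),
    if (strand_mode %in% c("both", "minus")) scan(dna_revcomp(primer), "-")
  )
  if (nrow(out) == 0) empty else arrange(out, .data$start)
}

#' Simulate a multiplex PCR and collect virtual gel lanes
#'
#' For every forward-primer site and reverse-primer site on a template, in
#' either orientation, with the forward 3' end upstream of the reverse
#' 3' end and the product no longer than `max_product_len`, an amplicon is
#' emitted. Products formed by the forward primer of one pair and the
#' reverse primer of another ("cross-pair" artifacts, a real multiplex
#' risk) are emitted too and flagged. A sample's lane is the union of the
#' bands of all its templates.
#'
#' @param templates Tibble with `id` and `seq` (gaps are stripped), plus an
#'   optional `sample` column grouping several templates into one reaction
#'   (defaults to `id`).
#' @param panel A `scar_panel`.
#' @param params A [pcr_params()] list.
#' @return A `scar_gel` object: `$amplicons` (template, coordinates, size,
#'   primer pair), `$lanes` (sample, size, count of distinct amplicons at
#'   that size), `$samples` (every sample, including empty lanes).
#'   `tidy()` returns the lanes.
#' @export
simulate_multiplex <- function(templates, panel, params = pcr_params()) {
  if (nrow(panel) == 0) scar_abort("empty panel", class = "scar_empty_panel")
  if (!"sample" %in% names(templates)) templates$sample <- templates$id
  templates$seq <- ungap(toupper(templates$seq))

  amps <- list()
  for (i in seq_len(nrow(templates))) {
    tpl <- templates$seq[i]
    sites <- map(seq_len(nrow(panel)), function(k) list(
      f = find_binding_sites(tpl, panel$forward[k], params),
      r = find_binding_sites(tpl, panel$reverse[k], params)
    ))
    for (kf in seq_len(nrow(panel))) {
      for (kr in seq_len(nrow(panel))) {
        f <- sites[[kf]]$f
        r <- sites[[kr]]$r
        # plus orientation: forward on +, reverse (as revcomp) on -
        fp <- f[f$strand == "+", ]
        rm_ <- r[r$strand == "-", ]
        for (a in seq_len(nrow(fp))) {
          for (b in seq_len(nrow(rm_))) {
            if (fp$three_prime[a] < rm_$three_prime[b]) {
              size <- rm_$end[b] - fp$start[a] + 1L
              if (size <= params$max_product_len) {
                amps[[length(amps) + 1]] <- tibble(
                  sample = templates$sample[i], template = templates$id[i],
                  taxon_f = panel$taxon[kf], taxon_r = panel$taxon[kr],
                  cross = kf != kr, orientation = "+",
                  start = fp$start[a] - 1L, end = rm_$end[b], size = size
                )
              }
            }
          }
        }
        # minus orientation: the template is the reverse complement of the
        # canonical amplicon; reverse primer verbatim on +, forward on -
        rp <- r[r$strand == "+", ]
        fm <- f[f$strand == "-", ]
        for (a in seq_len(nrow(rp))) {
          for (b in seq_len(nrow(fm))) {
            if (rp$three_prime[a] < fm$three_prime[b]) {
              size <- fm$end[b] - rp$start[a] + 1L
              if (size <= params$max_product_len) {
                amps[[length(amps) + 1]] <- tibble(
                  sample = templates$sample[i], template = templates$id[i],
                  taxon_f = panel$taxon[kf], taxon_r = panel$taxon[kr],
                  cross = kf != kr, orientation = "-",
                  start = rp$start[a] - 1L, end = fm$end[b], size = size
                )
              }
            }
          }
        }
      }
    }
  }
  amplicons <- if (length(amps) > 0) bind_rows(amps) else
    tibble(sample = character(), template = character(),
           taxon_f = character(), taxon_r = character(), cross = logical(),
           orientation = character(), start = integer(), end = integer(),
           size = integer())
  lanes <- amplicons |>
    distinct(.data$sample, .data$template, .data$taxon_f, .data$taxon_r,
             .data$start, .data$end, .keep_all = TRUE) |>
    group_by(.data$sample, .data$size) |>
    summarise(count = n(), .groups = "drop") |>
    arrange(.data$sample, .data$size)
  structure(list(amplicons = amplicons, lanes = lanes,
                 samples = unique(templates$sample),
                 panel = panel, params = params),
            class = "scar_gel")
}

#' @export
tidy.scar_gel <- function(x, ...) x$lanes

#' @export
glance.scar_gel <- function(x, ...) {
  tibble(n_samples = length(x$samples),
         n_samples_with_bands = length(unique(x$lanes$sample)),
         n_bands = nrow(x$lanes),
         n_cross_pair = sum(x$amplicons$cross))
}

#' @export
print.scar_gel <- function(x, ...) {
  cat(sprintf("<scar_gel> %d samples, %d bands\n",
              length(x$samples), nrow(x$lanes)))
  print(x$lanes)
  invisible(x)
}

#' Virtual gel plot
#'
#' Renders lanes as an agarose-gel sketch: one lane per sample, band
#' position by product size (largest at the top, like a gel run from top to
#' bottom), thicker bands where several distinct amplicons co-migrate.
#'
#' @param object A `scar_gel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scar_gel <- function(object, ...) {
  lanes <- mutate(object$lanes,
                  lane = as.numeric(factor(.data$sample, levels = object$samples)))
  ggplot2::ggplot(lanes) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$lane - 0.35, xend = .data$lane + 0.35,
      y = .data$size, yend = .data$size, linewidth = .data$count
    ), colour = "grey15") +
    ggplot2::scale_x_continuous(breaks = seq_along(object$samples),
                                labels = object$samples) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_linewidth(range = c(1.2, 3), guide = "none") +
    ggplot2::labs(x = NULL, y = "product size (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Classify virtual gel lanes against a panel
#'
#' Each band is assigned to the unique panel taxon whose expected product
#' size lies within `size_tolerance`; the per-sample call follows from the
#' set of detected taxa relative to the designated authentic taxa:
#' `authentic` (only authentic taxa detected, no stray bands),
#' `adulterant_detected` (only non-authentic taxa), `mixed` (both),
#' `no_amplification` (empty lane) or `unexplained_bands` (a band matching
#' no panel product).
#'
#' @param gel A `scar_gel` from [simulate_multiplex()], or a lane tibble
#'   with columns `sample`, `size`.
#' @param panel The `scar_panel` the assay was run with.
#' @param authentic Character vector of taxa constituting authentic
#'   material.
#' @param params A [pcr_params()] list (supplies `size_tolerance`). Panels
#'   whose expected sizes are closer than twice the tolerance are rejected
#'   as ambiguous at configuration time.
#' @return Tibble `sample`, `taxa_detected` (comma-separated), `n_bands`,
#'   `status`.
#' @export
classify_lane <- function(gel, panel, authentic, params = pcr_params()) {
  sizes <- panel$expected_size
  if (anyNA(sizes)) {
    scar_abort("panel has missing expected sizes", class = "scar_format")
  }
  if (nrow(panel) >= 2 && min(dist(sizes)) <= 2 * params$size_tolerance) {
    scar_abort("panel product sizes are closer than twice the size tolerance: bands would be ambiguous",
               class = "scar_ambiguous_panel")
  }
  if (!all(authentic %in% panel$taxon)) {
    scar_abort("authentic taxa must appear in the panel", class = "scar_partition")
  }
  if (inherits(gel, "scar_gel")) {
    lanes <- gel$lanes
    samples <- gel$samples
  } else {
    lanes <- gel
    samples <- unique(lanes$sample)
  }
  if (length(samples) == 0) {
    return(tibble(sample = character(), taxa_detected = character(),
                  n_bands = integer(), status = character()))
  }
  rows <- map(samples, function(sm) {
    bands <- lanes$size[lanes$sample == sm]
    hit <- map_chr(bands, function(b) {
      k <- which(abs(sizes - b) <= params$size_tolerance)
      if (length(k) == 1) panel$taxon[k] else NA_character_
    })
    detected <- sort(unique(hit[!is.na(hit)]))
    status <- if (length(bands) == 0) {
      "no_amplification"
    } else if (anyNA(hit)) {
      "unexplained_bands"
    } else if (all(detected %in% authentic)) {
      "authentic"
    } else if (any(detected %in% authentic)) {
      "mixed"
    } else {
      "adulterant_detected"
    }
    tibble(sample = sm, taxa_detected = paste(detected, collapse = ","),
           n_bands = length(bands), status = status)
  })
  bind_rows(rows)
}
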