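#' Scan an alignment for taxon-diagnostic substitution and indel sites
#'
#' A substitution site for a taxon is an alignment column where (i) all of
#' the taxon's samples share one unambiguous base, (ii) that base occurs in
#' no other sample, (iii) no sample anywhere in the column carries a gap or
#' an IUPAC ambiguity code. Requiring the whole column to be gap-free keeps
#' indel columns out of the substitution count (they are reported as indel
#' events instead); requiring it ambiguity-free is a conservative choice for
#' marker design. Because samples outside the taxon need not agree among
#' themselves, one column can be diagnostic for more than one taxon.
#'
#' An indel event for a taxon is a maximal run of consecutive columns gapped
#' in all of the taxon's samples and ungapped in all others (a deletion), or
#' the inverse (an insertion); each run counts once.
#'
#' @param seqs Aligned sequence tibble with `id`, `taxon`, `seq`.
#' @param exclude_taxa Taxa (e.g. the outgroup) removed before scanning.
#' @param collapse_indels If `FALSE`, indel rows are reported per column
#'   instead of one row per run.
#' @return A `scar_diagnostics` object; `tidy()` returns the site table
#'   (`taxon`, `column` 0-based, `length`, `kind`, `target_state`,
#'   `other_states`), [diagnostic_counts()] the per-taxon counts.
#' @export
scan_diagnostic_sites <- function(seqs, exclude_taxa = NULL,
                                  collapse_indels = TRUE) {
  check_aligned(seqs)
  check_taxon_column(seqs)
  seqs <- filter(seqs, !(.data$taxon %in% exclude_taxa))
  taxa <- unique(seqs$taxon)
  mat <- seq_matrix(seqs)
  nc <- ncol(mat)
  is_gap <- mat == "-"
  is_base <- matrix(mat %in% SCAR_BASES, nrow(mat), nc)
  col_clean <- colSums(!is_base) == 0          # no gap/ambiguity anywhere

  sites <- list()
  for (tx in taxa) {
    tr <- seqs$taxon == tx
    if (!any(tr)) {
      scar_abort(sprintf("taxon %s has no samples in the alignment", tx),
                 class = "scar_partition")
    }
    tmat <- mat[tr, , drop = FALSE]
    omat <- mat[!tr, , drop = FALSE]

    # substitution sites
    fixed <- apply(tmat, 2, function(col) {
      u <- unique(col)
      if (length(u) == 1 && u %in% SCAR_BASES) u else NA_character_
    })
    sub_cols <- which(col_clean & !is.na(fixed) &
                        !map_lgl(seq_len(nc), function(j) fixed[j] %in% omat[, j]))
    if (length(sub_cols) > 0) {
      sites[[length(sites) + 1]] <- tibble(
        taxon = tx, column = sub_cols - 1L, length = 1L, kind = "substitution",
        target_state = fixed[sub_cols],
        other_states = map_chr(sub_cols, function(j)
          paste(sort(unique(omat[, j])), collapse = "/"))
      )
    }

    # indel events: taxon-exclusive gap runs (either polarity)
    tgap <- colSums(is_gap[tr, , drop = FALSE]) == sum(tr)
    tbase <- colSums(is_gap[tr, , drop = FALSE]) == 0
    ogap <- colSums(is_gap[!tr, , drop = FALSE]) == sum(!tr)
    obase <- colSums(is_gap[!tr, , drop = FALSE]) == 0
    del_cols <- tgap & obase                   # deletion in target
    ins_cols <- tbase & ogap                   # insertion in target
    for (polarity in c("deletion", "insertion")) {
      flag <- if (polarity == "deletion") del_cols else ins_cols
      if (!any(flag)) next
      r <- rle(flag)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- which(r$values)
      rows <- tibble(
        taxon = tx,
        column = starts[runs] - 1L,
        length = r$lengths[runs],
        kind = "indel",
        target_state = ifelse(polarity == "deletion",
                              strrep("-", r$lengths[runs]),
                              map_chr(runs, function(k) paste(
                                consensus_chars(mat[tr, starts[k]:ends[k], drop = FALSE]),
                                collapse = ""))),
        other_states = ifelse(polarity == "deletion", "base", "-")
      )
      if (!collapse_indels) {
        rows <- tidyr::uncount(rows, .data$length, .id = "offset") |>
          mutate(column = .data$column + .data$offset - 1L, length = 1L) |>
          select(-"offset")
      }
      sites[[length(sites) + 1]] <- rows
    }
  }
  sites <- if (length(sites) > 0) {
    arrange(bind_rows(sites), match(.data$taxon, taxa), .data$column)
  } else {
    tibble(taxon = character(), column = integer(), length = integer(),
           kind = character(), target_state = character(),
           other_states = character())
  }
  structure(list(sites = sites, taxa = taxa, n_columns = nc),
            class = "scar_diagnostics")
}

#' Per-taxon diagnostic site counts
#'
#' @param x A `scar_diagnostics` object.
#' @return Tibble with `taxon`, `n_substitution_sites`, `n_indel_events`.
#' @export
diagnostic_counts <- function(x) {
  stopifnot(inherits(x, "scar_diagnostics"))
  base <- tibble(taxon = x$taxa)
  tallies <- x$sites |>
    group_by(.data$taxon) |>
    summarise(
      n_substitution_sites = sum(.data$kind == "substitution"),
      n_indel_events = sum(.data$kind == "indel"),
      .groups = "drop"
    )
  out <- left_join(base, tallies, by = "taxon")
  out$n_substitution_sites[is.na(out$n_substitution_sites)] <- 0L
  out$n_indel_events[is.na(out$n_indel_events)] <- 0L
  out
}

#' @export
tidy.scar_diagnostics <- function(x, ...) x$sites

#' @export
glance.scar_diagnostics <- function(x, ...) {
  tibble(
    n_taxa = length(x$taxa),
    n_columns = x$n_columns,
    n_substitution_sites = sum(x$sites$kind == "substitution"),
    n_indel_events = sum(x$sites$kind == "indel")
  )
}

#' @export
print.scar_diagnostics <- function(x, ...) {
  cat(sprintf("<scar_diagnostics> %d taxa, %d columns\n",
              length(x$taxa), x$n_columns))
  print(diagnostic_counts(x))
  invisible(x)
}

#' Windows of the alignment dense in diagnostic sites
#'
#' Slides a fixed-length window over the alignment and reports, per taxon,
#' every half-open column interval containing at least `min_sites` diagnostic
#' sites, sorted by site count (descending) then leftmost start. These are
#' the regions worth anchoring primers in.
#'
#' @param diagnostics A `scar_diagnostics` object.
#' @param min_sites Minimum diagnostic sites a window must contain.
#' @param window_len Window length in alignment columns.
#' @return Tibble `taxon`, `start`, `end` (0-based half-open), `n_sites`.
#' @export
diagnostic_windows <- function(diagnostics, min_sites = 2, window_len = 100) {
  stopifnot(inherits(diagnostics, "scar_diagnostics"), window_len >= 1)
  nc <- diagnostics$n_columns
  out <- map(diagnostics$taxa, function(tx) {
    cols <- diagnostics$sites$column[diagnostics$sites$taxon == tx]
    if (length(cols) == 0) return(NULL)
    starts <- 0:max(nc - window_len, 0)
    n_in <- vapply(starts, function(s)
      sum(cols >= s & cols < s + window_len), integer(1))
    keep <- n_in >= min_sites
    if (!any(keep)) return(NULL)
    tibble(taxon = tx, start = starts[keep], end = starts[keep] + window_len,
           n_sites = n_in[keep])
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(taxon = character(), start = integer(), end = integer(),
                  n_sites = integer()))
  }
  arrange(out, match(.data$taxon, diagnostics$taxa), desc(.data$n_sites),
          .data$start)
}
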