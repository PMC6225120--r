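#' Read a (multi-)FASTA file into a sequence tibble
#'
#' Sequences are case-normalized to uppercase, `U` is mapped to `T` and `.`
#' (a common gap dialect) to `-`. Record IDs are taken as the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE`, all sequences must have equal length (an
#'   alignment); unequal lengths raise an alignment-shape error.
#' @return A tibble with columns `id` and `seq`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgu", ">b", "ACGT"), fa)
#' read_fasta(fa, aligned = TRUE)
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) {
    scar_abort(sprintf("FASTA file not found: %s", path), class = "scar_io")
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- chartr("u.", "T-", chartr("U", "T", toupper(as.character(ss))))
  names(seqs) <- NULL

  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    scar_abort(sprintf("duplicate sequence IDs: %s", paste(dup, collapse = ", ")),
               class = "scar_duplicate_id")
  }
  if (any(!nzchar(seqs))) {
    scar_abort(sprintf("empty sequence for ID %s", ids[!nzchar(seqs)][1]),
               class = "scar_format")
  }
  bad <- regexpr(sprintf("[^%s]", paste(SCAR_ALPHABET, collapse = "")), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    scar_abort(
      sprintf("illegal character '%s' in sequence '%s' at position %d",
              substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]),
      class = "scar_format"
    )
  }
  out <- tibble(id = ids, seq = seqs)
  if (aligned) check_aligned(out, arg = path)
  out
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for wrapping sequence text.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  lines <- unlist(map2(seqs$id, seqs$seq, function(id, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines %||% character(0), path)
  invisible(path)
}

#' Read a sample sheet mapping sequence IDs to taxa
#'
#' A two-column TSV with header `id<TAB>taxon`. Query FASTA files being
#' authenticated need no sheet.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `id`, `taxon`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (!all(c("id", "taxon") %in% names(sheet))) {
    scar_abort("sample sheet must have columns 'id' and 'taxon'",
               class = "scar_format")
  }
  as_tibble(sheet[, c("id", "taxon")])
}

#' Attach taxon labels to sequences
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param sheet Sample sheet tibble (`id`, `taxon`).
#' @return `seqs` with a `taxon` column. IDs in the sheet that are missing
#'   from `seqs`, or sequences without a sheet entry, raise a partition error.
#' @export
join_taxa <- function(seqs, sheet) {
  missing <- setdiff(sheet$id, seqs$id)
  if (length(missing) > 0) {
    scar_abort(sprintf("sample sheet IDs not present in sequences: %s",
                       paste(missing, collapse = ", ")),
               class = "scar_partition")
  }
  out <- left_join(seqs, sheet, by = "id")
  if (anyNA(out$taxon)) {
    scar_abort(sprintf("no taxon label for: %s",
                       paste(out$id[is.na(out$taxon)], collapse = ", ")),
               class = "scar_partition")
  }
  select(out, "id", "taxon", "seq")
}

#' Read a SCAR primer panel table
#'
#' Parses a TSV with columns `taxon`, `primer`, `sequence`, `size`, one row
#' per primer oligo. `F`/`R` suffixes on the primer name mark forward and
#' reverse primers; a blank `taxon` cell continues the taxon above (the usual
#' layout of published primer tables). Reverse primers are written 5'->3' as
#' synthesized, i.e. they bind the plus strand as their reverse complement.
#'
#' @param path Path to the panel TSV.
#' @return A `scar_panel` tibble: `taxon`, `forward_name`, `forward`,
#'   `reverse_name`, `reverse`, `expected_size`.
#' @export
read_primer_panel <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (nrow(tab) == 0) {
    scar_abort("primer panel file has no rows", class = "scar_empty_panel")
  }
  need <- c("taxon", "primer", "sequence")
  if (!all(need %in% names(tab))) {
    scar_abort("primer panel must have columns taxon, primer, sequence[, size]",
               class = "scar_format")
  }
  if (!"size" %in% names(tab)) tab$size <- NA_character_
  tab <- tidyr::fill(tab, "taxon")
  tab$sequence <- toupper(tab$sequence)

  rows <- tab |>
    mutate(dir = case_when(
      grepl("F$", .data$primer) ~ "forward",
      grepl("R$", .data$primer) ~ "reverse",
      TRUE ~ NA_character_
    ))
  if (anyNA(rows$dir)) {
    scar_abort(sprintf("primer name without F/R suffix: %s",
                       paste(rows$primer[is.na(rows$dir)], collapse = ", ")),
               class = "scar_format")
  }
  pairs <- rows |>
    group_by(.data$taxon) |>
    summarise(
      forward_name = .data$primer[.data$dir == "forward"][1],
      forward = .data$sequence[.data$dir == "forward"][1],
      reverse_name = .data$primer[.data$dir == "reverse"][1],
      reverse = .data$sequence[.data$dir == "reverse"][1],
      expected_size = suppressWarnings(as.integer(.data$size[!is.na(.data$size)][1])),
      n_f = sum(.data$dir == "forward"),
      n_r = sum(.data$dir == "reverse"),
      .groups = "drop"
    )
  bad <- pairs$n_f != 1 | pairs$n_r != 1
  if (any(bad)) {
    scar_abort(sprintf("taxon %s does not have exactly one forward and one reverse primer",
                       paste(pairs$taxon[bad], collapse = ", ")),
               class = "scar_pairing")
  }
  pairs <- pairs[match(unique(tab$taxon), pairs$taxon), ]
  new_scar_panel(select(pairs, -"n_f", -"n_r"))
}

# validating constructor for the panel tibble
new_scar_panel <- function(pairs, min_gap = NA_real_) {
  for (col in c("forward", "reverse")) {
    p <- pairs[[col]]
    if (any(nchar(p) < 10)) {
      scar_abort("primers must be at least 10 nt long", class = "scar_format")
    }
    if (any(grepl("[^ACGT]", p))) {
      scar_abort(sprintf("non-ACGT base in %s primer of taxon %s", col,
                         pairs$taxon[grepl("[^ACGT]", p)][1]),
                 class = "scar_format")
    }
  }
  if (!"forward_name" %in% names(pairs)) {
    pairs$forward_name <- paste0(pairs$taxon, "-F")
    pairs$reverse_name <- paste0(pairs$taxon, "-R")
  }
  out <- as_tibble(pairs)[, c("taxon", "forward_name", "forward",
                              "reverse_name", "reverse", "expected_size")]
  structure(out, class = c("scar_panel", class(tibble())), min_gap = min_gap)
}

#' Write a primer panel in published-table layout
#'
#' One row per oligo: `taxon`, `primer`, `sequence`, `size` (size printed on
#' the forward row only). The file round-trips through [read_primer_panel()].
#'
#' @param panel A `scar_panel`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  long <- tibble(
    taxon = rep(panel$taxon, each = 2),
    primer = as.vector(rbind(panel$forward_name, panel$reverse_name)),
    sequence = as.vector(rbind(panel$forward, panel$reverse)),
    size = as.vector(rbind(as.character(panel$expected_size), NA))
  )
  readr::write_tsv(long, path, na = "")
  invisible(path)
}

#' Write a tabular result to TSV or JSON
#'
#' Column order is preserved; [read_report()] restores an equal tibble.
#'
#' @param x A data frame of results.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- as.data.frame(x)
  if (format == "tsv") {
    readr::write_tsv(x, path)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report path.
#' @param format `"tsv"` or `"json"`.
#' @return A tibble.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    as_tibble(readr::read_tsv(path, col_types = readr::cols()))
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}
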