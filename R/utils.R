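# Internal helpers shared across modules.

# IUPAC alphabet accepted after normalization; '-' is the only gap character.
SCAR_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-")
SCAR_BASES <- c("A", "C", "G", "T")

scar_abort <- function(message, class, ...) {
  abort(message, class = c(class, "scar_error"), ...)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the IUPAC alphabet. Gaps (`-`) are
#' preserved.
#'
#' @param x Character vector of DNA strings (5'->3').
#' @return Character vector of the same length, each string reverse
#'   complemented.
#' @examples
#' dna_revcomp("AAACGT")
#' @export
dna_revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# sequence tibble -> character matrix (rows = records, cols = alignment cols)
seq_matrix <- function(seqs) {
  stopifnot(is.data.frame(seqs), "seq" %in% names(seqs))
  m <- do.call(rbind, strsplit(seqs$seq, "", fixed = TRUE))
  rownames(m) <- seqs$id
  m
}

check_aligned <- function(seqs, arg = "seqs") {
  len <- nchar(seqs$seq)
  if (length(unique(len)) > 1) {
    scar_abort(
      sprintf("%s is not a valid alignment: sequence lengths differ (%s)",
              arg, paste(unique(len), collapse = ", ")),
      class = "scar_alignment_shape"
    )
  }
  invisible(seqs)
}

check_taxon_column <- function(seqs) {
  if (!"taxon" %in% names(seqs) || anyNA(seqs$taxon)) {
    scar_abort("every sequence needs a taxon label (see `join_taxa()`)",
               class = "scar_partition")
  }
  invisible(seqs)
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# sample() without the length-1 surprise
resample <- function(x, size) x[sample.int(length(x), size)]

modal_value <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  as.integer(names(tab)[1])
}

# majority base per column among the given rows; gaps win a column only if
# they are the majority state. Ties resolved alphabetically for determinism.
consensus_chars <- function(mat) {
  apply(mat, 2, function(col) {
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1]
  })
}
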