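#' Progressive multiple alignment for near-identical barcode sequences
#'
#' Aligns a set of unaligned sequences by progressive merging: pairwise
#' global (Needleman-Wunsch, affine gaps) similarity scores pick the closest
#' pair first, then each remaining sequence (closest first) is aligned
#' against the running profile consensus and merged, inserting gap columns
#' where needed. The pairwise dynamic program is Biostrings'
#' `pairwiseAlignment()`. Output is deterministic for a fixed input order and
#' parameter set, and removing the gaps from any output row restores the
#' corresponding input sequence.
#'
#' This is intended for panels of near-identical barcode sequences (for which
#' any sane scoring gives the same alignment), not for deeply diverged sets.
#'
#' @param seqs Tibble with `id`, `seq` (and optionally `taxon`); at least two
#'   records. Gap characters in the input are stripped first.
#' @param match,mismatch Match score and mismatch penalty.
#' @param gap_open,gap_extend Gap opening / extension penalties (negative).
#' @return The input tibble with `seq` replaced by aligned rows of equal
#'   length, rows in input order.
#' @export
align_progressive <- function(seqs, match = 1, mismatch = -1,
                              gap_open = -5, gap_extend = -1) {
  if (nrow(seqs) < 2) {
    scar_abort("progressive alignment needs at least 2 sequences",
               class = "scar_degenerate_input")
  }
  raw <- ungap(seqs$seq)
  n <- length(raw)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  go <- abs(gap_open)
  ge <- abs(gap_extend)

  pair_aln <- function(pattern, subject) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
      type = "global", substitutionMatrix = submat,
      gapOpening = go, gapExtension = ge
    )
    list(p = as.character(Biostrings::alignedPattern(pa)),
         s = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa))
  }

  # guide order: best-scoring pair first, then nearest remaining sequence
  score <- matrix(-Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      score[i, j] <- score[j, i] <- pair_aln(raw[i], raw[j])$score
    }
  }
  first <- which(score == max(score), arr.ind = TRUE)
  first <- first[order(first[, 1], first[, 2]), , drop = FALSE][1, ]
  in_profile <- c(first[[1]], first[[2]])

  seed <- pair_aln(raw[first[[1]]], raw[first[[2]]])
  profile <- rbind(strsplit(seed$p, "")[[1]], strsplit(seed$s, "")[[1]])

  remaining <- setdiff(seq_len(n), in_profile)
  while (length(remaining) > 0) {
    sims <- vapply(remaining, function(k) mean(score[k, in_profile]), numeric(1))
    k <- remaining[order(-sims, remaining)][1]

    # every profile column is represented by its majority non-gap base, so
    # minority-insertion columns are not collapsed and re-opened downstream
    cons <- apply(profile, 2, function(col) {
      col <- col[col != "-"]
      if (length(col) == 0) return("N")
      tab <- table(col)
      names(tab)[order(-tab, names(tab))][1]
    })
    keep <- rep(TRUE, length(cons))
    cons_str <- paste(cons, collapse = "")
    aln <- pair_aln(raw[k], cons_str)
    pch <- strsplit(aln$p, "")[[1]]
    sch <- strsplit(aln$s, "")[[1]]

    # map aligned consensus positions back to profile columns, inserting
    # all-gap columns where the new sequence required them
    prof_cols <- which(keep)
    cols <- vector("list", 0)
    jp <- 1                                   # next profile consensus column
    consumed <- 0                             # profile cols emitted so far
    gap_row <- rep("-", nrow(profile))
    for (col in seq_along(pch)) {
      if (sch[col] != "-") {
        target <- prof_cols[jp]
        while (consumed < target - 1) {       # non-consensus profile columns
          consumed <- consumed + 1
          cols[[length(cols) + 1]] <- c(profile[, consumed], "-")
        }
        consumed <- consumed + 1
        cols[[length(cols) + 1]] <- c(profile[, consumed], pch[col])
        jp <- jp + 1
      } else {                                # insertion relative to profile
        cols[[length(cols) + 1]] <- c(gap_row, pch[col])
      }
    }
    while (consumed < ncol(profile)) {        # trailing non-consensus columns
      consumed <- consumed + 1
      cols[[length(cols) + 1]] <- c(profile[, consumed], "-")
    }
    profile <- do.call(cbind, cols)
    in_profile <- c(in_profile, k)
    remaining <- setdiff(remaining, k)
  }

  aligned <- apply(profile, 1, paste, collapse = "")
  out <- seqs
  out$seq[in_profile] <- aligned
  check_aligned(out)
  out
}
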