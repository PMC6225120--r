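#' Transition/transversion counts between two aligned rows
#'
#' Sites where either row carries a gap or an IUPAC ambiguity code are
#' excluded (pairwise deletion). Transitions are A<->G and C<->T;
#' transversions are all other differing base pairs.
#'
#' @param a,b Equal-length aligned sequence strings.
#' @return A one-row tibble with `P` (transition proportion), `Q`
#'   (transversion proportion) and `L` (number of compared sites).
#' @examples
#' pairwise_counts("ACGT", "GCGT")
#' @export
pairwise_counts <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    scar_abort("aligned rows must have equal length", class = "scar_alignment_shape")
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca %in% SCAR_BASES & cb %in% SCAR_BASES
  L <- sum(ok)
  if (L == 0) {
    scar_abort("no comparable (gap/ambiguity-free) sites between rows",
               class = "scar_undefined_distance")
  }
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  purine <- c("A", "G")
  ts <- diff & ((ca %in% purine) == (cb %in% purine))
  tibble(P = sum(ts) / L, Q = sum(diff & !ts) / L, L = L)
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` in substitutions per site,
#' where `P` and `Q` are the observed transition and transversion
#' proportions. Saturated inputs (arguments of the logs non-positive) raise a
#' saturation error rather than returning `NaN`.
#'
#' @param P,Q Transition and transversion proportions (vectorised), or pass
#'   a [pairwise_counts()] row as `P` with `Q` missing.
#' @return Numeric vector of distances.
#' @examples
#' k2p_distance(0.1, 0.05)
#' @export
k2p_distance <- function(P, Q) {
  if (missing(Q) && is.data.frame(P)) {
    Q <- P$Q
    P <- P$P
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (any(w1 <= 0 | w2 <= 0)) {
    scar_abort("saturated site pattern: K2P distance undefined",
               class = "scar_saturation")
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' All-pairs K2P distance matrix for an alignment
#'
#' @param seqs Aligned sequence tibble (`id`, `seq`).
#' @return A symmetric numeric matrix with zero diagonal, dimnames = IDs.
#'   Pairs with no comparable sites or saturated divergence become `NA` with
#'   a warning.
#' @export
k2p_matrix <- function(seqs) {
  check_aligned(seqs)
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      dij <- tryCatch(
        k2p_distance(pairwise_counts(seqs$seq[i], seqs$seq[j])),
        scar_error = function(e) NA_real_
      )
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (anyNA(d)) warn("some pairs had undefined K2P distances (NA)")
  d
}

#' Per-taxon barcode variability summary
#'
#' For each taxon: the (modal) ungapped barcode length, the aligned length,
#' the mean and SD of K2P distances over within-taxon pairs and over pairs
#' crossing into the other (non-excluded) taxa, and the counts of
#' taxon-specific substitution sites and indel events from
#' [scan_diagnostic_sites()]. SD is reported as `NA` when fewer than two
#' pairs contribute; intra fields are `NA` for single-sample taxa.
#'
#' @param seqs Aligned sequence tibble with `id`, `taxon`, `seq`.
#' @param exclude_taxa Taxa (e.g. an outgroup) removed before summarising.
#' @return A tibble with one row per taxon.
#' @export
summarize_variability <- function(seqs, exclude_taxa = NULL) {
  check_aligned(seqs)
  check_taxon_column(seqs)
  seqs <- filter(seqs, !(.data$taxon %in% exclude_taxa))
  d <- k2p_matrix(seqs)
  taxa <- unique(seqs$taxon)
  counts <- diagnostic_counts(scan_diagnostic_sites(seqs))

  pair_stats <- function(vals) {
    if (length(vals) == 0) return(c(NA_real_, NA_real_))
    c(mean(vals), if (length(vals) >= 2) sd(vals) else NA_real_)
  }
  rows <- map(taxa, function(tx) {
    inside <- which(seqs$taxon == tx)
    outside <- which(seqs$taxon != tx)
    intra <- if (length(inside) >= 2) d[inside, inside][upper.tri(d[inside, inside])] else numeric(0)
    inter <- as.vector(d[inside, outside, drop = FALSE])
    is_ <- pair_stats(intra)
    it_ <- pair_stats(inter)
    cnt <- counts[counts$taxon == tx, ]
    tibble(
      taxon = tx,
      n_samples = length(inside),
      its_length_bp = modal_value(nchar(ungap(seqs$seq[inside]))),
      aligned_length_bp = nchar(seqs$seq[1]),
      intra_mean = is_[1], intra_sd = is_[2],
      inter_mean = it_[1], inter_sd = it_[2],
      n_indel_events = cnt$n_indel_events,
      n_specific_substitutions = cnt$n_substitution_sites
    )
  })
  bind_rows(rows)
}
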