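#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper over [ape::nj()]: validates the matrix, clamps the
#' occasional small negative branch-length estimate to zero, and returns the
#' unrooted `phylo` object.
#'
#' @param d Symmetric numeric distance matrix with zero diagonal and row
#'   names; at least 3 taxa.
#' @return An unrooted `phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) {
    scar_abort("neighbor-joining needs at least 3 taxa",
               class = "scar_degenerate_input")
  }
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
    scar_abort("distance matrix must be symmetric with zero diagonal",
               class = "scar_format")
  }
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Does the tip set form one side of a bipartition of the (unrooted) tree?
is_clade <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) scar_abort("tips not in tree", class = "scar_partition")
  n <- length(tree$tip.label)
  if (length(idx) %in% c(1L, n)) return(TRUE)
  target <- sort(idx)
  anti <- sort(setdiff(seq_len(n), idx))
  parts <- ape::prop.part(tree)
  any(map_lgl(parts, function(p) {
    p <- sort(p)
    identical(p, target) || identical(p, anti)
  }))
}

#' Monophyly of each taxon with bootstrap support
#'
#' Builds the K2P neighbor-joining tree of the alignment and asks, per
#' taxon, whether its samples form one side of a bipartition (clade on the
#' unrooted tree). Support is the percentage of `n_replicates` trees, built
#' from alignments resampled column-wise with replacement, in which the
#' clade is recovered. Single-sample taxa are trivially monophyletic with
#' support 100. A panel with no pairwise divergence at all (a star tree)
#' returns `NA` monophyly.
#'
#' @param seqs Aligned sequence tibble with `id`, `taxon`, `seq`.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; results are deterministic for a fixed seed.
#' @param outgroup Taxa kept in the tree but not themselves evaluated.
#' @return Tibble `taxon`, `n_samples`, `is_monophyletic`, `support`.
#' @export
monophyly_support <- function(seqs, n_replicates = 100, seed = 1,
                              outgroup = NULL) {
  check_aligned(seqs)
  check_taxon_column(seqs)
  stopifnot(n_replicates >= 1)
  taxa <- setdiff(unique(seqs$taxon), outgroup)

  d <- suppressWarnings(k2p_matrix(seqs))
  star <- all(d[!is.na(d)] == 0)
  multi <- map_int(taxa, function(tx) sum(seqs$taxon == tx)) > 1L

  point <- rep(NA, length(taxa))
  if (!star && !anyNA(d)) {
    tree <- nj_tree(d)
    point <- map_lgl(taxa, function(tx) is_clade(tree, seqs$id[seqs$taxon == tx]))
  }
  point[!multi] <- TRUE

  nc <- nchar(seqs$seq[1])
  mat <- seq_matrix(seqs)
  hits <- setNames(rep(0L, length(taxa)), taxa)
  n_eff <- 0L
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (!star) {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(nc, nc, replace = TRUE)
      rep_seqs <- tibble(id = seqs$id,
                         seq = apply(mat[, cols, drop = FALSE], 1, paste, collapse = ""))
      db <- suppressWarnings(k2p_matrix(rep_seqs))
      if (anyNA(db)) next
      treeb <- nj_tree(db)
      n_eff <- n_eff + 1L
      for (tx in taxa) {
        if (is_clade(treeb, seqs$id[seqs$taxon == tx])) hits[tx] <- hits[tx] + 1L
      }
    }
  }
  support <- if (star || n_eff == 0) rep(NA_real_, length(taxa)) else
    100 * as.numeric(hits[taxa]) / n_eff
  support[!multi] <- 100
  if (star) point <- ifelse(multi, NA, TRUE)
  tibble(taxon = taxa,
         n_samples = map_int(taxa, function(tx) sum(seqs$taxon == tx)),
         is_monophyletic = as.logical(point),
         support = support)
}
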