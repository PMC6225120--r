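#' Configuration for the synthetic barcode panel generator
#'
#' Defaults emulate a small nuclear-ribosomal-spacer barcode study of three
#' closely related species: 15 near-identical sequences (7 + 4 + 4 samples)
#' over a 690-column alignment, 18/10/16 fixed species-specific
#' substitutions, one 1-bp species-exclusive insertion in the third taxon,
#' and rare intra-species polymorphism. Two conserved landing zones,
#' mirroring the ITS1 and ITS2 spacers flanking the 5.8S gene, each receive
#' at least three of the taxon's planted substitutions so that
#' species-specific primers can be anchored on either side of a short
#' amplicon.
#'
#' @param n_taxa Number of in-group taxa.
#' @param samples_per_taxon Integer vector (recycled) of samples per taxon.
#' @param base_length Alignment width in columns.
#' @param n_substitutions Planted fixed substitutions per taxon (recycled).
#' @param indel_lengths List (per taxon) of planted insertion lengths;
#'   each insertion is exclusive to its taxon (all other taxa gapped).
#' @param polymorphism_rate Per-site probability of a private intra-taxon
#'   polymorphism, in `[0, 1)`. Polymorphisms never land on planted columns,
#'   each alignment column hosts at most one, and single-sample taxa get
#'   none (a private variant in a one-sample taxon would be
#'   indistinguishable from a fixed species difference).
#' @param zone_forward,zone_reverse 0-based half-open column intervals of
#'   the two landing zones.
#' @param min_zone_sites Planted substitutions guaranteed inside each zone
#'   (per taxon, capped by `n_substitutions`).
#' @param taxon_names Optional taxon labels.
#' @param seed Integer seed; generation is byte-deterministic given it.
#' @return A `scar_panel_config` list.
#' @export
panel_config <- function(n_taxa = 3, samples_per_taxon = c(7, 4, 4),
                         base_length = 690,
                         n_substitutions = c(18, 10, 16),
                         indel_lengths = list(integer(0), integer(0), 1L),
                         polymorphism_rate = 0.001,
                         zone_forward = c(140, 240),
                         zone_reverse = c(380, 480),
                         min_zone_sites = 3,
                         taxon_names = NULL, seed = 1) {
  samples_per_taxon <- rep_len(samples_per_taxon, n_taxa)
  n_substitutions <- rep_len(n_substitutions, n_taxa)
  indel_lengths <- rep_len(indel_lengths, n_taxa)
  if (is.null(taxon_names)) taxon_names <- paste0("sp", LETTERS[seq_len(n_taxa)])
  stopifnot(polymorphism_rate >= 0, polymorphism_rate < 1,
            zone_forward[2] <= base_length, zone_reverse[2] <= base_length,
            zone_forward[2] <= zone_reverse[1])
  total <- sum(n_substitutions) + sum(lengths(indel_lengths)) +
    sum(unlist(indel_lengths))
  if (total >= base_length / 2) {
    scar_abort("requested planted features exceed what the sequence length can hold",
               class = "scar_config")
  }
  structure(list(n_taxa = n_taxa, samples_per_taxon = samples_per_taxon,
                 base_length = base_length, n_substitutions = n_substitutions,
                 indel_lengths = indel_lengths,
                 polymorphism_rate = polymorphism_rate,
                 zone_forward = zone_forward, zone_reverse = zone_reverse,
                 min_zone_sites = min_zone_sites,
                 taxon_names = taxon_names, seed = seed),
            class = "scar_panel_config")
}

#' Generate a synthetic barcode panel with planted ground truth
#'
#' Draws a uniform-random ancestral sequence, plants per-taxon fixed
#' substitutions (transitions with probability 0.5, exercising both the
#' transition and transversion channels of the K2P model) and taxon-
#' exclusive insertion runs, then adds private intra-taxon polymorphisms.
#' Planted features never overlap, so [scan_diagnostic_sites()] on the
#' emitted alignment recovers the truth exactly for panels of three or more
#' taxa.
#'
#' @param config A [panel_config()].
#' @return A `scar_panel_sim` list: `$aligned` and `$unaligned` sequence
#'   tibbles (`id`, `taxon`, `seq`), `$partition` (`id`, `taxon`), `$truth`
#'   (ancestral sequence, planted `sites` tibble with 0-based columns, and
#'   `polymorphisms` tibble), and `$config`.
#' @export
simulate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "scar_panel_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  W <- config$base_length
  taxa <- config$taxon_names
  anc <- sample(SCAR_BASES, W, replace = TRUE)
  zoneF <- (config$zone_forward[1] + 1):config$zone_forward[2]
  zoneR <- (config$zone_reverse[1] + 1):config$zone_reverse[2]
  used <- rep(FALSE, W)

  # taxon-exclusive insertion runs, outside the landing zones, separated by
  # at least one free column so distinct runs never merge
  indels <- list()
  for (t in seq_along(taxa)) {
    for (len in config$indel_lengths[[t]]) {
      free <- !used
      free[c(zoneF, zoneR)] <- FALSE
      ok_start <- which(vapply(seq_len(W - len - 1), function(s)
        all(free[s:(s + len + 1)]), logical(1)))
      if (length(ok_start) == 0) {
        scar_abort("no room left to plant an indel run", class = "scar_config")
      }
      s <- resample(ok_start, 1) + 1L           # keep a free spacer column left
      used[(s - 1):(s + len)] <- TRUE         # run plus one spacer each side
      indels[[length(indels) + 1]] <- list(taxon_i = t, start = s, len = len)
    }
  }
  indel_cols_of <- function(t) {
    unlist(map(indels, function(x)
      if (x$taxon_i == t) x$start:(x$start + x$len - 1) else integer(0)))
  }

  # planted fixed substitutions: at least min_zone_sites in each zone
  transversion <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  sub_cols <- vector("list", length(taxa))
  sub_states <- vector("list", length(taxa))
  for (t in seq_along(taxa)) {
    n <- config$n_substitutions[t]
    nz <- min(config$min_zone_sites, n %/% 2)
    pickF <- resample(zoneF[!used[zoneF]], min(nz, n, sum(!used[zoneF])))
    used[pickF] <- TRUE
    pickR <- resample(zoneR[!used[zoneR]], min(nz, max(n - length(pickF), 0), sum(!used[zoneR])))
    used[pickR] <- TRUE
    rest <- integer(0)
    n_rest <- n - length(pickF) - length(pickR)
    if (n_rest > 0) {
      rest <- resample(which(!used), n_rest)
      used[rest] <- TRUE
    }
    cols <- sort(c(pickF, pickR, rest))
    states <- vapply(cols, function(j) {
      if (stats::runif(1) < 0.5) transition[[anc[j]]]
      else sample(transversion[[anc[j]]], 1)
    }, character(1))
    sub_cols[[t]] <- cols
    sub_states[[t]] <- states
  }

  # per-taxon consensus rows
  cons <- map(seq_along(taxa), function(t) {
    row <- anc
    row[sub_cols[[t]]] <- sub_states[[t]]
    for (x in indels) {
      if (x$taxon_i != t) row[x$start:(x$start + x$len - 1)] <- "-"
    }
    row
  })

  # samples with private polymorphisms (only in taxa with >= 2 samples;
  # each alignment column hosts at most one polymorphism panel-wide)
  planted <- used
  avail <- which(!planted)
  ids <- character(0); tx_of <- character(0); seqs <- character(0)
  poly <- list()
  for (t in seq_along(taxa)) {
    for (k in seq_len(config$samples_per_taxon[t])) {
      row <- cons[[t]]
      id <- sprintf("%s_%02d", taxa[t], k)
      if (config$samples_per_taxon[t] >= 2 && config$polymorphism_rate > 0) {
        n_poly <- stats::rbinom(1, length(avail), config$polymorphism_rate)
        if (n_poly > 0) {
          cols <- resample(avail, min(n_poly, length(avail)))
          avail <- setdiff(avail, cols)
          for (j in cols) {
            row[j] <- sample(setdiff(SCAR_BASES, row[j]), 1)
            poly[[length(poly) + 1]] <- tibble(id = id, column = j - 1L,
                                               base = row[j])
          }
        }
      }
      ids <- c(ids, id); tx_of <- c(tx_of, taxa[t])
      seqs <- c(seqs, paste(row, collapse = ""))
    }
  }

  aligned <- tibble(id = ids, taxon = tx_of, seq = seqs)
  truth_sites <- bind_rows(
    bind_rows(map(seq_along(taxa), function(t) {
      if (length(sub_cols[[t]]) == 0) return(NULL)
      tibble(taxon = taxa[t], column = sub_cols[[t]] - 1L, length = 1L,
             kind = "substitution", state = sub_states[[t]])
    })),
    bind_rows(map(indels, function(x)
      tibble(taxon = taxa[x$taxon_i], column = x$start - 1L,
             length = x$len, kind = "indel",
             state = paste(anc[x$start:(x$start + x$len - 1)], collapse = ""))))
  )
  if (nrow(truth_sites) == 0) {
    truth_sites <- tibble(taxon = character(), column = integer(),
                          length = integer(), kind = character(),
                          state = character())
  }
  structure(list(
    aligned = aligned,
    unaligned = mutate(aligned, seq = ungap(.data$seq)),
    partition = select(aligned, "id", "taxon"),
    truth = list(ancestral = paste(anc, collapse = ""),
                 sites = arrange(truth_sites, match(.data$taxon, taxa), .data$column),
                 polymorphisms = if (length(poly) > 0) bind_rows(poly) else
                   tibble(id = character(), column = integer(), base = character())),
    config = config
  ), class = "scar_panel_sim")
}

#' Write a simulated panel to disk
#'
#' Emits `panel_aligned.fasta`, `panel_unaligned.fasta`, `samples.tsv` and
#' `truth.json` under `dir`.
#'
#' @param sim A `scar_panel_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$aligned, file.path(dir, "panel_aligned.fasta"))
  write_fasta(sim$unaligned, file.path(dir, "panel_unaligned.fasta"))
  readr::write_tsv(sim$partition, file.path(dir, "samples.tsv"))
  jsonlite::write_json(
    list(ancestral = sim$truth$ancestral, sites = sim$truth$sites,
         polymorphisms = sim$truth$polymorphisms),
    file.path(dir, "truth.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
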