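planted_panel <- function(...) simulate_panel(panel_config(...))

test_that("planted substitutions are recovered for exactly the right taxon", {
  sim <- planted_panel(seed = 31, n_substitutions = c(5, 0, 0),
                       indel_lengths = list(integer(0)),
                       polymorphism_rate = 0)
  diag <- scan_diagnostic_sites(sim$aligned)
  counts <- diagnostic_counts(diag)
  expect_equal(counts$n_substitution_sites, c(5L, 0L, 0L))
  expect_equal(counts$n_indel_events, c(0L, 0L, 0L))
  truth <- sim$truth$sites
  found <- tidy(diag)
  expect_setequal(found$column[found$taxon == "spA"],
                  truth$column[truth$taxon == "spA"])
  expect_equal(found$target_state[order(found$column)],
               truth$state[order(truth$column)])
})

test_that("an intra-taxon polymorphic column is never diagnostic", {
  seqs <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    taxon = c("A", "A", "B", "B"),
    seq = c("AAGT", "ATGT", "ACGA", "ACGA")
  )
  # column 1 (0-based): A fixed 'A'... actually polymorphic A/T in taxon A
  diag <- scan_diagnostic_sites(seqs)
  found <- tidy(diag)
  expect_false(1L %in% found$column[found$taxon == "A"])
  # column 3 is fixed 'A' in B and 'T' in A: diagnostic for both taxa
  expect_true(3L %in% found$column[found$taxon == "B"])
  expect_true(3L %in% found$column[found$taxon == "A"])
})

test_that("ambiguity codes disqualify a column for every taxon", {
  seqs <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    taxon = c("A", "A", "B", "B"),
    seq = c("TCGT", "TCGT", "ACGN", "ACGA")
  )
  found <- tidy(scan_diagnostic_sites(seqs))
  expect_false(3L %in% found$column)      # N anywhere kills the column
  expect_true(0L %in% found$column[found$taxon == "A"])
})

test_that("a multi-column exclusive gap run counts as one indel event", {
  seqs <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    taxon = c("A", "A", "B", "B"),
    seq = c("AC--GTAC", "AC--GTAC", "ACTTGTAC", "ACTTGTAC")
  )
  diag <- scan_diagnostic_sites(seqs)
  counts <- diagnostic_counts(diag)
  expect_equal(counts$n_indel_events[counts$taxon == "A"], 1L)
  expect_equal(counts$n_indel_events[counts$taxon == "B"], 1L)  # inverse polarity
  run <- tidy(diag) |> dplyr::filter(taxon == "A", kind == "indel")
  expect_equal(run$column, 2L)
  expect_equal(run$length, 2L)
  # per-column reporting via the flag
  percol <- tidy(scan_diagnostic_sites(seqs, collapse_indels = FALSE))
  expect_equal(sum(percol$kind == "indel" & percol$taxon == "A"), 2L)
})

test_that("excluded taxa (outgroup) do not constrain the scan", {
  sim <- planted_panel(seed = 32)
  out <- rbind(sim$aligned,
               tibble::tibble(id = "og1", taxon = "outgroup",
                              seq = paste(rep("A", 690), collapse = "")))
  counts <- diagnostic_counts(scan_diagnostic_sites(out, exclude_taxa = "outgroup"))
  expect_equal(counts$n_substitution_sites, c(18L, 10L, 16L))
  expect_false("outgroup" %in% counts$taxon)
})

test_that("counts are invariant to sample order", {
  sim <- planted_panel(seed = 33, polymorphism_rate = 0.004)
  c1 <- diagnostic_counts(scan_diagnostic_sites(sim$aligned))
  perm <- withr::with_seed(2, sample(nrow(sim$aligned)))
  c2 <- diagnostic_counts(scan_diagnostic_sites(sim$aligned[perm, ]))
  expect_equal(dplyr::arrange(c1, taxon), dplyr::arrange(c2, taxon))
})

test_that("adding a non-target sample carrying the target state removes only that site", {
  sim <- planted_panel(seed = 34, polymorphism_rate = 0)
  diag <- scan_diagnostic_sites(sim$aligned)
  sites_a <- tidy(diag) |> dplyr::filter(taxon == "spA", kind == "substitution")
  hit <- sites_a[1, ]
  intruder <- sim$aligned[sim$aligned$taxon == "spB", ][1, ]
  s <- strsplit(intruder$seq, "")[[1]]
  s[hit$column + 1] <- hit$target_state
  extra <- tibble::tibble(id = "intruder", taxon = "spB",
                          seq = paste(s, collapse = ""))
  diag2 <- scan_diagnostic_sites(rbind(sim$aligned, extra))
  sites_a2 <- tidy(diag2) |> dplyr::filter(taxon == "spA", kind == "substitution")
  expect_equal(nrow(sites_a2), nrow(sites_a) - 1)
  expect_setequal(sites_a2$column, setdiff(sites_a$column, hit$column))
})

test_that("diagnostic windows enumerate dense intervals like a sliding oracle", {
  sim <- planted_panel(seed = 35, n_substitutions = c(0, 0, 0),
                       indel_lengths = list(integer(0)))
  diag0 <- scan_diagnostic_sites(sim$aligned)
  expect_equal(nrow(diagnostic_windows(diag0)), 0)

  # synthetic diagnostics with sites at columns 10, 12, 30 for one taxon
  seqs <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    taxon = c("A", "A", "B", "B"),
    seq = c(strrep("A", 40), strrep("A", 40), strrep("A", 40), strrep("A", 40))
  )
  for (cl in c(10, 12, 30)) {
    substr(seqs$seq[1], cl + 1, cl + 1) <- "G"
    substr(seqs$seq[2], cl + 1, cl + 1) <- "G"
  }
  diag <- scan_diagnostic_sites(seqs)
  win <- diagnostic_windows(diag, min_sites = 2, window_len = 10)
  win_a <- win[win$taxon == "A", ]
  # oracle: enumerate every start and count sites inside
  sites <- c(10, 12, 30)
  oracle <- vapply(0:30, function(s) sum(sites >= s & sites < s + 10), integer(1))
  expect_equal(nrow(win_a), sum(oracle >= 2))
  expect_equal(win_a$start[1], min(which(oracle == max(oracle))) - 1)
  expect_equal(win_a$end[1] - win_a$start[1], 10)
  expect_true(all(diff(win_a$n_sites) <= 0))
})

test_that("windows rank a planted cluster first", {
  sim <- planted_panel(seed = 36)
  diag <- scan_diagnostic_sites(sim$aligned)
  win <- diagnostic_windows(diag, min_sites = 2, window_len = 101)
  for (tx in c("spA", "spB", "spC")) {
    top <- win[win$taxon == tx, ][1, ]
    truth_cols <- sim$truth$sites$column[sim$truth$sites$taxon == tx]
    expect_gte(sum(truth_cols >= top$start & truth_cols < top$end), 3)
  }
})
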