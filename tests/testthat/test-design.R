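design_fixture <- function(seed = 51, ...) {
  sim <- simulate_panel(panel_config(seed = seed, ...))
  diag <- scan_diagnostic_sites(sim$aligned)
  list(sim = sim, diag = diag,
       cands = dplyr::bind_rows(lapply(diag$taxa, function(tx)
         enumerate_candidates(sim$aligned, diag, tx))))
}

test_that("no diagnostic sites means no candidates, not an error", {
  fx <- design_fixture(seed = 52, n_substitutions = c(0, 5, 5),
                       indel_lengths = list(integer(0)))
  expect_equal(nrow(enumerate_candidates(fx$sim$aligned, fx$diag, "spA")), 0)
  expect_error(enumerate_candidates(fx$sim$aligned, fx$diag, "nope"),
               class = "scar_partition")
})

test_that("every candidate covers a diagnostic site with a 3'-anchor and obeys constraints", {
  fx <- design_fixture()
  cons <- design_constraints()
  expect_gt(nrow(fx$cands), 0)
  expect_true(all(fx$cands$n_diag >= 1))
  expect_true(all(fx$cands$anchor3))
  expect_true(all(fx$cands$length >= cons$primer_len[1] &
                    fx$cands$length <= cons$primer_len[2]))
  expect_true(all(fx$cands$tm >= cons$tm[1] & fx$cands$tm <= cons$tm[2]))
  expect_true(all(fx$cands$gc >= cons$gc[1] & fx$cands$gc <= cons$gc[2]))

  # each candidate occurs exactly once in its own taxon consensus, on its
  # designed strand
  prof <- scarmux:::taxon_profiles(fx$sim$aligned)
  for (i in sample(nrow(fx$cands), 25)) {
    cand <- fx$cands[i, ]
    cons_seq <- gsub("-", "", paste(prof[[cand$taxon]]$cons, collapse = ""))
    probe <- if (cand$strand == "+") cand$sequence else dna_revcomp(cand$sequence)
    hits <- gregexpr(probe, cons_seq, fixed = TRUE)[[1]]
    expect_equal(sum(hits > 0), 1)
  }
})

test_that("candidates carry enough mismatches against every non-target taxon", {
  fx <- design_fixture(seed = 53)
  prof <- scarmux:::taxon_profiles(fx$sim$aligned)
  for (i in sample(nrow(fx$cands), 20)) {
    cand <- fx$cands[i, ]
    idx <- (cand$start + 1):cand$end
    mine <- prof[[cand$taxon]]$cons[idx]
    for (other in setdiff(names(prof), cand$taxon)) {
      theirs <- prof[[other]]$cons[idx]
      expect_gte(sum(mine != theirs | theirs == "-"), 2)
    }
  }
})

test_that("planted-cluster forward candidates stay inside an annotated region", {
  fx0 <- design_fixture(seed = 54)
  constraints <- design_constraints(region_forward = c(140, 240),
                                    region_reverse = c(380, 480))
  cands <- enumerate_candidates(fx0$sim$aligned, fx0$diag, "spA", constraints)
  fwd <- cands[cands$strand == "+", ]
  expect_gt(nrow(fwd), 0)
  expect_true(all(fwd$start >= 140 & fwd$end <= 240))
  truth_cols <- fx0$sim$truth$sites$column[fx0$sim$truth$sites$taxon == "spA"]
  expect_true(all(vapply(seq_len(nrow(fwd)), function(i)
    any(truth_cols >= fwd$start[i] & truth_cols < fwd$end[i]), logical(1))))
})

test_that("shrinking the amplicon range never adds candidate pairs", {
  fx <- design_fixture(seed = 55)
  prof <- scarmux:::taxon_profiles(fx$sim$aligned)
  wide <- scarmux:::pair_candidates(
    dplyr::filter(fx$cands, taxon == "spA"), prof$spA,
    design_constraints(amplicon = c(100, 400)))
  narrow <- scarmux:::pair_candidates(
    dplyr::filter(fx$cands, taxon == "spA"), prof$spA,
    design_constraints(amplicon = c(150, 350)))
  expect_true(all(narrow$size %in% wide$size))
  expect_true(all(narrow$size >= 150 & narrow$size <= 350))
})

test_that("size-ladder choice maximizes the minimum gap with stated tie-breaks", {
  combos <- choose_panel_sizes(
    list(t1 = c(150, 200), t2 = c(200, 260), t3 = 320), min_gap = 40)
  expect_equal(unlist(combos[1, c("t1", "t2", "t3")]),
               c(t1 = 150, t2 = 260, t3 = 320))
  expect_equal(combos$min_gap[1], 60)
  # identical sizes everywhere: infeasible, reporting the best achievable gap
  err <- expect_error(
    choose_panel_sizes(list(a = 200, b = 200, c = 200), min_gap = 40),
    class = "scar_infeasible")
  expect_equal(err$best_gap, 0)
})

test_that("selected panels pass the in-silico closed loop on their own panel", {
  fx <- design_fixture(seed = 56)
  panel <- select_multiplex_panel(fx$cands, fx$sim$aligned)
  expect_s3_class(panel, "scar_panel")
  expect_equal(sort(panel$taxon), c("spA", "spB", "spC"))
  expect_gte(min(dist(panel$expected_size)), 40)
  expect_true(scarmux:::panel_verifies(panel, fx$sim$aligned))

  gel <- simulate_multiplex(fx$sim$unaligned, panel, pcr_params(max_mismatch = 0))
  lanes <- dplyr::left_join(gel$lanes, fx$sim$partition,
                            by = c(sample = "id"))
  for (i in seq_len(nrow(lanes))) {
    expect_equal(lanes$size[i],
                 panel$expected_size[panel$taxon == lanes$taxon[i]])
  }
  expect_setequal(unique(lanes$sample), fx$sim$partition$id)
})

test_that("panel selection reports infeasibility when sizes cannot be separated", {
  fx <- design_fixture(seed = 57)
  expect_error(
    select_multiplex_panel(fx$cands, fx$sim$aligned,
                           design_constraints(amplicon = c(150, 200),
                                              min_size_gap = 45)),
    class = "scar_infeasible")
})

test_that("tidy and glance summarise a panel", {
  panel <- angelica_panel()
  td <- tidy(panel)
  expect_equal(nrow(td), 6)
  expect_equal(td$primer[td$direction == "forward"],
               c("ADA-F", "AAN-F", "AJA-F"))
  gl <- glance(panel)
  expect_equal(gl$n_taxa, 3)
  expect_equal(gl$min_size_gap, 50)
})
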