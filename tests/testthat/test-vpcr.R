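test_that("binding sites respect mismatch budget and 3' clamp", {
  primer <- "ATCGGCGTCTTTCCA"
  tpl <- paste0("TTTTT", primer, "TTTTT")
  hit <- find_binding_sites(tpl, primer, pcr_params(max_mismatch = 0))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$strand, "+")
  expect_equal(hit$start, 6)
  expect_equal(hit$mismatches, 0)

  # one mismatch at the 3'-terminal base: rejected by the clamp even with budget
  tpl2 <- paste0("TTTTT", "ATCGGCGTCTTTCCG", "TTTTT")
  expect_equal(nrow(find_binding_sites(tpl2, primer, pcr_params(max_mismatch = 2))), 0)
  # the same mismatch away from the clamp is tolerated
  tpl3 <- paste0("TTTTT", "ATAGGCGTCTTTCCA", "TTTTT")
  hit3 <- find_binding_sites(tpl3, primer, pcr_params(max_mismatch = 2))
  expect_equal(hit3$mismatches, 1)
  # and not when the budget is zero
  expect_equal(nrow(find_binding_sites(tpl3, primer, pcr_params(max_mismatch = 0))), 0)
})

test_that("minus-strand sites equal plus-strand sites on the reverse complement", {
  withr::with_seed(8, {
    tpl <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  })
  primer <- substr(dna_revcomp(tpl), 50, 70)   # embeds revcomp(primer) in tpl
  hit <- find_binding_sites(tpl, primer, pcr_params(max_mismatch = 0))
  expect_equal(hit$strand, "-")
  mirror <- find_binding_sites(dna_revcomp(tpl), primer, pcr_params(max_mismatch = 0))
  expect_equal(mirror$strand, "+")
  expect_equal(hit$start, nchar(tpl) - mirror$end + 1)
})

test_that("mismatch budget is monotone and long primers give empty results", {
  tpl <- strrep("ACGT", 30)
  primer <- "ACGTACGTACGTACGTACGT"
  for (m in 0:2) {
    s0 <- find_binding_sites(tpl, primer, pcr_params(max_mismatch = m))
    s1 <- find_binding_sites(tpl, primer, pcr_params(max_mismatch = m + 1))
    key0 <- paste(s0$strand, s0$start)
    key1 <- paste(s1$strand, s1$start)
    expect_true(all(key0 %in% key1))
  }
  expect_equal(nrow(find_binding_sites("ACGT", primer)), 0)
})

test_that("a constructed pair template yields one product of the designed size", {
  panel <- angelica_panel()
  aan <- panel[panel$taxon == "A_anomala", ]
  tpl <- pair_template(aan$forward, aan$reverse, spacer_len = 215, seed = 3,
                       screen = panel)
  expect_equal(nchar(tpl), 22 + 215 + 22)
  gel <- simulate_multiplex(tibble::tibble(id = "syn", seq = tpl), panel,
                            pcr_params(max_mismatch = 0))
  expect_equal(gel$lanes, tibble::tibble(sample = "syn", size = 259L, count = 1L))
  # the amplicon substring carries the primers at its ends
  amp <- gel$amplicons
  frag <- substr(tpl, amp$start + 1, amp$end)
  expect_equal(nchar(frag), amp$size)
  expect_equal(substr(frag, 1, 22), aan$forward)
  expect_equal(substr(frag, nchar(frag) - 21, nchar(frag)),
               dna_revcomp(aan$reverse))
})

test_that("lanes are strand-symmetric and mixtures are band unions", {
  panel <- angelica_panel()
  t1 <- pair_template(panel$forward[1], panel$reverse[1], spacer_len = 156,
                      seed = 4, screen = panel)   # 156 + 43 = 199 bp product
  t2 <- pair_template(panel$forward[3], panel$reverse[3], spacer_len = 256,
                      seed = 5, screen = panel)   # 256 + 44 = 300 bp product
  single <- simulate_multiplex(
    tibble::tibble(id = c("s1", "s2"), seq = c(t1, t2)), panel, pcr_params(0))
  expect_equal(single$lanes$size, c(199L, 300L))

  mixed <- simulate_multiplex(
    tibble::tibble(id = c("t1", "t2"), sample = "mix", seq = c(t1, t2)),
    panel, pcr_params(0))
  expect_equal(mixed$lanes$size, c(199L, 300L))
  expect_equal(unique(mixed$lanes$sample), "mix")

  flipped <- simulate_multiplex(
    tibble::tibble(id = c("t1", "t2"), sample = "mix",
                   seq = dna_revcomp(c(t1, t2))), panel, pcr_params(0))
  expect_equal(flipped$lanes$size, mixed$lanes$size)

  none <- simulate_multiplex(tibble::tibble(id = "blank", seq = strrep("AC", 200)),
                             panel, pcr_params(0))
  expect_equal(nrow(none$lanes), 0)
  expect_equal(none$samples, "blank")
})

test_that("lane classification follows the detected-taxa semantics", {
  panel <- angelica_panel()
  params <- pcr_params()
  lane <- function(sample, sizes) tibble::tibble(sample = sample, size = sizes,
                                                 count = 1L)
  res <- classify_lane(lane("q1", 259L), panel, authentic = "A_dahurica", params)
  expect_equal(res$taxa_detected, "A_anomala")
  expect_equal(res$status, "adulterant_detected")

  expect_equal(classify_lane(lane("q2", integer(0)), panel, "A_dahurica",
                             params)$status, character(0))
  gel_empty <- structure(list(lanes = lane("x", integer(0))[0, ],
                              samples = "q2"), class = "scar_gel")
  expect_equal(classify_lane(gel_empty, panel, "A_dahurica", params)$status,
               "no_amplification")

  res_mix <- classify_lane(lane("q3", c(183L, 259L)), panel, "A_dahurica", params)
  expect_equal(res_mix$status, "mixed")
  expect_equal(res_mix$taxa_detected, "A_anomala,A_dahurica")

  expect_equal(classify_lane(lane("q4", 184L), panel, "A_dahurica",
                             params)$status, "authentic")   # within +-3 bp
  expect_equal(classify_lane(lane("q5", 500L), panel, "A_dahurica",
                             params)$status, "unexplained_bands")

  squeezed <- panel
  squeezed$expected_size <- c(183L, 186L, 309L)
  expect_error(classify_lane(lane("q6", 183L), squeezed, "A_dahurica", params),
               class = "scar_ambiguous_panel")
  expect_error(classify_lane(lane("q7", 183L), panel, "unknown_taxon", params),
               class = "scar_partition")
})

test_that("gel objects tidy, glance and plot", {
  panel <- angelica_panel()
  tpl <- pair_template(panel$forward[2], panel$reverse[2], spacer_len = 215,
                       seed = 6, screen = panel)
  gel <- simulate_multiplex(tibble::tibble(id = "s", seq = tpl), panel,
                            pcr_params(0))
  expect_equal(tidy(gel), gel$lanes)
  gl <- glance(gel)
  expect_equal(gl$n_samples, 1L)
  expect_equal(gl$n_bands, 1L)
  p <- autoplot(gel)
  expect_s3_class(p, "ggplot")
})
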