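test_that("a cleanly planted TSD is called with its target tetranucleotide", {
  set.seed(71)
  left <- paste0(r_dna(20), "TTTT", "ACGTACGTC")
  right <- paste0("ACGTACGTC", r_dna(20))
  call <- call_tsd(tibble::tibble(locus_id = "l1", left_flank = left,
                                  right_flank = right))
  expect_equal(call$status, "tsd")
  expect_equal(call$tsd_seq, "ACGTACGTC")
  expect_equal(call$tsd_len, 9L)
  expect_equal(call$left_slack, 0L)
  expect_equal(call$right_slack, 0L)
  expect_equal(call$target_tetranucleotide, "TTTT")
  expect_true(call$t_rich)
})

test_that("independent random flanks yield no TSD", {
  set.seed(72)
  for (i in 1:20) {
    l <- r_dna(50)
    r <- r_dna(50)
    call <- call_tsd(tibble::tibble(locus_id = "x", left_flank = l,
                                    right_flank = r))
    ora <- oracle_call_tsd(l, r)
    expect_equal(call$status, ora$status)
    expect_equal(call$tsd_len, as.integer(ora$tsd_len))
  }
  # shared-word-free by construction
  left <- strrep("AC", 25)
  right <- strrep("GT", 25)
  expect_equal(call_tsd(tibble::tibble(locus_id = "x", left_flank = left,
                                       right_flank = right))$status, "none")
})

test_that("long-TSD mode recovers a planted 443 bp duplication", {
  set.seed(73)
  tsd <- r_dna(443)
  left <- paste0(r_dna(60), tsd)
  right <- paste0(tsd, r_dna(60))
  call <- call_tsd(tibble::tibble(locus_id = "long", left_flank = left,
                                  right_flank = right), max_len = 500, slack = 3)
  expect_equal(call$status, "tsd")
  expect_equal(call$tsd_len, 443L)
  expect_equal(call$tsd_seq, tsd)
})

test_that("slack-shifted simulator loci match the brute-force TSD oracle", {
  set.seed(74)
  specs <- family_spec("fam", element_len = 250, structure = "none",
                       copy_number = 40, tsd_model = "uniform",
                       tsd_min = 7, tsd_max = 19, truncation_prob = 0.5)
  sim <- plant_copies(specs, genome_len = 30000, seed = 740, flank_len = 40)
  loci <- loci_from_truth(sim, jitter = 3)
  calls <- call_tsd(loci, min_len = 5, max_len = 25, slack = 3)
  for (i in seq_len(nrow(loci))) {
    ora <- oracle_call_tsd(loci$left_flank[i], loci$right_flank[i],
                           min_len = 5, max_len = 25, slack = 3)
    expect_equal(calls$status[i], ora$status)
    expect_equal(calls$tsd_len[i], as.integer(ora$tsd_len))
    expect_equal(calls$tsd_seq[i], ora$tsd_seq)
    expect_equal(calls$left_slack[i], as.integer(ora$ls))
    expect_equal(calls$right_slack[i], as.integer(ora$rs))
  }
  # the planted TSDs are recovered despite the jitter (slack >= jitter);
  # element or background bases leaking into a jittered flank can extend the
  # exact duplication, so the called TSD may contain the planted one
  keep <- sim$truth$tsd_len >= 5
  expect_true(all(calls$tsd_len[keep] >= sim$truth$tsd_len[keep]))
  expect_true(all(mapply(grepl, sim$truth$tsd_seq[keep],
                         calls$tsd_seq[keep], MoreArgs = list(fixed = TRUE))))
  expect_gt(mean(calls$tsd_len[keep] == sim$truth$tsd_len[keep]), 0.5)
})

test_that("T-richness is >= 3 of 4 T rule and rejects bad input", {
  expect_true(check_target_site("TTTT"))
  expect_true(all(check_target_site(c("TTTG", "TTTC", "TCTT", "TGTT"))))
  expect_false(check_target_site("TTAG"))
  expect_false(check_target_site("ACGT"))
  expect_error(check_target_site("TTT"), "exactly 4")
})

test_that("empty-site reconstruction removes exactly one TSD copy", {
  set.seed(75)
  # no-TSD target-specific junction restores the TTTTT run
  left <- paste0(strrep("AC", 16), "TTTT")
  right <- paste0("T", strrep("GA", 16))
  loci <- tibble::tibble(locus_id = "j", left_flank = left, right_flank = right)
  calls <- call_tsd(loci)
  expect_equal(calls$status, "none")
  es <- reconstruct_empty_site(loci, calls)
  expect_true(grepl("TTTTT", es$empty_site))
  expect_equal(nchar(es$empty_site), nchar(left) + nchar(right))

  # tsd case: length accounting
  tsd <- "ACGTACGTC"
  loci2 <- tibble::tibble(locus_id = "t",
                          left_flank = paste0(r_dna(30), tsd),
                          right_flank = paste0(tsd, r_dna(30)))
  calls2 <- call_tsd(loci2)
  es2 <- reconstruct_empty_site(loci2, calls2)
  expect_equal(nchar(es2$empty_site),
               nchar(loci2$left_flank) + nchar(loci2$right_flank) - 9L)

  # simulator round trip across statuses
  specs <- dplyr::bind_rows(
    family_spec("tsd", element_len = 200, structure = "none", copy_number = 15,
                tsd_model = "uniform", tsd_min = 7, tsd_max = 19),
    family_spec("no_tsd", element_len = 200, structure = "none",
                copy_number = 15, tsd_model = "none",
                target_preference_prob = 1)
  )
  sim <- plant_copies(specs, genome_len = 30000, seed = 750)
  loci3 <- loci_from_truth(sim)
  calls3 <- call_tsd(loci3)
  es3 <- reconstruct_empty_site(loci3, calls3)
  expect_equal(es3$empty_site, sim$truth$pre_insertion_locus)
})

test_that("family summaries tally fractions, histograms and targets", {
  set.seed(76)
  mk_locus <- function(i, tsd_len) {
    tsd <- if (tsd_len > 0) r_dna(tsd_len) else ""
    tibble::tibble(locus_id = sprintf("l%d", i),
                   left_flank = paste0(r_dna(40), tsd),
                   right_flank = paste0(tsd, r_dna(40)))
  }
  loci <- dplyr::bind_rows(
    lapply(1:7, function(i) mk_locus(i, sample(7:19, 1))),
    lapply(8:10, function(i) mk_locus(i, 0))
  )
  fam <- summarize_family(loci, family_id = "toy")
  expect_equal(fam$n_loci, 10L)
  expect_equal(fam$n_tsd, 7L)
  expect_equal(fam$tsd_fraction, 0.7)
  expect_equal(sum(fam$tsd_length_histogram[[1]]$n), fam$n_tsd)
  expect_equal(sum(fam$target_counts[[1]]$n), 10L)

  # invariant under locus reordering
  fam2 <- summarize_family(loci[sample(10), ], family_id = "toy")
  expect_equal(fam2$tsd_fraction, fam$tsd_fraction)
  expect_equal(dplyr::arrange(fam2$tsd_length_histogram[[1]], tsd_len),
               dplyr::arrange(fam$tsd_length_histogram[[1]], tsd_len))

  single <- summarize_family(mk_locus(99, 0))
  expect_equal(single$tsd_fraction, 0)
  expect_equal(nrow(single$tsd_length_histogram[[1]]), 0L)
})

test_that("simulated family fraction converges to the generating probability", {
  spec <- family_spec("fam", element_len = 150, structure = "none",
                      copy_number = 150, tsd_model = "uniform",
                      tsd_min = 7, tsd_max = 19, tsd_prob = 0.7)
  sim <- plant_copies(spec, genome_len = 80000, seed = 761)
  fam <- summarize_family(loci_from_truth(sim), family_id = "fam")
  # within the 95% binomial interval of p = 0.7 at n = 150
  half <- 1.96 * sqrt(0.7 * 0.3 / 150)
  expect_lt(abs(fam$tsd_fraction - 0.7), half + 1e-9)
  # and within 3 binomial standard deviations across further seeds
  for (s in c(762, 763)) {
    sim_s <- plant_copies(spec, genome_len = 80000, seed = s)
    f_s <- summarize_family(loci_from_truth(sim_s))
    expect_lt(abs(f_s$tsd_fraction - 0.7), 3 * sqrt(0.7 * 0.3 / 150))
  }
})

test_that("truncation profiles report coverage and intact fractions", {
  full <- tibble::tibble(copy_id = sprintf("c%d", 1:5), start = 1L, end = 300L)
  tp <- truncation_profile(full, consensus_len = 300)
  expect_equal(tp$five_prime_intact_fraction, 1)
  expect_equal(tp$three_prime_intact_fraction, 1)
  expect_true(all(tp$coverage == 5L))
  expect_equal(glance(tp)$n_copies, 5L)
  expect_equal(nrow(tidy(tp)), 300L)

  half <- tibble::tibble(copy_id = sprintf("c%d", 1:5), start = 151L, end = 300L)
  tp2 <- truncation_profile(half, consensus_len = 300)
  expect_equal(tp2$five_prime_intact_fraction, 0)
  expect_equal(tp2$three_prime_intact_fraction, 1)

  expect_error(truncation_profile(
    tibble::tibble(copy_id = "c", start = 0L, end = 10L), 300), "out of range")
})

test_that("geometric 5'-truncation gives monotone non-decreasing coverage", {
  set.seed(77)
  L <- 400L
  starts <- pmin(1L + stats::rgeom(60, 1 / 120), L - 50L)
  aligns <- tibble::tibble(copy_id = sprintf("c%d", 1:60),
                           start = as.integer(starts), end = L)
  tp <- truncation_profile(aligns, consensus_len = L)
  expect_true(all(diff(tp$coverage) >= 0L))
  expect_equal(tp$three_prime_intact_fraction, 1)
  expect_lt(tp$five_prime_intact_fraction, 1)
})
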