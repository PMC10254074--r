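d5 <- tiny_design(5)
m5 <- full_mask(d5, len = 10000)

test_that("the defining haploid pass case is accepted", {
  v <- make_site(d5, pos = 100, alt_by = c(prog_01 = 12))
  res <- find_denovo_candidates(v, m5, d5)
  expect_equal(nrow(res), 1)
  expect_equal(res$status, "accepted")
  expect_equal(res$carrier, "prog_01")
  expect_equal(res$alt_fraction, 1)
})

test_that("each rejection carries its first failing reason in fixed order", {
  # partial fraction: 11 of 12 reads support the alternative
  v_part <- make_site(d5, pos = 100, alt_by = c(prog_01 = 11))
  expect_equal(find_denovo_candidates(v_part, m5, d5)$reason, "partial_fraction")

  # shared between two progeny
  v_shared <- make_site(d5, pos = 200, alt_by = c(prog_01 = 12, prog_02 = 12))
  expect_equal(find_denovo_candidates(v_shared, m5, d5)$reason, "shared_carriers")

  # a single low-quality read in any other individual disqualifies
  v_lqa <- make_site(d5, pos = 300, alt_by = c(prog_01 = 10), dp = 10,
                     lqa_by = c(prog_04 = 1))
  expect_equal(find_denovo_candidates(v_lqa, m5, d5)$reason, "alt_in_others")

  # a low-quality read in a parent disqualifies too
  v_par <- make_site(d5, pos = 350, alt_by = c(prog_01 = 10), dp = 10,
                     lqa_by = c(par_f = 2))
  expect_equal(find_denovo_candidates(v_par, m5, d5)$reason, "alt_in_others")

  # non-callable dominates every other failure
  v_out <- make_site(d5, pos = 99999, alt_by = c(prog_01 = 11, prog_02 = 4))
  expect_equal(find_denovo_candidates(v_out, m5, d5)$reason, "not_callable")

  # a site with no progeny carrier (parent-only variant) is not a candidate
  v_parent <- make_site(d5, pos = 400, alt_by = c(par_m = 12))
  expect_equal(find_denovo_candidates(v_parent, m5, d5)$reason, "shared_carriers")
})

test_that("every variant receives exactly one status and counts add up", {
  v <- dplyr::bind_rows(
    make_site(d5, pos = 100, alt_by = c(prog_01 = 12)),
    make_site(d5, pos = 200, alt_by = c(prog_02 = 6)),
    make_site(d5, pos = 300, alt_by = c(prog_01 = 12, prog_03 = 12), alt = "G"),
    make_site(d5, pos = 99999, alt_by = c(prog_05 = 12))
  )
  res <- find_denovo_candidates(v, m5, d5)
  expect_equal(nrow(res), 4)
  expect_true(all(res$status %in% c("accepted", "rejected")))
  expect_equal(sum(res$status == "accepted") + sum(res$status == "rejected"), 4)
  expect_true(all(is.na(res$reason[res$status == "accepted"])))
  expect_true(all(!is.na(res$reason[res$status == "rejected"])))
})

test_that("records for individuals outside the design are rejected loudly", {
  v <- make_site(d5, pos = 100, alt_by = c(prog_01 = 12))
  v$individual[1] <- "intruder"
  expect_error(find_denovo_candidates(v, m5, d5), "intruder")
})

test_that("structural candidates add a cross-individual proximity veto", {
  # unique deletion; nearest other-individual SV is 5 kb away
  v_far <- dplyr::bind_rows(
    make_site(d5, pos = 1000, alt_by = c(prog_01 = 12), var_class = "SV"),
    make_site(d5, pos = 6000, alt_by = c(prog_02 = 12), var_class = "SV", alt = "G")
  )
  res_far <- filter_structural_candidates(v_far, proximity_window = 1000,
                                          design = d5, mask = m5)
  expect_equal(res_far$status[res_far$pos == 1000], "accepted")

  # another individual's SV 300 nt away vetoes the candidate
  v_near <- dplyr::bind_rows(
    make_site(d5, pos = 1000, alt_by = c(prog_01 = 12), var_class = "SV"),
    make_site(d5, pos = 1300, alt_by = c(prog_02 = 12), var_class = "SV", alt = "G")
  )
  res_near <- filter_structural_candidates(v_near, proximity_window = 1000,
                                           design = d5, mask = m5)
  expect_equal(res_near$reason[res_near$pos == 1000], "proximity")

  empty <- v_near[0, ]
  expect_equal(nrow(filter_structural_candidates(empty, design = d5, mask = m5)), 0)
  expect_error(filter_structural_candidates(v_near, proximity_window = -5,
                                            design = d5, mask = m5),
               "proximity_window")
})

test_that("stringency sweep reproduces the strict filter at threshold 1", {
  v <- dplyr::bind_rows(
    make_site(d5, pos = 100, alt_by = c(prog_01 = 12)),
    make_site(d5, pos = 200, alt_by = c(prog_02 = 19), dp = 20)  # 0.95 mosaic
  )
  sweep <- sensitivity_sweep(v, m5, d5, thresholds = c(0.9, 1.0))
  expect_equal(sweep$n_accepted[sweep$threshold == 1.0],
               sum(find_denovo_candidates(v, m5, d5)$status == "accepted"))
  # the 0.95 mosaic is counted at 0.9 but not at 1.0
  expect_equal(sweep$n_accepted[sweep$threshold == 0.9], 2)
  expect_equal(sweep$n_accepted[sweep$threshold == 1.0], 1)
  expect_error(sensitivity_sweep(v, m5, d5, thresholds = 0), "thresholds")
})

test_that("relaxing stringency recovers nothing on clean data", {
  sim <- simulate_pedigree(clean_config(seed = 21))
  mask <- callable_mask_strict(sim$tracks, min_depth = 10)
  sweep <- sensitivity_sweep(sim$variants, mask, sim$design,
                             thresholds = c(0.9, 1.0))
  expect_equal(sweep$n_accepted[1], sweep$n_accepted[2])
})

test_that("clean synthetic data gives perfect recall at callable sites", {
  sim <- simulate_pedigree(clean_config(seed = 33))
  mask <- callable_mask_strict(sim$tracks, min_depth = 10)
  res <- find_denovo_candidates(sim$variants, mask, sim$design)
  acc <- res[res$status == "accepted", ]
  tm <- sim$truth$true_mutations
  tm$callable <- positions_callable(mask, tm$chrom, tm$pos)
  # precision: every accepted site is a true mutation with the right carrier
  hit <- dplyr::inner_join(acc, tm,
                           by = c("chrom", "pos", "ref", "alt",
                                  carrier = "individual"))
  expect_equal(nrow(hit), nrow(acc))
  # recall: every callable true mutation is accepted
  expect_equal(nrow(acc), sum(tm$callable))
})

test_that("no confounder class survives the filters (truth-table check)", {
  sim <- simulate_pedigree(synth_config(genome_length = 2e5, n_chromosomes = 4,
                                        n_progeny = 8,
                                        n_standing_variants = 60,
                                        somatic_rate = 5e-5,
                                        artifact_rate = 5e-3,
                                        error_rate = 5e-5, seed = 44))
  mask <- callable_mask_strict(sim$tracks, min_depth = 10)
  acc <- find_denovo_candidates(sim$variants, mask, sim$design)
  acc <- acc[acc$status == "accepted", ]
  confounders <- c(
    paste(sim$truth$standing_variants$chrom, sim$truth$standing_variants$pos),
    paste(sim$truth$somatic_events$chrom, sim$truth$somatic_events$pos),
    paste(sim$truth$artifacts$chrom, sim$truth$artifacts$pos)
  )
  expect_equal(sum(paste(acc$chrom, acc$pos) %in% confounders), 0)
})
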