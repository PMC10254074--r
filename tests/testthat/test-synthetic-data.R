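test_that("config validation names the offending field", {
  expect_error(synth_config(repeat_fraction = 1.2), "repeat_fraction")
  expect_error(synth_config(mu_true = -1), "mu_true")
  expect_error(synth_config(genome_length = 100, n_chromosomes = 7),
               "divide evenly")
  expect_error(synth_config(n_progeny = 0), "n_progeny")
})

test_that("reference partitions the genome into equal chromosomes", {
  ref <- generate_reference(synth_config(genome_length = 280000,
                                         n_chromosomes = 28))
  expect_length(ref$sequences, 28)
  expect_true(all(Biostrings::width(ref$sequences) == 10000))
})

test_that("repeat annotation tracks repeat_fraction", {
  ref0 <- generate_reference(synth_config(genome_length = 100000,
                                          n_chromosomes = 10,
                                          repeat_fraction = 0))
  expect_equal(nrow(ref0$repeats), 0)

  ref <- generate_reference(synth_config(genome_length = 100000,
                                         n_chromosomes = 10,
                                         repeat_fraction = 0.2))
  expect_equal(sum(ref$repeats$end - ref$repeats$start), 20000)
  expect_true(all(ref$repeats$start >= 0 & ref$repeats$end <= 10000))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(genome_length = 5e4, n_chromosomes = 2, n_progeny = 4,
                      seed = 11)
  a <- simulate_pedigree(cfg)
  b <- simulate_pedigree(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
})

test_that("mu_true = 0 yields no true mutations and excessive mu is refused", {
  sim <- simulate_pedigree(synth_config(genome_length = 5e4, n_chromosomes = 2,
                                        n_progeny = 4, mu_true = 0, seed = 2))
  expect_equal(nrow(sim$truth$true_mutations), 0)
  expect_error(
    simulate_pedigree(synth_config(genome_length = 1e4, n_chromosomes = 2,
                                   n_progeny = 30, mu_true = 0.5)),
    "mu_true"
  )
})

test_that("every true mutation is recoverable in principle", {
  sim <- simulate_pedigree(synth_config(genome_length = 1e5, n_chromosomes = 4,
                                        n_progeny = 6, mu_true = 2e-4, seed = 5))
  tm <- sim$truth$true_mutations
  expect_gt(nrow(tm), 0)
  v <- dplyr::semi_join(sim$variants, tm, by = c("chrom", "pos"))
  carrier_rows <- dplyr::inner_join(
    v, tm, by = c("chrom", "pos", "individual", "ref", "alt"))
  expect_equal(nrow(carrier_rows), nrow(tm))
  expect_true(all(carrier_rows$alt_depth == carrier_rows$total_depth))
  non_carriers <- dplyr::anti_join(v, tm[, c("chrom", "pos", "individual")],
                                   by = c("chrom", "pos", "individual"))
  expect_true(all(non_carriers$alt_depth == 0))
  expect_true(all(non_carriers$lq_alt_count == 0))
})

test_that("confounders are separable by construction", {
  sim <- simulate_pedigree(synth_config(genome_length = 1e5, n_chromosomes = 4,
                                        n_progeny = 8,
                                        n_standing_variants = 50,
                                        somatic_rate = 5e-5,
                                        artifact_rate = 5e-3, seed = 9))
  tr <- sim$truth
  expect_gt(nrow(tr$standing_variants), 0)
  expect_gt(nrow(tr$somatic_events), 0)
  expect_gt(nrow(tr$artifacts), 0)
  # standing variants always have >= 2 carriers (parent + >= 1 progeny)
  expect_true(all(lengths(strsplit(tr$standing_variants$carriers, ",")) >= 2))
  # somatic support is strictly partial wherever depth allows a call
  som <- dplyr::inner_join(sim$variants, tr$somatic_events,
                           by = c("chrom", "pos", "individual"))
  callable_som <- som[som$total_depth >= 2, ]
  expect_true(all(callable_som$alt_depth >= 1 &
                    callable_som$alt_depth < callable_som$total_depth))
  # artifact sites carry only low-quality support, in >= 2 individuals
  art <- dplyr::semi_join(sim$variants, tr$artifacts, by = c("chrom", "pos"))
  expect_true(all(art$alt_depth == 0))
  n_lq <- art |> dplyr::group_by(chrom, pos) |>
    dplyr::summarise(k = sum(lq_alt_count > 0), .groups = "drop")
  expect_true(all(n_lq$k >= 2))
  # all special site classes occupy distinct positions
  keys <- c(
    paste(tr$true_mutations$chrom, tr$true_mutations$pos),
    paste(tr$standing_variants$chrom, tr$standing_variants$pos),
    paste(tr$somatic_events$chrom, tr$somatic_events$pos),
    paste(tr$artifacts$chrom, tr$artifacts$pos)
  )
  expect_equal(anyDuplicated(keys), 0)
})

test_that("true-mutation counts match the Poisson expectation over seeds", {
  # scaled-down Monte Carlo: lambda = genome x I x mu = 10
  cfg0 <- synth_config(genome_length = 1e5, n_chromosomes = 4, n_progeny = 10,
                       mu_true = 1e-5, n_standing_variants = 0,
                       somatic_rate = 0, artifact_rate = 0, error_rate = 0,
                       repeat_fraction = 0, wcd_probability = 0)
  ref <- generate_reference(cfg0)
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(s) {
    cfg <- synth_config(genome_length = 1e5, n_chromosomes = 4, n_progeny = 10,
                        mu_true = 1e-5, n_standing_variants = 0,
                        somatic_rate = 0, artifact_rate = 0, error_rate = 0,
                        repeat_fraction = 0, wcd_probability = 0, seed = 1000 + s)
    nrow(simulate_pedigree(cfg, ref)$truth$true_mutations)
  }, numeric(1))
  lambda <- 1e5 * 10 * 1e-5
  se <- sqrt(lambda / n_rep)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("forced duplications double coverage on the affected chromosomes", {
  cfg <- synth_config(genome_length = 5e5, n_chromosomes = 5, n_progeny = 4,
                      wcd_probability = 1, seed = 13)
  sim <- simulate_pedigree(cfg)
  dup <- sim$truth$duplicated_chromosomes
  expect_setequal(unique(dup$individual), sim$design$progeny)
  for (ind in sim$design$progeny) {
    tr <- sim$tracks[sim$tracks$individual == ind, ]
    dup_ch <- dup$chromosome[dup$individual == ind]
    m_dup <- mean(tr$depth[tr$chrom %in% dup_ch])
    m_other <- mean(tr$depth[!tr$chrom %in% dup_ch])
    expect_true(m_dup / m_other > 1.9 && m_dup / m_other < 2.1)
  }
})

test_that("simulated expression injects the requested fold", {
  expr <- simulate_expression_table(200, sprintf("chr%02d", 1:5), "chr03",
                                    fold = 2, sigma = 0, seed = 3)
  wide <- expr |>
    dplyr::group_by(gene, chromosome, strain) |>
    dplyr::summarise(m = mean(tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = strain, values_from = m)
  on_dup <- wide$chromosome == "chr03"
  expect_true(all(abs(wide$test[on_dup] / wide$control[on_dup] - 2) < 1e-12))
  expect_true(all(abs(wide$test[!on_dup] / wide$control[!on_dup] - 1) < 1e-12))
})
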