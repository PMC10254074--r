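test_that("windowed coverage computes length-weighted means and terminal windows", {
  tr <- tibble::tibble(individual = "a", chrom = "chr1",
                       start = 0L, end = 12000L, depth = 30L)
  wc <- window_coverage(tr, window_size = 5000)
  expect_equal(wc$end - wc$start, c(5000, 5000, 2000))
  expect_true(all(wc$mean_depth == 30))

  # depth 30 on half a window and 10 on the other half averages to 20
  tr2 <- tibble::tibble(individual = "a", chrom = "chr1",
                        start = c(0L, 2500L), end = c(2500L, 5000L),
                        depth = c(30L, 10L))
  wc2 <- window_coverage(tr2, window_size = 5000)
  expect_equal(wc2$mean_depth, 20)

  expect_warning(window_coverage(tr, window_size = 5000, exclude = "ghost"),
                 "ghost")
})

test_that("duplication calls follow the ratio thresholds", {
  # windows engineered to give ratios 2.0, 1.9, 1.9, 2.1 over a baseline of 10
  mk <- function(chrom, depth, n = 20) {
    tibble::tibble(individual = "x", chrom = chrom,
                   start = (0:(n - 1)) * 5000L, end = (1:n) * 5000L,
                   depth = as.integer(depth))
  }
  tr <- dplyr::bind_rows(
    mk("c14", 20), mk("c16", 19), mk("c18", 19), mk("c19", 21),
    mk("b1", 10), mk("b2", 10), mk("b3", 10), mk("b4", 10), mk("b5", 10)
  )
  calls <- detect_duplications(window_coverage(tr))
  dup <- calls[calls$chromosome %in% c("c14", "c16", "c18", "c19"), ]
  expect_true(all(dup$status == "duplicated"))
  expect_equal(dup$ratio[order(dup$chromosome)], c(2.0, 1.9, 1.9, 2.1))
  expect_true(all(calls$status[calls$chromosome %in% paste0("b", 1:5)] == "normal"))

  # a 1.8 chromosome falls in the ambiguous band and is not counted
  tr18 <- dplyr::bind_rows(mk("c19", 18), mk("b1", 10), mk("b2", 10), mk("b3", 10))
  calls18 <- detect_duplications(window_coverage(tr18))
  expect_equal(calls18$status[calls18$chromosome == "c19"], "ambiguous")

  expect_error(detect_duplications(window_coverage(mk("only", 10))),
               "two chromosomes")
})

test_that("depth ratios are invariant to global scaling of a track", {
  set.seed(5)
  tr <- dplyr::bind_rows(lapply(sprintf("c%d", 1:4), function(ch) {
    tibble::tibble(individual = "x", chrom = ch,
                   start = (0:39) * 5000L, end = (1:40) * 5000L,
                   depth = rpois(40, if (ch == "c2") 60 else 30))
  }))
  calls <- detect_duplications(window_coverage(tr))
  tr3 <- dplyr::mutate(tr, depth = depth * 3L)
  calls3 <- detect_duplications(window_coverage(tr3))
  expect_equal(calls$ratio, calls3$ratio, tolerance = 1e-12)
})

test_that("simulated 2x chromosomes are called duplicated near ratio 2", {
  set.seed(23)
  # 6 chromosomes x 80 windows at depth 20; one drawn at 2x
  tr <- dplyr::bind_rows(lapply(sprintf("c%d", 1:6), function(ch) {
    tibble::tibble(individual = "x", chrom = ch,
                   start = (0:79) * 5000L, end = (1:80) * 5000L,
                   depth = rpois(80, if (ch == "c3") 40 else 20))
  }))
  calls <- detect_duplications(window_coverage(tr))
  c3 <- calls[calls$chromosome == "c3", ]
  expect_equal(c3$status, "duplicated")
  expect_true(c3$ratio >= 1.9 && c3$ratio <= 2.1)
  expect_true(all(calls$status[calls$chromosome != "c3"] == "normal"))
})

test_that("windows partition every chromosome exactly", {
  sim <- simulate_pedigree(synth_config(genome_length = 1e5, n_chromosomes = 4,
                                        n_progeny = 2, seed = 3))
  wc <- window_coverage(sim$tracks[sim$tracks$individual == "prog_01", ],
                        window_size = 5000)
  by_chrom <- wc |> dplyr::group_by(chrom) |>
    dplyr::summarise(total = sum(end - start), .groups = "drop")
  expect_true(all(by_chrom$total == 25000))
  expect_true(all(wc$start %% 5000 == 0))
})

test_that("dosage fold recovers engineered expression ratios", {
  # identical expression on both strains: fold exactly 1
  expr_flat <- simulate_expression_table(100, sprintf("c%d", 1:4), "c2",
                                         fold = 1, sigma = 0, seed = 2)
  expect_equal(dosage_ratio(expr_flat, "c2")$fold, 1, tolerance = 1e-12)

  # exact 2x on duplicated-chromosome genes
  expr2 <- simulate_expression_table(100, sprintf("c%d", 1:4), "c2",
                                     fold = 2, sigma = 0, seed = 2)
  expect_equal(dosage_ratio(expr2, "c2")$fold, 2, tolerance = 1e-12)

  expect_error(dosage_ratio(expr2, "absent_chrom"), "partition")
  expect_error(dosage_ratio(expr2[, -5], "c2"), "tpm")
})

test_that("dosage fold is recovered under replicate noise (Monte Carlo)", {
  folds <- vapply(1:20, function(s) {
    expr <- simulate_expression_table(500, sprintf("c%d", 1:10),
                                      c("c2", "c7"), fold = 1.7,
                                      sigma = 0.2, seed = 100 + s)
    dosage_ratio(expr, c("c2", "c7"))$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) - 1.7), 0.05)
})

test_that("the TPM filter removes weakly expressed genes from both partitions", {
  expr <- simulate_expression_table(300, sprintf("c%d", 1:4), "c2",
                                    fold = 2, sigma = 0.1,
                                    base_meanlog = log(2), base_sdlog = 1.5,
                                    seed = 6)
  d <- dosage_ratio(expr, "c2", tpm_min = 1)
  expect_true(all(d$per_gene$mean_test > 1 & d$per_gene$mean_control > 1))
  expect_lt(nrow(d$per_gene), 300)
})
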