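#' Configuration for the synthetic haploid pedigree generator
#'
#' Bundles every parameter of the synthetic data generator with validation.
#' The defaults describe a small but fully featured study: a 1-Mb genome in
#' 20 equal chromosomes, one diploid cross sequenced as two haploid parents,
#' 30 meiotic haploid progeny at ~30x depth, a true mutation rate of
#' 1e-5 per site per generation, plus every confounder class the de novo
#' filters must reject (standing variants, somatic mosaics, repeat-driven
#' mapping artifacts, stray low-quality reads) and rare whole-chromosome
#' duplications.
#'
#' @param genome_length Total genome size in nucleotides; must divide evenly
#'   into `n_chromosomes` contiguous chromosomes.
#' @param n_chromosomes Number of equally sized chromosomes.
#' @param repeat_fraction Proportion of each chromosome flagged as repetitive
#'   (one contiguous block per chromosome); mapping artifacts are placed only
#'   in these regions.
#' @param n_progeny Number of haploid meiotic progeny (the I of the rate
#'   denominator).
#' @param mu_true True de novo mutation rate, mutations per site per
#'   generation.
#' @param mean_depth Mean sequencing depth per site (reads).
#' @param depth_dropout_fraction Proportion of the genome falling in shared
#'   low-coverage blocks (depth drawn at `dropout_depth_mean`), emulating
#'   unmappable regions. Dropout blocks are shared across individuals so the
#'   callable intersection stays realistic.
#' @param error_rate Per-site, per-individual probability of a stray
#'   low-quality alternative read (mapping/sequencing noise).
#' @param n_standing_variants Number of variants heterozygous in the parent
#'   pair (one haploid parent carries the alternative allele; each progeny
#'   inherits it with probability 1/2).
#' @param somatic_rate Per-site, per-progeny rate of somatic mosaic variants
#'   with alternative-allele fraction strictly inside (0, 1).
#' @param artifact_rate Per-repeat-base rate of artifact sites carrying 1-2
#'   low-quality alternative reads in two or more individuals.
#' @param wcd_probability Probability, per progeny, of one whole-chromosome
#'   duplication event duplicating a small random subset of chromosomes
#'   (depth doubles on those chromosomes).
#' @param depth_tile Granularity, in nucleotides, at which depth is drawn:
#'   one Poisson draw per tile. `depth_tile = 1` gives independent per-site
#'   draws; the default of 100 keeps interval-format coverage tracks compact
#'   while preserving every threshold-crossing behaviour the pipeline
#'   consumes.
#' @param dropout_depth_mean Mean depth inside dropout blocks.
#' @param seed Integer seed; a fixed seed makes the generated dataset
#'   byte-identical across runs.
#'
#' @return A validated list of class `synth_config`.
#' @examples
#' synth_config(seed = 1)
#' @export
synth_config <- function(genome_length = 1e6,
                         n_chromosomes = 20,
                         repeat_fraction = 0.05,
                         n_progeny = 30,
                         mu_true = 1e-5,
                         mean_depth = 30,
                         depth_dropout_fraction = 0.1,
                         error_rate = 1e-5,
                         n_standing_variants = 100,
                         somatic_rate = 1e-6,
                         artifact_rate = 5e-4,
                         wcd_probability = 1 / 30,
                         depth_tile = 100,
                         dropout_depth_mean = 2,
                         seed = 1L) {
  check_number(genome_length, "genome_length", min = 1, integer = TRUE)
  check_number(n_chromosomes, "n_chromosomes", min = 1, integer = TRUE)
  if (genome_length < n_chromosomes) {
    abort("`genome_length` must be at least `n_chromosomes`")
  }
  if (genome_length %% n_chromosomes != 0) {
    abort(sprintf(
      "`genome_length` (%d) must divide evenly into `n_chromosomes` (%d) blocks",
      genome_length, n_chromosomes
    ))
  }
  check_number(repeat_fraction, "repeat_fraction", min = 0, max = 1)
  check_number(n_progeny, "n_progeny", min = 1, integer = TRUE)
  check_number(mu_true, "mu_true", min = 0, max = 1)
  check_number(mean_depth, "mean_depth", min = 0)
  check_number(depth_dropout_fraction, "depth_dropout_fraction", min = 0, max = 1)
  check_number(error_rate, "error_rate", min = 0, max = 1)
  check_number(n_standing_variants, "n_standing_variants", min = 0, integer = TRUE)
  check_number(somatic_rate, "somatic_rate", min = 0, max = 1)
  check_number(artifact_rate, "artifact_rate", min = 0, max = 1)
  check_number(wcd_probability, "wcd_probability", min = 0, max = 1)
  check_number(depth_tile, "depth_tile", min = 1, integer = TRUE)
  check_number(dropout_depth_mean, "dropout_depth_mean", min = 0)
  check_number(seed, "seed", min = -.Machine$integer.max, max = .Machine$integer.max,
               integer = TRUE)

  structure(
    list(
      genome_length = as.integer(genome_length),
      n_chromosomes = as.integer(n_chromosomes),
      repeat_fraction = repeat_fraction,
      n_progeny = as.integer(n_progeny),
      mu_true = mu_true,
      mean_depth = mean_depth,
      depth_dropout_fraction = depth_dropout_fraction,
      error_rate = error_rate,
      n_standing_variants = as.integer(n_standing_variants),
      somatic_rate = somatic_rate,
      artifact_rate = artifact_rate,
      wcd_probability = wcd_probability,
      depth_tile = as.integer(depth_tile),
      dropout_depth_mean = dropout_depth_mean,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  genome   : %s nt in %d chromosomes (%.0f nt each)\n",
              format(x$genome_length, big.mark = ","), x$n_chromosomes,
              x$genome_length / x$n_chromosomes))
  cat(sprintf("  pedigree : 2 parents + %d haploid progeny, mu_true = %s\n",
              x$n_progeny, format_rate(x$mu_true)))
  cat(sprintf("  depth    : Poisson(%.0f) per %d-nt tile, %.0f%% dropout at mean %.1f\n",
              x$mean_depth, x$depth_tile, 100 * x$depth_dropout_fraction,
              x$dropout_depth_mean))
  cat(sprintf("  confound : %d standing, somatic %s, artifact %s, noise %s, WCD p = %.3f\n",
              x$n_standing_variants, format_rate(x$somatic_rate),
              format_rate(x$artifact_rate), format_rate(x$error_rate),
              x$wcd_probability))
  cat("  seed     :", x$seed, "\n")
  invisible(x)
}

# deterministic child seeds so sub-generators can be reordered without
# perturbing each other
derive_seeds <- function(seed, n = 8L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
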