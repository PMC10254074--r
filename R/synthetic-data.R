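#' Generate a synthetic reference genome with repeat annotation
#'
#' Builds a random nucleotide sequence partitioned into equal chromosomes and
#' marks one contiguous repeat block per chromosome so that repeat-driven
#' mapping artifacts can be placed realistically.
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_reference` with elements
#'   `sequences` (a named [Biostrings::DNAStringSet]), `repeats` (a tibble of
#'   0-based half-open intervals: chrom, start, end), `chrom_lengths`
#'   (named integer vector) and the `config` used.
#' @examples
#' ref <- generate_reference(synth_config(genome_length = 2000, n_chromosomes = 2))
#' names(ref$sequences)
#' @export
generate_reference <- function(config) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must be created with synth_config()")
  }
  seeds <- derive_seeds(config$seed)
  set.seed(seeds[1])

  chrom_len <- config$genome_length %/% config$n_chromosomes
  chroms <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  chrom_lengths <- setNames(rep(chrom_len, config$n_chromosomes), chroms)

  base_raw <- charToRaw("ACGT")
  seq_chr <- vapply(chroms, function(ch) {
    rawToChar(sample(base_raw, chrom_len, replace = TRUE))
  }, character(1))
  sequences <- Biostrings::DNAStringSet(seq_chr)

  if (config$repeat_fraction > 0) {
    rep_len <- round(config$repeat_fraction * chrom_len)
    rep_len <- max(1L, min(rep_len, chrom_len))
    starts <- vapply(chroms, function(ch) {
      sample.int(chrom_len - rep_len + 1L, 1L) - 1L
    }, integer(1))
    repeats <- tibble(chrom = chroms, start = as.integer(starts),
                      end = as.integer(starts + rep_len))
  } else {
    repeats <- tibble(chrom = character(), start = integer(), end = integer())
  }

  structure(
    list(sequences = sequences, repeats = repeats,
         chrom_lengths = chrom_lengths, config = config),
    class = "synthetic_reference"
  )
}

# map global 1-based positions to (chrom, pos) for equal-length chromosomes
global_to_chrom <- function(gpos, chroms, chrom_len) {
  idx <- (gpos - 1L) %/% chrom_len + 1L
  tibble(chrom = chroms[idx], pos = as.integer((gpos - 1L) %% chrom_len + 1L))
}

#' Simulate a sequenced haploid pedigree with known ground truth
#'
#' Generates the three artefacts the mutation-rate pipeline consumes — a
#' multi-sample variant table, per-individual coverage tracks, and a truth
#' table — for one diploid cross (sequenced as two haploid parents) and
#' `n_progeny` meiotic haploid offspring.
#'
#' The simulated signals are:
#' \itemize{
#'   \item true de novo mutations, each unique to one progeny with
#'     alternative reads equal to the total depth at the site (haploid
#'     germline expectation);
#'   \item standing variants carried by one parent and roughly half the
#'     progeny (always at least one progeny, so every standing variant is
#'     shared);
#'   \item somatic mosaic variants with alternative support strictly between
#'     1 and depth - 1 reads;
#'   \item repeat-region mapping artifacts: 1-2 low-quality alternative
#'     reads in two or more individuals, zero high-quality support;
#'   \item stray single-individual low-quality reads (sequencing noise);
#'   \item whole-chromosome duplications doubling depth on the affected
#'     chromosomes.
#' }
#' All special site classes occupy disjoint positions, so no confounder can
#' satisfy the full de novo acceptance criteria and the truth table is an
#' exact oracle. Depth is Poisson per `depth_tile` (see [synth_config()]);
#' dropout blocks are shared across individuals.
#'
#' @param config A [synth_config()].
#' @param reference A reference from [generate_reference()] built from a
#'   config that matches in every field except possibly `seed` (generated
#'   automatically if omitted). Allowing a seed mismatch lets replicate
#'   pedigrees share one genome, as repeated sequencing experiments on one
#'   organism would.
#' @return A list of class `pedigree_sim` with elements `variants` (long
#'   tibble: chrom, pos, ref, alt, var_class, individual, total_depth,
#'   alt_depth, lq_alt_count), `tracks` (tibble: individual, chrom, start,
#'   end, depth; 0-based half-open), `truth` (see Details), `design`
#'   (a [pedigree_design()]), `dropout` (tibble of dropout intervals),
#'   `reference` and `config`.
#' @examples
#' sim <- simulate_pedigree(synth_config(genome_length = 5e4, n_chromosomes = 2,
#'                                       n_progeny = 4, seed = 7))
#' nrow(sim$truth$true_mutations)
#' @export
simulate_pedigree <- function(config, reference = NULL) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must be created with synth_config()")
  }
  if (is.null(reference)) reference <- generate_reference(config)
  drop_seed <- function(x) x[setdiff(names(x), "seed")]
  if (!inherits(reference, "synthetic_reference") ||
      !identical(drop_seed(unclass(reference$config)), drop_seed(unclass(config)))) {
    abort("`reference` must come from generate_reference() on a matching `config`")
  }
  if (config$mu_true * config$n_progeny > 1) {
    abort("`mu_true` is too high: expected mutations per site across the pedigree exceeds 1")
  }

  seeds <- derive_seeds(config$seed)
  set.seed(seeds[2])

  G <- config$genome_length
  I <- config$n_progeny
  tile <- config$depth_tile
  chroms <- names(reference$chrom_lengths)
  chrom_len <- unname(reference$chrom_lengths[1])
  parents <- c("par_f", "par_m")
  progeny <- sprintf("prog_%02d", seq_len(I))
  individuals <- c(parents, progeny)
  n_ind <- length(individuals)
  design <- pedigree_design(parents, progeny, generations = 1L)

  ## ---- whole-chromosome duplications -------------------------------------
  dup_list <- lapply(progeny, function(p) {
    if (runif(1) < config$wcd_probability) {
      k <- sample.int(min(4L, config$n_chromosomes), 1L)
      sort(sample(chroms, k))
    } else character()
  })
  names(dup_list) <- progeny
  duplicated_chromosomes <- tibble(
    individual = rep(progeny, lengths(dup_list)),
    chromosome = unlist(dup_list, use.names = FALSE) %||% character()
  )

  ## ---- dropout blocks (shared across individuals, tile-aligned) ----------
  n_tiles <- as.integer(ceiling(chrom_len / tile))
  drop_tiles_per_chrom <- as.integer(round(config$depth_dropout_fraction * n_tiles))
  dropout <- purrr::map(chroms, function(ch) {
    if (drop_tiles_per_chrom == 0L) return(NULL)
    s <- sample.int(n_tiles - drop_tiles_per_chrom + 1L, 1L) - 1L
    tibble(chrom = ch, start = s * tile,
           end = min((s + drop_tiles_per_chrom) * tile, chrom_len))
  })
  dropout <- dplyr::bind_rows(dropout)
  if (nrow(dropout) == 0L) {
    dropout <- tibble(chrom = character(), start = integer(), end = integer())
  }

  ## ---- per-tile depth -----------------------------------------------------
  tile_starts <- (seq_len(n_tiles) - 1L) * tile
  tile_ends <- pmin(tile_starts + tile, chrom_len)
  depth_mats <- vector("list", length(chroms))
  names(depth_mats) <- chroms
  for (ch in chroms) {
    drop_row <- dropout[dropout$chrom == ch, ]
    in_drop <- if (nrow(drop_row)) {
      tile_starts >= drop_row$start[1] & tile_starts < drop_row$end[1]
    } else rep(FALSE, n_tiles)
    base_mean <- ifelse(in_drop, config$dropout_depth_mean, config$mean_depth)
    mat <- matrix(0L, nrow = n_tiles, ncol = n_ind,
                  dimnames = list(NULL, individuals))
    for (j in seq_len(n_ind)) {
      fac <- if (individuals[j] %in% progeny && ch %in% dup_list[[individuals[j]]]) 2 else 1
      mat[, j] <- rpois(n_tiles, fac * base_mean)
    }
    depth_mats[[ch]] <- mat
  }

  tracks <- purrr::map(chroms, function(ch) {
    mat <- depth_mats[[ch]]
    tibble(
      individual = rep(individuals, each = n_tiles),
      chrom = ch,
      start = rep(as.integer(tile_starts), n_ind),
      end = rep(as.integer(tile_ends), n_ind),
      depth = as.integer(mat)
    )
  })
  tracks <- dplyr::bind_rows(tracks)

  ## ---- choose disjoint positions for every special site class ------------
  n_true <- rpois(1, G * I * config$mu_true)
  n_somatic <- rpois(1, G * I * config$somatic_rate)
  n_noise <- rpois(1, G * n_ind * config$error_rate)
  n_standing <- config$n_standing_variants

  repeat_len <- sum(reference$repeats$end - reference$repeats$start)
  n_artifact <- if (repeat_len > 0) rpois(1, repeat_len * config$artifact_rate) else 0L

  art_gpos <- integer()
  if (n_artifact > 0) {
    # global positions uniform over the repeat blocks
    rep_tbl <- reference$repeats
    rep_tbl$g_off <- (match(rep_tbl$chrom, chroms) - 1L) * chrom_len
    widths <- rep_tbl$end - rep_tbl$start
    pick <- sample.int(length(widths), n_artifact, replace = TRUE, prob = widths)
    art_gpos <- rep_tbl$g_off[pick] + rep_tbl$start[pick] +
      sapply(widths[pick], function(w) sample.int(w, 1L))
    art_gpos <- unique(art_gpos)
    n_artifact <- length(art_gpos)
  }

  n_other <- n_true + n_standing + n_somatic + n_noise
  other_gpos <- integer()
  if (n_other > 0) {
    other_gpos <- sample.int(G, n_other)
    while (any(other_gpos %in% art_gpos) || anyDuplicated(other_gpos)) {
      other_gpos <- unique(other_gpos[!other_gpos %in% art_gpos])
      need <- n_other - length(other_gpos)
      other_gpos <- c(other_gpos, sample.int(G, need))
    }
  }

  take <- function(n) {
    out <- other_gpos[seq_len(n)]
    other_gpos <<- other_gpos[-seq_len(n)]
    out
  }
  gp_true <- if (n_true) take(n_true) else integer()
  gp_stand <- if (n_standing) take(n_standing) else integer()
  gp_som <- if (n_somatic) take(n_somatic) else integer()
  gp_noise <- if (n_noise) take(n_noise) else integer()

  seq_chr <- as.character(reference$sequences)
  make_sites <- function(gpos, class) {
    if (!length(gpos)) {
      return(tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), class = character()))
    }
    loc <- global_to_chrom(gpos, chroms, chrom_len)
    ref_base <- unname(substring(seq_chr[loc$chrom], loc$pos, loc$pos))
    alt_base <- vapply(ref_base, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1), USE.NAMES = FALSE)
    tibble(chrom = loc$chrom, pos = loc$pos, ref = ref_base, alt = alt_base,
           class = class)
  }

  sites_true <- make_sites(gp_true, "true")
  sites_true$carrier <- if (n_true) sample(progeny, n_true, replace = TRUE) else character()
  sites_stand <- make_sites(gp_stand, "standing")
  sites_som <- make_sites(gp_som, "somatic")
  sites_som$carrier <- if (n_somatic) sample(progeny, n_somatic, replace = TRUE) else character()
  sites_som$alt_fraction <- if (n_somatic) runif(n_somatic, 0.2, 0.8) else numeric()
  sites_noise <- make_sites(gp_noise, "noise")
  sites_noise$carrier <- if (n_noise) sample(individuals, n_noise, replace = TRUE) else character()
  sites_art <- make_sites(art_gpos, "artifact")

  # standing variants: one haploid parent + >=1 progeny (binomial 1/2 each)
  stand_carriers <- lapply(seq_len(n_standing), function(i) {
    par <- sample(parents, 1L)
    kids <- progeny[runif(I) < 0.5]
    while (length(kids) == 0L) kids <- progeny[runif(I) < 0.5]
    c(par, kids)
  })

  # artifact sites: 1-2 low-quality alt reads in 2-4 individuals
  art_affected <- lapply(seq_len(n_artifact), function(i) {
    sample(individuals, sample(2:4, 1L))
  })

  ## ---- assemble the long variant table ------------------------------------
  sites <- dplyr::bind_rows(
    sites_true |> dplyr::select("chrom", "pos", "ref", "alt", "class", "carrier"),
    sites_stand |> dplyr::mutate(carrier = NA_character_),
    sites_som |> dplyr::select("chrom", "pos", "ref", "alt", "class", "carrier",
                               "alt_fraction"),
    sites_art |> dplyr::mutate(carrier = NA_character_),
    sites_noise |> dplyr::select("chrom", "pos", "ref", "alt", "class", "carrier")
  )

  variants <- tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    var_class = character(), individual = character(),
    total_depth = integer(), alt_depth = integer(), lq_alt_count = integer()
  )

  if (nrow(sites) > 0) {
    n_sites <- nrow(sites)
    sites$site_id <- seq_len(n_sites)
    long <- sites[rep(seq_len(n_sites), each = n_ind), ]
    long$individual <- rep(individuals, times = n_sites)

    # depth lookup from the tile matrices
    long$tile <- (long$pos - 1L) %/% tile + 1L
    long$ind_idx <- match(long$individual, individuals)
    long$total_depth <- 0L
    for (ch in unique(long$chrom)) {
      sel <- long$chrom == ch
      long$total_depth[sel] <-
        depth_mats[[ch]][cbind(long$tile[sel], long$ind_idx[sel])]
    }

    long$alt_depth <- 0L
    long$lq_alt_count <- 0L

    # true mutations: carrier alt reads = total reads
    is_true_carrier <- long$class == "true" & long$individual == long$carrier
    long$alt_depth[is_true_carrier] <- long$total_depth[is_true_carrier]

    # standing variants: all carriers (haploid) at full alt fraction
    if (n_standing > 0) {
      stand_ids <- sites$site_id[sites$class == "standing"]
      stand_long <- tibble(
        site_id = rep(stand_ids, lengths(stand_carriers)),
        individual = unlist(stand_carriers)
      )
      key <- paste(long$site_id, long$individual)
      hit <- key %in% paste(stand_long$site_id, stand_long$individual)
      long$alt_depth[hit] <- long$total_depth[hit]
    }

    # somatic mosaics: binomial support clamped strictly inside (0, depth)
    is_som_carrier <- long$class == "somatic" & long$individual == long$carrier
    if (any(is_som_carrier)) {
      dp <- long$total_depth[is_som_carrier]
      f <- sites$alt_fraction[match(long$site_id[is_som_carrier], sites$site_id)]
      ad <- rbinom(length(dp), dp, f)
      ad <- ifelse(dp >= 2L, pmin(pmax(ad, 1L), dp - 1L), 0L)
      long$alt_depth[is_som_carrier] <- as.integer(ad)
    }

    # repeat artifacts: low-quality alt reads only
    if (n_artifact > 0) {
      art_ids <- sites$site_id[sites$class == "artifact"]
      art_long <- tibble(
        site_id = rep(art_ids, lengths(art_affected)),
        individual = unlist(art_affected)
      )
      key <- paste(long$site_id, long$individual)
      hit <- key %in% paste(art_long$site_id, art_long$individual)
      long$lq_alt_count[hit] <- sample(1:2, sum(hit), replace = TRUE)
    }

    # stray noise: one low-quality read in one individual
    is_noise <- long$class == "noise" & long$individual == long$carrier
    long$lq_alt_count[is_noise] <- 1L

    variants <- long |>
      dplyr::transmute(
        chrom = .data$chrom, pos = .data$pos, ref = .data$ref, alt = .data$alt,
        var_class = "SNV", individual = .data$individual,
        total_depth = .data$total_depth, alt_depth = .data$alt_depth,
        lq_alt_count = .data$lq_alt_count
      ) |>
      dplyr::arrange(.data$chrom, .data$pos, .data$individual)
  }

  truth <- structure(list(
    true_mutations = sites_true |>
      dplyr::select(individual = "carrier", "chrom", "pos", "ref", "alt") |>
      dplyr::arrange(.data$chrom, .data$pos),
    standing_variants = tibble(
      chrom = sites_stand$chrom, pos = sites_stand$pos,
      carriers = vapply(stand_carriers, paste, character(1), collapse = ",")
    ),
    somatic_events = sites_som |>
      dplyr::select(individual = "carrier", "chrom", "pos", "alt_fraction"),
    artifacts = tibble(
      chrom = sites_art$chrom, pos = sites_art$pos,
      individuals = vapply(art_affected, paste, character(1), collapse = ",")
    ),
    duplicated_chromosomes = duplicated_chromosomes
  ), class = "truth_table")

  structure(
    list(variants = variants, tracks = tracks, truth = truth, design = design,
         dropout = dropout, reference = reference, config = config),
    class = "pedigree_sim"
  )
}

#' @export
print.pedigree_sim <- function(x, ...) {
  cat("<pedigree_sim>\n")
  cat(sprintf("  genome    : %s nt, %d chromosomes\n",
              format(x$config$genome_length, big.mark = ","),
              x$config$n_chromosomes))
  cat(sprintf("  pedigree  : %d parents + %d progeny\n",
              length(x$design$parents), length(x$design$progeny)))
  cat(sprintf("  variants  : %d sites x %d individuals\n",
              nrow(dplyr::distinct(x$variants, .data$chrom, .data$pos, .data$alt)),
              length(design_individuals(x$design))))
  cat(sprintf("  truth     : %d true de novo, %d standing, %d somatic, %d artifact, %d duplicated chromosome(s)\n",
              nrow(x$truth$true_mutations), nrow(x$truth$standing_variants),
              nrow(x$truth$somatic_events), nrow(x$truth$artifacts),
              nrow(x$truth$duplicated_chromosomes)))
  invisible(x)
}

#' Simulate an expression (TPM) table around a chromosome-duplication event
#'
#' Generates a tidy gene-by-replicate TPM table for a duplicated strain
#' ("test") and an euploid sibling ("control"), with genes on the duplicated
#' chromosomes expressed `fold` times higher in the test strain and
#' multiplicative log-normal replicate noise. Used to validate the dosage
#' analysis against a known injected fold.
#'
#' @param n_genes Number of genes, assigned uniformly to `chromosomes`.
#' @param chromosomes Character vector of chromosome names.
#' @param duplicated_chromosomes Chromosomes duplicated in the test strain.
#' @param fold True expression fold for duplicated-chromosome genes.
#' @param n_replicates Replicates per strain.
#' @param sigma Log-normal replicate noise (sdlog).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline gene TPM.
#' @param seed Integer seed.
#' @return A tibble: gene, chromosome, strain ("test"/"control"),
#'   replicate, tpm.
#' @examples
#' simulate_expression_table(50, c("chr01", "chr02"), "chr02", fold = 2, seed = 1)
#' @export
simulate_expression_table <- function(n_genes = 500,
                                      chromosomes = sprintf("chr%02d", 1:20),
                                      duplicated_chromosomes = character(),
                                      fold = 2,
                                      n_replicates = 3,
                                      sigma = 0.2,
                                      base_meanlog = log(20),
                                      base_sdlog = 1,
                                      seed = 1L) {
  check_number(n_genes, "n_genes", min = 1, integer = TRUE)
  check_number(fold, "fold", min = 0)
  check_number(n_replicates, "n_replicates", min = 1, integer = TRUE)
  check_number(sigma, "sigma", min = 0)
  set.seed(seed)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  chrom <- sample(chromosomes, n_genes, replace = TRUE)
  base <- rlnorm(n_genes, base_meanlog, base_sdlog)
  dup <- chrom %in% duplicated_chromosomes
  grid <- tidyr::expand_grid(
    gene_idx = seq_len(n_genes),
    strain = c("test", "control"),
    replicate = seq_len(n_replicates)
  )
  mu <- base[grid$gene_idx] * ifelse(grid$strain == "test" & dup[grid$gene_idx], fold, 1)
  tibble(
    gene = genes[grid$gene_idx],
    chromosome = chrom[grid$gene_idx],
    strain = grid$strain,
    replicate = grid$replicate,
    tpm = mu * rlnorm(nrow(grid), 0, sigma)
  )
}
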