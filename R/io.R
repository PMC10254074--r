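# Readers and writers for the pipeline's on-disk interchange formats:
# FASTA (Biostrings), depth BED (0-based half-open), multi-sample VCF with a
# custom LQA FORMAT field for low-quality alternative read counts, and
# plain TSVs for truth tables and summaries.

#' Write and read per-individual depth tracks as BED-like TSV
#'
#' Columns: chrom, start, end, depth, individual; 0-based half-open
#' coordinates, no header (BED convention).
#'
#' @param tracks Coverage track tibble.
#' @param path Output/input file path.
#' @return `write_depth_bed()` returns `path` invisibly; `read_depth_bed()`
#'   returns the track tibble.
#' @export
write_depth_bed <- function(tracks, path) {
  validate_tracks(tracks)
  readr::write_tsv(
    tracks[, c("chrom", "start", "end", "depth", "individual")],
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_depth_bed
#' @export
read_depth_bed <- function(path) {
  readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "depth", "individual"),
    col_types = "ciiic", progress = FALSE
  )[, c("individual", "chrom", "start", "end", "depth")]
}

#' Write a callable mask as 3-column BED
#'
#' @param mask A `callable_mask`.
#' @param path Output path.
#' @export
write_callable_bed <- function(mask, path) {
  readr::write_tsv(as_tibble(mask)[, c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write a long variant table as a multi-sample VCF
#'
#' Produces a minimal VCF 4.2 file with one line per (chrom, pos, ref, alt)
#' and FORMAT `GT:DP:AD:LQA`, where AD is "ref,alt" and LQA is the count of
#' low-quality alternative reads (the field the "no alternative reads even
#' at low quality" criterion inspects). Haploid genotypes: 1 for any
#' individual with alternative support, else 0.
#'
#' @param variants Long variant table.
#' @param path Output path.
#' @param design A [pedigree_design()] fixing the sample column order.
#' @export
write_variants_vcf <- function(variants, path, design) {
  validate_variants(variants, design, include_checks = TRUE)
  ids <- design_individuals(design, include_checks = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplomu",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
    "##FORMAT=<ID=LQA,Number=1,Type=Integer,Description=\"Low-quality alternative read count\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  if (nrow(variants) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  wide <- variants |>
    dplyr::mutate(
      gt = sprintf("%d:%d:%d,%d:%d",
                   as.integer(.data$alt_depth > 0), .data$total_depth,
                   .data$total_depth - .data$alt_depth, .data$alt_depth,
                   .data$lq_alt_count),
      individual = factor(.data$individual, levels = ids)
    ) |>
    dplyr::select("chrom", "pos", "ref", "alt", "var_class", "individual", "gt") |>
    tidyr::pivot_wider(names_from = "individual", values_from = "gt") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  body <- apply(
    cbind(wide$chrom, wide$pos, ".", wide$ref, wide$alt, ".", "PASS",
          paste0("VC=", wide$var_class), "GT:DP:AD:LQA",
          as.matrix(wide[, ids, drop = FALSE])),
    1, paste, collapse = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into the long variant-table format
#'
#' Parses DP, AD and (if present) LQA FORMAT fields via \pkg{vcfR} and
#' returns one row per site per individual. The variant class is taken from
#' a `VC=` INFO key when present; otherwise SNVs and indels are inferred
#' from allele lengths.
#'
#' @param path VCF file path.
#' @return A long variant tibble (see [simulate_pedigree()]).
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), var_class = character(),
                  individual = character(), total_depth = integer(),
                  alt_depth = integer(), lq_alt_count = integer()))
  }
  fix <- as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  vc <- stringr::str_match(info, "VC=([^;]+)")[, 2]
  vc <- dplyr::coalesce(
    vc,
    dplyr::if_else(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1, "SNV", "indel")
  )
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  alt_d <- apply(ad, 2, function(x) {
    as.integer(vapply(strsplit(x, ","), function(p) p[2], character(1)))
  })
  lqa <- tryCatch(vcfR::extract.gt(v, "LQA", as.numeric = TRUE),
                  error = function(e) matrix(0, nrow(dp), ncol(dp),
                                             dimnames = dimnames(dp)))
  lqa[is.na(lqa)] <- 0
  samples <- colnames(dp)
  n_sites <- nrow(fix)
  tibble(
    chrom = rep(fix$CHROM, times = length(samples)),
    pos = rep(as.integer(fix$POS), times = length(samples)),
    ref = rep(fix$REF, times = length(samples)),
    alt = rep(fix$ALT, times = length(samples)),
    var_class = rep(vc, times = length(samples)),
    individual = rep(samples, each = n_sites),
    total_depth = as.integer(dp),
    alt_depth = as.integer(alt_d),
    lq_alt_count = as.integer(lqa)
  ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$individual)
}

#' Write every artefact of a simulated pedigree to a directory
#'
#' Writes the reference FASTA, the multi-sample VCF, the depth BED, the
#' repeat and dropout BEDs and the truth tables (TSV) so a simulated
#' dataset can be consumed by external tools or re-read later.
#'
#' @param sim A `pedigree_sim` from [simulate_pedigree()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pedigree_sim <- function(sim, dir) {
  if (!inherits(sim, "pedigree_sim")) abort("`sim` must be a pedigree_sim")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$reference$sequences,
                              file.path(dir, "reference.fasta"))
  write_variants_vcf(sim$variants, file.path(dir, "variants.vcf"), sim$design)
  write_depth_bed(sim$tracks, file.path(dir, "depth.bed"))
  readr::write_tsv(sim$reference$repeats, file.path(dir, "repeats.bed"),
                   col_names = FALSE)
  readr::write_tsv(sim$dropout, file.path(dir, "dropout.bed"), col_names = FALSE)
  for (nm in names(sim$truth)) {
    readr::write_tsv(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
  }
  invisible(dir)
}
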