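# Spike-in false-negative simulation: plant known mutations in the
# reference, regenerate detection input, rerun the filters and account for
# every miss.

#' Spike known mutations into a reference sequence
#'
#' Sets `n_mutations` positions within `[start, end]` of one chromosome to
#' `target_base`, skipping positions that already carry it. Placement is an
#' even grid by default (deterministic), or uniform random under `seed`.
#' The original bases are recorded so the edit is exactly reversible.
#'
#' @param reference A named [Biostrings::DNAStringSet], or a
#'   `synthetic_reference` from [generate_reference()].
#' @param chrom Chromosome name to modify.
#' @param n_mutations Number of sites to spike.
#' @param start,end 1-based inclusive bounds of the target region.
#' @param target_base The base every spiked site is set to (default "G").
#' @param placement "even" (default) or "random".
#' @param seed Seed for random placement.
#' @return A list with `reference` (modified DNAStringSet) and `spikes`
#'   (tibble: chrom, pos, original, target).
#' @examples
#' ref <- generate_reference(synth_config(genome_length = 2000, n_chromosomes = 2))
#' sp <- spike_mutations(ref, "chr01", 10, 1, 1000)
#' sp$spikes
#' @export
spike_mutations <- function(reference, chrom, n_mutations, start, end,
                            target_base = "G",
                            placement = c("even", "random"), seed = 1L) {
  placement <- match.arg(placement)
  if (inherits(reference, "synthetic_reference")) reference <- reference$sequences
  if (!methods::is(reference, "DNAStringSet")) {
    abort("`reference` must be a DNAStringSet or synthetic_reference")
  }
  if (!chrom %in% names(reference)) {
    abort(sprintf("chromosome %s not found in the reference", chrom))
  }
  check_number(n_mutations, "n_mutations", min = 0, integer = TRUE)
  check_number(start, "start", min = 1, integer = TRUE)
  check_number(end, "end", min = 1, integer = TRUE)
  if (end <= start) abort("`end` must be greater than `start`")
  if (!target_base %in% c("A", "C", "G", "T")) {
    abort("`target_base` must be one of A, C, G, T")
  }
  chrom_seq <- as.character(reference[[chrom]])
  end <- min(end, nchar(chrom_seq))
  region <- strsplit(substring(chrom_seq, start, end), "")[[1]]
  eligible <- which(region != target_base) + start - 1L
  if (n_mutations > length(eligible)) {
    abort(sprintf(
      "region %d-%d has only %d site(s) not already %s; cannot spike %d",
      start, end, length(eligible), target_base, n_mutations
    ))
  }
  if (n_mutations == 0) {
    return(list(reference = reference,
                spikes = tibble(chrom = character(), pos = integer(),
                                original = character(), target = character())))
  }
  pos <- if (placement == "even") {
    eligible[unique(round(seq(1, length(eligible), length.out = n_mutations)))]
  } else {
    set.seed(seed)
    sort(sample(eligible, n_mutations))
  }
  # an even grid can collapse duplicates when n approaches the region size
  pos <- unique(pos)
  original <- substring(chrom_seq, pos, pos)
  modified <- reference
  seq_vec <- strsplit(chrom_seq, "")[[1]]
  seq_vec[pos] <- target_base
  modified[[chrom]] <- Biostrings::DNAString(paste(seq_vec, collapse = ""))
  list(
    reference = modified,
    spikes = tibble(chrom = chrom, pos = as.integer(pos),
                    original = original, target = target_base)
  )
}

#' Revert spiked mutations
#'
#' @param reference The modified [Biostrings::DNAStringSet].
#' @param spikes The spike table from [spike_mutations()].
#' @return The reference with every spiked base restored.
#' @export
revert_spikes <- function(reference, spikes) {
  if (nrow(spikes) == 0) return(reference)
  for (ch in unique(spikes$chrom)) {
    sp <- spikes[spikes$chrom == ch, ]
    seq_vec <- strsplit(as.character(reference[[ch]]), "")[[1]]
    seq_vec[sp$pos] <- sp$original
    reference[[ch]] <- Biostrings::DNAString(paste(seq_vec, collapse = ""))
  }
  reference
}

#' Build the variant table a spiked reference would yield
#'
#' Emulates re-mapping one individual's reads against a spiked reference:
#' at every spiked site that individual shows the spiked base at the full
#' local depth (haploid expectation) and every other individual shows only
#' reference reads. Depths come from the supplied coverage tracks, so
#' spikes landing in low-coverage regions stay invisible exactly as they
#' would in a real rerun.
#'
#' @param spikes Spike table from [spike_mutations()].
#' @param tracks Coverage tracks (individual, chrom, start, end, depth).
#' @param carrier The individual whose reads were re-mapped.
#' @param design A [pedigree_design()] listing all individuals.
#' @return A long variant table suitable for [find_denovo_candidates()].
#' @export
spike_variant_table <- function(spikes, tracks, carrier, design) {
  ids <- design_individuals(design)
  if (!carrier %in% ids) {
    abort(sprintf("carrier %s is not part of the design", carrier))
  }
  validate_tracks(tracks)
  if (nrow(spikes) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), var_class = character(),
                  individual = character(), total_depth = integer(),
                  alt_depth = integer(), lq_alt_count = integer()))
  }
  n_sites <- nrow(spikes)
  long <- spikes[rep(seq_len(n_sites), each = length(ids)), ]
  long$individual <- rep(ids, times = n_sites)
  long$total_depth <- depth_at(tracks, long$individual, long$chrom, long$pos)
  long |>
    dplyr::transmute(
      chrom = .data$chrom, pos = .data$pos, ref = .data$original,
      alt = .data$target, var_class = "SNV", individual = .data$individual,
      total_depth = .data$total_depth,
      alt_depth = dplyr::if_else(.data$individual == carrier,
                                 .data$total_depth, 0L),
      lq_alt_count = 0L
    )
}

# depth lookup in interval tracks; 0 outside any interval
depth_at <- function(tracks, individual, chrom, pos) {
  out <- integer(length(pos))
  key <- paste(individual, chrom)
  for (k in unique(key)) {
    sel <- key == k
    tr <- tracks[paste(tracks$individual, tracks$chrom) == k, , drop = FALSE]
    if (nrow(tr) == 0) next
    ord <- order(tr$start)
    starts <- tr$start[ord]; ends <- tr$end[ord]; dep <- tr$depth[ord]
    idx <- findInterval(pos[sel] - 1L, starts)
    hit <- idx >= 1 & (pos[sel] - 1L) < ends[pmax(idx, 1L)]
    out[sel][hit] <- dep[idx[hit]]
  }
  out
}

#' Account for every spiked mutation after re-detection
#'
#' Partitions the spike set into recovered sites (accepted by the filters
#' with the spiked alternative allele) and misses, attributing each miss to
#' a cause: `non_callable` when the site lies outside the callable mask,
#' otherwise `filtered:<reason>` carrying the filter's rejection reason.
#'
#' @param detected Candidate table from [find_denovo_candidates()] run on
#'   the spiked data.
#' @param truth Spike table from [spike_mutations()] (must be non-empty).
#' @param mask The `callable_mask` used during detection.
#' @return A list of class `recovery_report`: `summary` (one-row tibble:
#'   n_spiked, n_recovered, n_missed, fnr) and `misses` (tibble: chrom,
#'   pos, cause). `n_recovered + nrow(misses) == n_spiked` always.
#' @export
evaluate_recovery <- function(detected, truth, mask) {
  if (nrow(truth) == 0) abort("`truth` must contain at least one spiked site")
  det <- detected |>
    dplyr::transmute(.data$chrom, .data$pos, .data$alt, .data$status,
                     .data$reason)
  tr <- truth |>
    dplyr::left_join(det, by = c("chrom", "pos", target = "alt")) |>
    dplyr::mutate(
      callable = positions_callable(mask, .data$chrom, .data$pos),
      recovered = !is.na(.data$status) & .data$status == "accepted",
      cause = dplyr::case_when(
        recovered ~ NA_character_,
        !callable ~ "non_callable",
        is.na(status) ~ "not_detected",
        TRUE ~ paste0("filtered:", reason)
      )
    )
  misses <- tr |>
    dplyr::filter(!.data$recovered) |>
    dplyr::select("chrom", "pos", "cause")
  structure(
    list(
      summary = tibble(
        n_spiked = nrow(tr),
        n_recovered = sum(tr$recovered),
        n_missed = nrow(misses),
        fnr = nrow(misses) / nrow(tr)
      ),
      misses = misses
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<recovery_report: %d/%d spikes recovered (FNR %.1f%%)>\n",
              s$n_recovered, s$n_spiked, 100 * s$fnr))
  if (nrow(x$misses)) print(dplyr::count(x$misses, .data$cause))
  invisible(x)
}

#' @export
glance.recovery_report <- function(x, ...) x$summary

#' @export
tidy.recovery_report <- function(x, ...) x$misses
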