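# Shared fixtures: tiny pedigrees, hand-built variant sites and coverage
# tracks, and a naive per-base callable-site oracle kept deliberately
# independent of the package's interval sweep.

tiny_design <- function(n_progeny = 3) {
  pedigree_design(c("par_f", "par_m"), sprintf("prog_%02d", seq_len(n_progeny)))
}

# one interval per individual covering [0, len) at a constant depth
uniform_tracks <- function(design, len = 1000L, depth = 12L, chrom = "chr1") {
  ids <- c(design$parents, design$progeny, design$checks)
  tibble::tibble(individual = ids, chrom = chrom, start = 0L,
                 end = as.integer(len), depth = as.integer(depth))
}

# a full-genome callable mask for hand-built variant sites
full_mask <- function(design, len = 1000L, chrom = "chr1") {
  callable_mask_strict(uniform_tracks(design, len = len, depth = 1000L, chrom = chrom),
                       min_depth = 10)
}

# long variant rows for a single site; alt_by / lqa_by are named vectors of
# per-individual alternative and low-quality-alternative read counts
make_site <- function(design, pos = 100L, alt_by = c(), lqa_by = c(),
                      dp = 12L, chrom = "chr1", ref = "A", alt = "T",
                      var_class = "SNV", dp_by = c()) {
  ids <- c(design$parents, design$progeny, design$checks)
  dp_vec <- setNames(rep(as.integer(dp), length(ids)), ids)
  dp_vec[names(dp_by)] <- as.integer(dp_by)
  alt_vec <- setNames(rep(0L, length(ids)), ids)
  alt_vec[names(alt_by)] <- as.integer(alt_by)
  lqa_vec <- setNames(rep(0L, length(ids)), ids)
  lqa_vec[names(lqa_by)] <- as.integer(lqa_by)
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    var_class = var_class, individual = ids,
    total_depth = unname(dp_vec), alt_depth = unname(alt_vec),
    lq_alt_count = unname(lqa_vec)
  )
}

# per-position tracks from a depth matrix (individuals x positions), one
# 1-nt interval per position
tracks_from_matrix <- function(depth_mat, chrom = "chr1") {
  ids <- rownames(depth_mat)
  len <- ncol(depth_mat)
  do.call(rbind, lapply(ids, function(id) {
    tibble::tibble(individual = id, chrom = chrom,
                   start = 0:(len - 1), end = 1:len,
                   depth = as.integer(depth_mat[id, ]))
  }))
}

# naive per-base oracle: expand every track to a per-position depth vector
# with an explicit loop, then count individuals passing the threshold
bf_callable <- function(tracks, min_depth, required = NULL,
                        min_individuals = NULL) {
  chroms <- unique(tracks$chrom)
  ids <- unique(tracks$individual)
  if (!is.null(required)) ids <- required
  G_strict <- 0
  counts <- numeric(length(unique(tracks$individual)) + 1)
  n_all <- length(unique(tracks$individual))
  for (ch in chroms) {
    tr <- tracks[tracks$chrom == ch, ]
    len <- max(tr$end)
    depth <- matrix(0L, nrow = n_all, ncol = len,
                    dimnames = list(unique(tracks$individual), NULL))
    for (r in seq_len(nrow(tr))) {
      if ((tr$end[r] - tr$start[r]) > 0) {
        depth[tr$individual[r], (tr$start[r] + 1):tr$end[r]] <- tr$depth[r]
      }
    }
    for (p in seq_len(len)) {
      pass <- depth[, p] >= min_depth
      if (all(pass[ids])) G_strict <- G_strict + 1
      i <- sum(pass)
      counts[i + 1] <- counts[i + 1] + 1
    }
  }
  i_vals <- 0:n_all
  out <- list(G_strict = G_strict, per_i = counts)
  if (!is.null(min_individuals)) {
    keep <- i_vals >= min_individuals
    out$G_quorum <- sum(i_vals[keep] * counts[keep])
    out$distinct <- sum(counts[keep])
  }
  out
}

# interval part of a callable mask, stripped of class/attributes
as_tibble_strip <- function(x) {
  tibble::tibble(chrom = x$chrom, start = x$start, end = x$end)
}

# small clean config: every confounder disabled
clean_config <- function(...) {
  synth_config(genome_length = 2e5, n_chromosomes = 4, n_progeny = 6,
               repeat_fraction = 0, n_standing_variants = 0, somatic_rate = 0,
               artifact_rate = 0, error_rate = 0, wcd_probability = 0, ...)
}
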