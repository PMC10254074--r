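# Callable-site accounting.
#
# Coverage tracks are tidy interval tables (individual, chrom, start, end,
# depth) in 0-based half-open coordinates, as written by bedtools-style depth
# tools. Positions are the unit of account: per chromosome, the number of
# individuals passing the depth threshold at every base is accumulated with
# a boundary-count (tabulate + cumsum) sweep over the intervals, which the
# test suite checks against a naive per-base oracle.

validate_tracks <- function(tracks) {
  needed <- c("individual", "chrom", "start", "end", "depth")
  missing <- setdiff(needed, names(tracks))
  if (length(missing)) {
    abort(sprintf("coverage tracks lack column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(tracks) == 0) abort("coverage tracks are empty")
  if (any(tracks$end <= tracks$start)) abort("track intervals must satisfy end > start")
  if (any(tracks$depth < 0)) abort("track depth must be >= 0")
  ord <- order(tracks$individual, tracks$chrom, tracks$start, method = "radix")
  t2 <- tracks[ord, ]
  same <- t2$individual == dplyr::lag(t2$individual, default = "") &
    t2$chrom == dplyr::lag(t2$chrom, default = "")
  if (any(same & t2$start < dplyr::lag(t2$end, default = 0L))) {
    abort("track intervals must be non-overlapping within an individual")
  }
  invisible(tracks)
}

# per-chromosome extent inferred from the union of all tracks
chrom_extents <- function(tracks) {
  ext <- tracks |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(len = max(.data$end), .groups = "drop")
  setNames(ext$len, ext$chrom)
}

# per-base count of individuals with depth >= min_depth on one chromosome,
# by a boundary-count sweep; assumes intervals are non-overlapping per
# individual (validated upstream on small inputs, a track-format contract)
passing_count_per_base <- function(tracks_ch, min_depth, len) {
  cal <- tracks_ch[tracks_ch$depth >= min_depth, , drop = FALSE]
  if (nrow(cal) == 0) return(integer(len))
  delta <- tabulate(cal$start + 1L, nbins = len) -
    tabulate(pmin(cal$end, len) + 1L, nbins = len)
  # removals falling beyond position len are irrelevant (interval runs to
  # the chromosome end)
  cumsum(delta)
}

# 0-based half-open intervals where a logical per-base vector is TRUE
logical_to_intervals <- function(keep, chrom) {
  if (!any(keep)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble(chrom = chrom, start = as.integer(starts[r$values]),
         end = as.integer(ends[r$values]))
}

#' Strict callable mask: minimum depth in every required individual
#'
#' A position is callable iff its depth is at least `min_depth` in *all*
#' required individuals. This is the scheme used for deeply covered
#' pedigrees, where the rate denominator is G* = the number of callable
#' positions and exposure is G* x I x g.
#'
#' @param tracks Tidy coverage tracks: individual, chrom, start, end, depth
#'   (0-based half-open intervals, non-overlapping per individual).
#' @param required_individuals Individuals that must all pass the depth
#'   threshold (default: every individual present in `tracks`).
#' @param min_depth Minimum depth (integer reads). A ">9x" rule is
#'   `min_depth = 10`: depths are integers, so >9 and >=10 coincide.
#' @param genome_length Total genome size used for the callable fraction;
#'   inferred from the track extents if omitted.
#' @param exclude_chroms Chromosome names dropped before computing the mask
#'   (e.g. an unplaced-contig bin).
#' @return A `callable_mask`: a tibble of callable intervals (chrom, start,
#'   end; 0-based half-open) with attributes `scheme`, `G_star`,
#'   `min_depth`, `genome_length` and `callable_fraction`. Use
#'   [callable_summary()] or `glance()` for the totals.
#' @examples
#' tr <- tibble::tibble(individual = rep(c("a", "b"), each = 1),
#'                      chrom = "chr1", start = 0L, end = 10L, depth = 12L)
#' callable_mask_strict(tr, min_depth = 10)
#' @export
callable_mask_strict <- function(tracks, required_individuals = NULL,
                                 min_depth = 10, genome_length = NULL,
                                 exclude_chroms = character()) {
  tracks <- validate_tracks(as_tibble(tracks))
  check_number(min_depth, "min_depth", min = 1, integer = TRUE)
  present <- unique(tracks$individual)
  if (is.null(required_individuals)) required_individuals <- present
  if (length(required_individuals) == 0) {
    abort("`required_individuals` must not be empty")
  }
  missing <- setdiff(required_individuals, present)
  if (length(missing)) {
    abort(sprintf("no coverage track for individual(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tracks <- tracks[tracks$individual %in% required_individuals &
                     !tracks$chrom %in% exclude_chroms, , drop = FALSE]
  if (nrow(tracks) == 0) abort("no track intervals left after chromosome exclusion")
  ext <- chrom_extents(tracks)
  if (is.null(genome_length)) genome_length <- sum(ext)
  n_req <- length(required_individuals)

  pieces <- purrr::imap(split(tracks, tracks$chrom), function(tr_ch, ch) {
    cnt <- passing_count_per_base(tr_ch, min_depth, ext[[ch]])
    logical_to_intervals(cnt == n_req, ch)
  })
  mask <- dplyr::bind_rows(pieces)
  if (nrow(mask) == 0) {
    mask <- tibble(chrom = character(), start = integer(), end = integer())
  }
  g_star <- sum(mask$end - mask$start)
  new_callable_mask(mask, scheme = "strict", G_star = g_star,
                    min_depth = min_depth, min_individuals = n_req,
                    genome_length = unname(genome_length))
}

new_callable_mask <- function(mask, scheme, G_star, min_depth, min_individuals,
                              genome_length, per_i_counts = NULL,
                              distinct_positions = NULL) {
  structure(
    mask,
    class = c("callable_mask", class(mask)),
    scheme = scheme,
    G_star = as.numeric(G_star),
    min_depth = as.integer(min_depth),
    min_individuals = as.integer(min_individuals),
    genome_length = as.numeric(genome_length),
    distinct_positions = as.numeric(distinct_positions %||% sum(mask$end - mask$start)),
    callable_fraction = (distinct_positions %||% sum(mask$end - mask$start)) / genome_length,
    per_i_counts = per_i_counts
  )
}

#' Quorum callable total: depth in at least k of the individuals
#'
#' For shallower designs a position contributes whenever at least
#' `min_individuals` of the sequenced individuals reach `min_depth` there.
#' Each position is weighted by its individual count i, so
#' G* = sum over i >= min_individuals of (i x N_i), where N_i is the number
#' of positions callable in exactly i individuals; the exposure is then
#' G* x g with no separate x I factor. The unweighted number of distinct
#' callable positions is reported alongside for callable-fraction
#' statistics.
#'
#' @inheritParams callable_mask_strict
#' @param min_individuals Minimum number of individuals (quorum) that must
#'   reach `min_depth` for a position to count.
#' @return A `callable_mask` (intervals callable in at least the quorum)
#'   whose attributes carry `G_star` (the i-weighted total), the
#'   `per_i_counts` tibble (i, N_i) and `distinct_positions`.
#' @examples
#' tr <- tibble::tibble(individual = rep(c("a", "b", "c"), each = 1),
#'                      chrom = "chr1", start = 0L, end = 100L,
#'                      depth = c(6L, 6L, 2L))
#' glance(callable_total_quorum(tr, min_depth = 5, min_individuals = 2))
#' @export
callable_total_quorum <- function(tracks, min_depth = 5, min_individuals = 2,
                                  genome_length = NULL,
                                  exclude_chroms = character()) {
  tracks <- validate_tracks(as_tibble(tracks))
  check_number(min_depth, "min_depth", min = 1, integer = TRUE)
  check_number(min_individuals, "min_individuals", min = 1, integer = TRUE)
  n_ind <- length(unique(tracks$individual))
  if (min_individuals > n_ind) {
    abort(sprintf("`min_individuals` (%d) exceeds the %d individuals with tracks",
                  min_individuals, n_ind))
  }
  tracks <- tracks[!tracks$chrom %in% exclude_chroms, , drop = FALSE]
  if (nrow(tracks) == 0) abort("no track intervals left after chromosome exclusion")
  ext <- chrom_extents(tracks)
  if (is.null(genome_length)) genome_length <- sum(ext)

  counts <- numeric(n_ind + 1L)  # counts[i + 1] = N_i, i = 0..n_ind
  pieces <- purrr::imap(split(tracks, tracks$chrom), function(tr_ch, ch) {
    cnt <- passing_count_per_base(tr_ch, min_depth, ext[[ch]])
    counts <<- counts + tabulate(cnt + 1L, nbins = n_ind + 1L)
    logical_to_intervals(cnt >= min_individuals, ch)
  })
  mask <- dplyr::bind_rows(pieces)
  if (nrow(mask) == 0) {
    mask <- tibble(chrom = character(), start = integer(), end = integer())
  }

  per_i <- tibble(i = 0:n_ind, N_i = as.numeric(counts))
  per_i <- per_i[per_i$N_i > 0, , drop = FALSE]
  keep <- per_i$i >= min_individuals
  g_star <- sum(per_i$i[keep] * per_i$N_i[keep])
  distinct <- sum(per_i$N_i[keep])

  new_callable_mask(mask, scheme = "quorum", G_star = g_star,
                    min_depth = min_depth, min_individuals = min_individuals,
                    genome_length = unname(genome_length),
                    per_i_counts = per_i, distinct_positions = distinct)
}

#' Summarise a callable mask
#'
#' @param mask A `callable_mask` from [callable_mask_strict()] or
#'   [callable_total_quorum()].
#' @return A one-row tibble: scheme, min_depth, min_individuals, G_star,
#'   distinct_positions, genome_length, callable_fraction.
#' @export
callable_summary <- function(mask) {
  if (!inherits(mask, "callable_mask")) abort("`mask` must be a callable_mask")
  tibble(
    scheme = attr(mask, "scheme"),
    min_depth = attr(mask, "min_depth"),
    min_individuals = attr(mask, "min_individuals"),
    G_star = attr(mask, "G_star"),
    distinct_positions = attr(mask, "distinct_positions"),
    genome_length = attr(mask, "genome_length"),
    callable_fraction = attr(mask, "callable_fraction")
  )
}

#' @export
glance.callable_mask <- function(x, ...) callable_summary(x)

#' @export
tidy.callable_mask <- function(x, ...) {
  if (!is.null(attr(x, "per_i_counts"))) return(as_tibble(attr(x, "per_i_counts")))
  as_tibble(x)[, c("chrom", "start", "end")]
}

#' @export
print.callable_mask <- function(x, ...) {
  s <- callable_summary(x)
  cat(sprintf("<callable_mask: %s scheme>\n", s$scheme))
  cat(sprintf("  min_depth %d, min_individuals %d\n", s$min_depth, s$min_individuals))
  cat(sprintf("  G* = %s; %s distinct callable positions (%.2f%% of %s nt)\n",
              format(s$G_star, big.mark = ","),
              format(s$distinct_positions, big.mark = ","),
              100 * s$callable_fraction,
              format(s$genome_length, big.mark = ",")))
  cat(sprintf("  %d interval(s)\n", nrow(x)))
  invisible(x)
}

#' Test positions for callability against a mask
#'
#' @param mask A `callable_mask`.
#' @param chrom,pos Parallel vectors of chromosome names and 1-based
#'   positions.
#' @return Logical vector: is each position inside the mask?
#' @export
positions_callable <- function(mask, chrom, pos) {
  if (length(chrom) != length(pos)) abort("`chrom` and `pos` must have equal length")
  out <- logical(length(pos))
  m <- as_tibble(mask)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    mi <- m[m$chrom == ch, , drop = FALSE]
    if (nrow(mi) == 0) next
    ord <- order(mi$start)
    starts <- mi$start[ord]; ends <- mi$end[ord]
    idx <- findInterval(pos[sel] - 1L, starts)
    out[sel] <- idx >= 1 & (pos[sel] - 1L) < ends[pmax(idx, 1L)]
  }
  out
}
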