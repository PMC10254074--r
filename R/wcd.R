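# Whole-chromosome duplication detection from windowed coverage, and dosage
# analysis of duplicated chromosomes from an expression table.

#' Windowed mean coverage along the genome
#'
#' Tiles each chromosome with fixed-size windows (the terminal window may be
#' shorter) and computes the length-weighted mean depth per window from an
#' interval coverage track.
#'
#' @param track Coverage track for one or more individuals: individual,
#'   chrom, start, end, depth (0-based half-open).
#' @param window_size Window size in nucleotides (default 5 kb).
#' @param exclude Chromosome names to drop (e.g. an unplaced-contig bin);
#'   unknown names produce a warning, not an error.
#' @return A `window_coverage` tibble: individual, chrom, start, end,
#'   mean_depth.
#' @examples
#' tr <- tibble::tibble(individual = "a", chrom = "chr1",
#'                      start = c(0L, 6000L), end = c(6000L, 12000L),
#'                      depth = c(30L, 10L))
#' window_coverage(tr, window_size = 5000)
#' @export
window_coverage <- function(track, window_size = 5000, exclude = character()) {
  track <- validate_tracks(as_tibble(track))
  check_number(window_size, "window_size", min = 1, integer = TRUE)
  unknown <- setdiff(exclude, unique(track$chrom))
  if (length(unknown)) {
    warn(sprintf("excluded chromosome(s) not present in the track: %s",
                 paste(unknown, collapse = ", ")))
  }
  track <- track[!track$chrom %in% exclude, , drop = FALSE]
  if (nrow(track) == 0) abort("no track intervals left after chromosome exclusion")
  ext <- chrom_extents(track)

  out <- purrr::map(split(track, list(track$individual, track$chrom), drop = TRUE),
                    function(tr) {
    ch <- tr$chrom[1]
    len <- ext[[ch]]
    cov <- IRanges::coverage(
      IRanges::IRanges(start = tr$start + 1L, end = tr$end),
      weight = tr$depth, width = len
    )
    starts <- seq(1L, len, by = window_size)
    ends <- pmin(starts + window_size - 1L, len)
    v <- IRanges::Views(cov, start = starts, end = ends)
    tibble(
      individual = tr$individual[1], chrom = ch,
      start = starts - 1L, end = ends,
      mean_depth = as.numeric(IRanges::viewMeans(v))
    )
  })
  out <- dplyr::bind_rows(out) |>
    dplyr::arrange(.data$individual, .data$chrom, .data$start)
  class(out) <- c("window_coverage", class(out))
  attr(out, "window_size") <- as.integer(window_size)
  out
}

#' @export
autoplot.window_coverage <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::group_by(.data$individual) |>
    dplyr::arrange(.data$chrom, .data$start, .by_group = TRUE) |>
    dplyr::mutate(gpos = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gpos, y = .data$mean_depth,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.3, show.legend = FALSE) +
    ggplot2::facet_wrap(~individual, ncol = 1) +
    ggplot2::labs(x = "window index (genome order)", y = "mean depth",
                  title = "Windowed genome coverage") +
    ggplot2::theme_minimal()
}

#' Call whole-chromosome duplications from windowed coverage
#'
#' For each individual and chromosome, the depth ratio is the median of that
#' chromosome's window depths divided by a baseline computed as the median
#' window depth over all *other* chromosomes. Medians on both sides make the
#' ratio robust to the duplicated chromosomes themselves (no prior knowledge
#' of which chromosomes are affected is needed) and to low-coverage or
#' unmappable stretches inside the tested chromosome; `chrom_stat = "mean"`
#' recovers a plain mean numerator. A chromosome is
#' `duplicated` at ratio >= `dup_threshold`, `ambiguous` in
#' [`ambiguous_threshold`, `dup_threshold`) — a grey zone where an early,
#' widely shared somatic event cannot be excluded — and `normal` below.
#'
#' @param wc A `window_coverage` table from [window_coverage()].
#' @param dup_threshold Ratio at or above which a chromosome is called
#'   duplicated (default 1.9).
#' @param ambiguous_threshold Lower edge of the ambiguous band (default 1.5).
#' @param chrom_stat Statistic over the tested chromosome's windows:
#'   "median" (default) or "mean".
#' @return A `duplication_calls` tibble: individual, chromosome,
#'   chrom_depth, baseline, ratio, status.
#' @examples
#' tr <- tibble::tibble(
#'   individual = "a",
#'   chrom = rep(c("chr1", "chr2"), each = 2),
#'   start = rep(c(0L, 5000L), 2), end = rep(c(5000L, 10000L), 2),
#'   depth = c(30L, 30L, 60L, 60L)
#' )
#' detect_duplications(window_coverage(tr))
#' @export
detect_duplications <- function(wc, dup_threshold = 1.9,
                                ambiguous_threshold = 1.5,
                                chrom_stat = c("median", "mean")) {
  chrom_stat <- match.arg(chrom_stat)
  stat <- if (chrom_stat == "median") median else mean
  check_number(dup_threshold, "dup_threshold", min = 0)
  check_number(ambiguous_threshold, "ambiguous_threshold", min = 0)
  if (ambiguous_threshold > dup_threshold) {
    abort("`ambiguous_threshold` must not exceed `dup_threshold`")
  }
  wc <- as_tibble(wc)
  calls <- purrr::map(split(wc, wc$individual), function(w) {
    chroms <- unique(w$chrom)
    if (length(chroms) < 2) {
      abort("duplication detection needs at least two chromosomes (the baseline excludes the tested one)")
    }
    purrr::map_dfr(chroms, function(ch) {
      tested <- stat(w$mean_depth[w$chrom == ch])
      baseline <- median(w$mean_depth[w$chrom != ch])
      if (baseline <= 0) abort("baseline depth is zero; cannot form ratios")
      tibble(individual = w$individual[1], chromosome = ch,
             chrom_depth = tested, baseline = baseline,
             ratio = tested / baseline)
    })
  })
  calls <- dplyr::bind_rows(calls) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$ratio >= dup_threshold ~ "duplicated",
      .data$ratio >= ambiguous_threshold ~ "ambiguous",
      TRUE ~ "normal"
    )) |>
    dplyr::arrange(.data$individual, .data$chromosome)
  class(calls) <- c("duplication_calls", class(calls))
  attr(calls, "dup_threshold") <- dup_threshold
  attr(calls, "ambiguous_threshold") <- ambiguous_threshold
  calls
}

#' @export
autoplot.duplication_calls <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$chromosome, y = .data$ratio,
                               colour = .data$status)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "dup_threshold"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = attr(object, "ambiguous_threshold"),
                        linetype = "dotted") +
    ggplot2::facet_wrap(~individual) +
    ggplot2::labs(y = "depth ratio vs baseline", x = NULL,
                  title = "Chromosome duplication calls") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Expression dosage ratio of duplicated versus non-duplicated chromosomes
#'
#' Quantifies dosage (non-)compensation from a tidy TPM table. Genes are
#' kept when their mean TPM exceeds `tpm_min` in both strains; each gene's
#' ratio is its mean test TPM over its mean control TPM; the reported fold
#' is the aggregate (mean by default) of those ratios over
#' duplicated-chromosome genes divided by the aggregate over all other
#' genes. A fold near the copy-number ratio (2 for a duplicated
#' chromosome) indicates absent dosage compensation; a fold near 1
#' indicates full compensation.
#'
#' @param expr Tidy expression table: gene, chromosome, strain
#'   ("test"/"control"), replicate, tpm. See
#'   [simulate_expression_table()].
#' @param duplicated_chromosomes Chromosomes duplicated in the test strain.
#' @param tpm_min Expression filter: genes must exceed this mean TPM in both
#'   strains (default 1).
#' @param aggregate "mean" (default) or "median" across genes.
#' @return A list of class `dosage_result`: `fold`, `n_dup_genes`,
#'   `n_other_genes`, `aggregate`, and `per_gene` (gene, chromosome,
#'   duplicated, mean_test, mean_control, ratio).
#' @export
dosage_ratio <- function(expr, duplicated_chromosomes, tpm_min = 1,
                         aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  expr <- as_tibble(expr)
  needed <- c("gene", "chromosome", "strain", "replicate", "tpm")
  missing <- setdiff(needed, names(expr))
  if (length(missing)) {
    abort(sprintf("expression table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(expr$tpm < 0)) abort("`tpm` must be >= 0")
  if (!all(c("test", "control") %in% expr$strain)) {
    abort("`strain` must contain both \"test\" and \"control\"")
  }
  check_number(tpm_min, "tpm_min", min = 0)

  per_gene <- expr |>
    dplyr::group_by(.data$gene, .data$chromosome, .data$strain) |>
    dplyr::summarise(mean_tpm = mean(.data$tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "strain", values_from = "mean_tpm",
                       names_prefix = "mean_") |>
    dplyr::filter(.data$mean_test > tpm_min, .data$mean_control > tpm_min) |>
    dplyr::mutate(
      duplicated = .data$chromosome %in% duplicated_chromosomes,
      ratio = .data$mean_test / .data$mean_control
    )
  n_dup <- sum(per_gene$duplicated)
  n_other <- sum(!per_gene$duplicated)
  if (n_dup == 0 || n_other == 0) {
    abort("after TPM filtering one partition (duplicated / other) is empty")
  }
  agg <- if (aggregate == "mean") mean else median
  fold <- agg(per_gene$ratio[per_gene$duplicated]) /
    agg(per_gene$ratio[!per_gene$duplicated])
  structure(
    list(fold = fold, n_dup_genes = n_dup, n_other_genes = n_other,
         aggregate = aggregate, tpm_min = tpm_min, per_gene = per_gene),
    class = "dosage_result"
  )
}

#' @export
print.dosage_result <- function(x, ...) {
  cat(sprintf(
    "<dosage_result: %.2f-fold higher expression on duplicated chromosomes (%s of per-gene ratios; %d vs %d genes)>\n",
    x$fold, x$aggregate, x$n_dup_genes, x$n_other_genes))
  invisible(x)
}

#' @export
tidy.dosage_result <- function(x, ...) x$per_gene

#' @export
glance.dosage_result <- function(x, ...) {
  tibble(fold = x$fold, n_dup_genes = x$n_dup_genes,
         n_other_genes = x$n_other_genes, aggregate = x$aggregate,
         tpm_min = x$tpm_min)
}
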