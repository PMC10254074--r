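#' Run the full mutation-rate pipeline on one pedigree dataset
#'
#' Executes the stages in their canonical order — callable-site accounting,
#' de novo candidate filtering, rate estimation with its exact Poisson
#' interval, spectrum classification, whole-chromosome-duplication
#' detection and (optionally) effective-population-size estimation — and
#' returns every intermediate plus a one-row summary. All stages are
#' deterministic given fixed inputs; when `output_dir` is set, the report
#' (JSON), the candidate and rate tables (TSV) and the resolved parameters
#' are written there, and a rerun on the same inputs reproduces them
#' byte-identically.
#'
#' @param variants Long variant table (SNV/indel rows; SV rows are routed
#'   through the structural filter automatically).
#' @param tracks Coverage tracks (individual, chrom, start, end, depth).
#' @param design A [pedigree_design()].
#' @param scheme Callable scheme: "strict" (depth in all required
#'   individuals; exposure G* x I x g) or "quorum" (at least
#'   `min_individuals` individuals; G* already individual-weighted, so
#'   exposure is G* x g).
#' @param min_depth Callable depth threshold (10 for the strict scheme's
#'   ">9x" rule; 5 is typical for quorum designs).
#' @param min_individuals Quorum size (quorum scheme only; default: all
#'   individuals).
#' @param alpha Significance level of the rate interval.
#' @param sv_window Proximity window for structural candidates, nt.
#' @param window_size Coverage window for duplication detection, nt.
#' @param dup_threshold,ambiguous_threshold Duplication-call ratio
#'   thresholds.
#' @param pi_s Optional named vector of neutral diversities for Ne
#'   estimation.
#' @param exclude_chroms Chromosomes excluded throughout (e.g. an
#'   unplaced-contig bin).
#' @param genome_length Genome size for callable fractions (inferred from
#'   tracks if omitted).
#' @param include_checks Inspect the design's check individuals when
#'   vetoing candidates.
#' @param output_dir If set, write report.json and TSV outputs there.
#' @return A list of class `pipeline_report`: `callable` (summary tibble),
#'   `mask`, `candidates`, `sv_candidates`, `rate` (`rate_estimate`),
#'   `spectrum`, `duplications`, `wcd_rate`, `ne`, `params`. `glance()`
#'   returns the headline numbers as one row.
#' @examples
#' sim <- simulate_pedigree(synth_config(genome_length = 5e4, n_chromosomes = 2,
#'                                       n_progeny = 4, seed = 7))
#' rep <- run_pipeline(sim$variants, sim$tracks, sim$design)
#' glance(rep)
#' @export
run_pipeline <- function(variants, tracks, design,
                         scheme = c("strict", "quorum"),
                         min_depth = 10, min_individuals = NULL,
                         alpha = 0.05, sv_window = 1000,
                         window_size = 5000, dup_threshold = 1.9,
                         ambiguous_threshold = 1.5, pi_s = NULL,
                         exclude_chroms = character(),
                         genome_length = NULL, include_checks = FALSE,
                         output_dir = NULL) {
  scheme <- match.arg(scheme)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  mask <- stage("callable", {
    if (scheme == "strict") {
      callable_mask_strict(tracks,
                           required_individuals = design_individuals(design, include_checks),
                           min_depth = min_depth,
                           genome_length = genome_length,
                           exclude_chroms = exclude_chroms)
    } else {
      callable_total_quorum(tracks, min_depth = min_depth,
                            min_individuals = min_individuals %||%
                              length(unique(tracks$individual)),
                            genome_length = genome_length,
                            exclude_chroms = exclude_chroms)
    }
  })

  snv_indel <- variants[variants$var_class %in% c("SNV", "indel"), , drop = FALSE]
  sv <- variants[variants$var_class == "SV", , drop = FALSE]

  candidates <- stage("filter", {
    find_denovo_candidates(snv_indel, mask, design, include_checks = include_checks)
  })
  sv_candidates <- stage("filter_sv", {
    if (nrow(sv)) {
      filter_structural_candidates(sv, proximity_window = sv_window,
                                   design = design, mask = mask,
                                   include_checks = include_checks)
    } else candidates[0, ]
  })

  n_accepted <- sum(candidates$status == "accepted")
  rate <- stage("rate", {
    I_eff <- if (scheme == "strict") length(design$progeny) else 1L
    mutation_rate(n_accepted, attr(mask, "G_star"), I = I_eff,
                  g = design$generations, alpha = alpha)
  })

  spectrum <- stage("spectrum", {
    acc <- candidates[candidates$status == "accepted" &
                        candidates$var_class == "SNV", c("ref", "alt")]
    classify_spectrum(acc)
  })

  wcd <- stage("wcd", {
    wc <- window_coverage(tracks, window_size = window_size,
                          exclude = intersect(exclude_chroms,
                                              unique(tracks$chrom)))
    calls <- detect_duplications(wc, dup_threshold = dup_threshold,
                                 ambiguous_threshold = ambiguous_threshold)
    # progeny only: parents' karyotype is the baseline state
    calls[calls$individual %in% design$progeny, , drop = FALSE]
  })
  dup_calls <- wcd[wcd$status == "duplicated", , drop = FALSE]
  # one mis-segregation event per affected individual, however many
  # chromosomes it carried along
  n_events <- length(unique(dup_calls$individual))
  wcd_rates <- stage("wcd_rate", {
    wcd_rate(n_events,
             n_chromosomes = length(unique(tracks$chrom)) -
               length(intersect(exclude_chroms, unique(tracks$chrom))),
             I = length(design$progeny), g = design$generations)
  })

  ne <- if (!is.null(pi_s)) {
    stage("ne", effective_population_size(pi_s, rate = rate))
  } else NULL

  params <- tibble(
    scheme = scheme, min_depth = min_depth,
    min_individuals = attr(mask, "min_individuals"),
    alpha = alpha, sv_window = sv_window, window_size = window_size,
    dup_threshold = dup_threshold, ambiguous_threshold = ambiguous_threshold,
    include_checks = include_checks
  )

  report <- structure(
    list(callable = callable_summary(mask), mask = mask,
         candidates = candidates, sv_candidates = sv_candidates,
         rate = rate, spectrum = spectrum, duplications = wcd,
         wcd_rate = wcd_rates, ne = ne, params = params),
    class = "pipeline_report"
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(candidates, file.path(output_dir, "candidates.tsv"))
    readr::write_tsv(tidy(rate), file.path(output_dir, "rate.tsv"))
    readr::write_tsv(as_tibble(wcd), file.path(output_dir, "duplications.tsv"))
    readr::write_tsv(params, file.path(output_dir, "params.tsv"))
    jsonlite::write_json(
      list(callable = report$callable, rate = tidy(rate),
           spectrum = glance(spectrum), wcd_rate = wcd_rates,
           ne = ne, params = params),
      file.path(output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  s <- x$callable
  cat(sprintf("  callable : %s scheme, G* = %s (%.2f%% of genome)\n",
              s$scheme, format(s$G_star, big.mark = ","),
              100 * s$callable_fraction))
  cat(sprintf("  filter   : %d accepted / %d candidate sites\n",
              sum(x$candidates$status == "accepted"), nrow(x$candidates)))
  cat(sprintf("  rate     : mu = %s [%s - %s]\n", format_rate(x$rate$mu),
              format_rate(x$rate$ci_low), format_rate(x$rate$ci_high)))
  cat(sprintf("  spectrum : %d transitions, %d transversions\n",
              x$spectrum$n_transitions, x$spectrum$n_transversions))
  cat(sprintf("  WCD      : %d duplication event(s); %s per chromosome, %s per cell\n",
              x$wcd_rate$n_events,
              signif(x$wcd_rate$per_chromosome_rate, 2),
              signif(x$wcd_rate$per_cell_rate, 2)))
  if (!is.null(x$ne)) {
    for (i in seq_len(nrow(x$ne))) {
      cat(sprintf("  Ne       : %s ~ %s (pi_s = %g)\n", x$ne$region[i],
                  format(signif(x$ne$Ne[i], 2), big.mark = ","), x$ne$pi_s[i]))
    }
  }
  invisible(x)
}

#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(
    scheme = x$callable$scheme,
    G_star = x$callable$G_star,
    callable_fraction = x$callable$callable_fraction,
    n_accepted = sum(x$candidates$status == "accepted"),
    mu = x$rate$mu, ci_low = x$rate$ci_low, ci_high = x$rate$ci_high,
    n_transitions = x$spectrum$n_transitions,
    n_transversions = x$spectrum$n_transversions,
    wcd_events = x$wcd_rate$n_events,
    wcd_per_chromosome = x$wcd_rate$per_chromosome_rate,
    wcd_per_cell = x$wcd_rate$per_cell_rate
  )
}
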