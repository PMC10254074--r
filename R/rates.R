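# Mutation-rate point estimates, exact Poisson intervals, spectrum
# classification and chromosome-duplication rates.

#' Exact (Garwood) confidence interval for a Poisson rate
#'
#' For an observed count n over exposure T (site-generations), the exact
#' two-sided interval on the rate is obtained from chi-square quantiles:
#' lower = qchisq(alpha/2, 2n) / (2T) (0 when n = 0) and
#' upper = qchisq(1 - alpha/2, 2n + 2) / (2T). For n = 0 the upper bound
#' reduces to -log(alpha/2)/T.
#'
#' @param n Observed count (non-negative integer).
#' @param exposure Exposure T > 0, in site-generations.
#' @param alpha Two-sided significance level in (0, 1); 0.05 gives a 95%
#'   interval.
#' @return Named numeric vector `c(low, high)` on the rate scale.
#' @examples
#' poisson_ci(2, 163675306 * 30)
#' @export
poisson_ci <- function(n, exposure, alpha = 0.05) {
  check_number(n, "n", min = 0, integer = TRUE)
  check_number(exposure, "exposure", min = .Machine$double.xmin)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number strictly between 0 and 1")
  }
  low <- if (n == 0) 0 else qchisq(alpha / 2, 2 * n) / 2 / exposure
  high <- qchisq(1 - alpha / 2, 2 * n + 2) / 2 / exposure
  c(low = low, high = high)
}

#' Estimate a per-site per-generation mutation rate
#'
#' mu = n / (G* x I x g), where n is the accepted mutation count, G* the
#' callable-site total, I the number of sequenced progeny and g the
#' generations per progeny. Under the quorum callable scheme I is already
#' folded into G* (each position weighted by its individual count), so pass
#' `I = 1` there. An exact Poisson (Garwood) confidence interval on the
#' rate accompanies the point estimate.
#'
#' @param n Number of accepted de novo mutations.
#' @param G_star Callable-site total G* (> 0).
#' @param I Number of progeny individuals (1 for the quorum scheme).
#' @param g Generations per progeny.
#' @param alpha Significance level for the interval.
#' @return An object of class `rate_estimate`; see [tidy()]/[glance()] for
#'   tabular access.
#' @examples
#' mutation_rate(2, 163675306, I = 30, g = 1)
#' @export
mutation_rate <- function(n, G_star, I = 1, g = 1, alpha = 0.05) {
  check_number(n, "n", min = 0, integer = TRUE)
  check_number(G_star, "G_star", min = 0)
  if (G_star <= 0) abort("`G_star` must be > 0: the rate is undefined on zero callable sites")
  check_number(I, "I", min = 1, integer = TRUE)
  check_number(g, "g", min = 1, integer = TRUE)
  exposure <- G_star * I * g
  ci <- poisson_ci(n, exposure, alpha)
  structure(
    list(n = as.integer(n), G_star = G_star, I = as.integer(I),
         g = as.integer(g), exposure = exposure, mu = n / exposure,
         ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         alpha = alpha),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate>\n")
  cat(sprintf("  n = %d over G* = %s x I = %d x g = %d (T = %s site-generations)\n",
              x$n, format(x$G_star, big.mark = ","), x$I, x$g,
              format(x$exposure, big.mark = ",")))
  cat(sprintf("  mu = %s  [%d%% CI %s - %s]\n",
              format_rate(x$mu), round(100 * (1 - x$alpha)),
              format_rate(x$ci_low), format_rate(x$ci_high)))
  invisible(x)
}

#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble(n = x$n, G_star = x$G_star, I = x$I, g = x$g, exposure = x$exposure,
         mu = x$mu, ci_low = x$ci_low, ci_high = x$ci_high, alpha = x$alpha)
}

#' @export
glance.rate_estimate <- function(x, ...) tidy(x)

#' Classify a mutation spectrum into transitions and transversions
#'
#' A substitution is a transition when reference and alternative base are
#' both purines (A, G) or both pyrimidines (C, T), and a transversion
#' otherwise. Per-type counts are retained.
#'
#' @param mutations A data frame with columns `ref` and `alt` (single
#'   nucleotides), or a character vector of "R>A" substitution strings.
#' @return An object of class `spectrum_summary`: per-type counts plus
#'   transition/transversion totals. `tidy()` returns the per-type table,
#'   `glance()` the totals.
#' @examples
#' classify_spectrum(c("C>T", "T>C", "A>T", "G>T", "C>A", "T>G", "G>C"))
#' @export
classify_spectrum <- function(mutations) {
  if (is.character(mutations)) {
    parts <- stringr::str_match(mutations, "^([ACGT])>([ACGT])$")
    if (anyNA(parts[, 1]) && length(mutations) > 0) {
      abort("substitution strings must look like \"C>T\" with single A/C/G/T bases")
    }
    mutations <- tibble(ref = parts[, 2], alt = parts[, 3])
  }
  mutations <- as_tibble(mutations)
  if (nrow(mutations) > 0) {
    ok <- mutations$ref %in% c("A", "C", "G", "T") &
      mutations$alt %in% c("A", "C", "G", "T") &
      mutations$ref != mutations$alt
    if (!all(ok)) {
      abort("spectrum classification requires single-nucleotide ref/alt in {A,C,G,T}")
    }
  }
  purine <- c("A", "G")
  types <- mutations |>
    dplyr::mutate(
      substitution = paste0(.data$ref, ">", .data$alt),
      class = dplyr::if_else(
        (.data$ref %in% purine) == (.data$alt %in% purine),
        "transition", "transversion"
      )
    ) |>
    dplyr::count(.data$substitution, .data$class, name = "n") |>
    dplyr::arrange(.data$class, .data$substitution)
  structure(
    list(
      types = types,
      n_transitions = sum(types$n[types$class == "transition"]),
      n_transversions = sum(types$n[types$class == "transversion"]),
      total = sum(types$n)
    ),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary: %d substitutions (%d transitions, %d transversions)>\n",
              x$total, x$n_transitions, x$n_transversions))
  if (nrow(x$types)) print(x$types)
  invisible(x)
}

#' @export
tidy.spectrum_summary <- function(x, ...) x$types

#' @export
glance.spectrum_summary <- function(x, ...) {
  tibble(n_transitions = x$n_transitions, n_transversions = x$n_transversions,
         total = x$total,
         ts_tv_ratio = ifelse(x$n_transversions > 0,
                              x$n_transitions / x$n_transversions, NA_real_))
}

#' @export
autoplot.spectrum_summary <- function(object, ...) {
  ggplot2::ggplot(object$types,
                  ggplot2::aes(x = .data$substitution, y = .data$n,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "substitution", y = "count", fill = NULL,
                  title = "Mutation spectrum") +
    ggplot2::theme_minimal()
}

#' Whole-chromosome duplication rates
#'
#' Converts an event count into a per-chromosome and a per-cell duplication
#' rate: per_chromosome = n / (n_chromosomes x I x g) and
#' per_cell = n / (I x g). Co-duplicated chromosomes within one individual
#' are conventionally counted as a single event (one mis-segregation);
#' count them individually upstream if a per-chromosome event definition is
#' wanted.
#'
#' @param n_events Number of independent duplication events.
#' @param n_chromosomes Chromosomes in the karyotype.
#' @param I Number of individuals observed.
#' @param g Generations per individual.
#' @return A one-row tibble: n_events, n_chromosomes, I, g,
#'   per_chromosome_rate, per_cell_rate.
#' @examples
#' wcd_rate(1, n_chromosomes = 28, I = 30)
#' @export
wcd_rate <- function(n_events, n_chromosomes, I, g = 1) {
  check_number(n_events, "n_events", min = 0, integer = TRUE)
  check_number(n_chromosomes, "n_chromosomes", min = 1, integer = TRUE)
  check_number(I, "I", min = 1, integer = TRUE)
  check_number(g, "g", min = 1, integer = TRUE)
  tibble(
    n_events = as.integer(n_events),
    n_chromosomes = as.integer(n_chromosomes),
    I = as.integer(I), g = as.integer(g),
    per_chromosome_rate = n_events / (n_chromosomes * I * g),
    per_cell_rate = n_events / (I * g)
  )
}
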