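#' Effective population size from neutral diversity
#'
#' Under neutrality the expected synonymous diversity of a diploid
#' population is pi_s = 4 x Ne x mu, so Ne = pi_s / (4 mu). When a
#' [mutation_rate()] estimate is supplied its exact Poisson interval
#' propagates to Ne: the high rate bound gives the low Ne bound and vice
#' versa. Demographic history can distort pi_s, so these values are
#' indicative rather than definitive.
#'
#' @param pi_s Neutral (synonymous) nucleotide diversity, one value per
#'   region; may be a named vector or be labelled via `region`.
#' @param mu Mutation rate per site per generation (> 0), or omit and pass
#'   `rate`.
#' @param rate Optionally a `rate_estimate`; its `mu` and confidence bounds
#'   are used.
#' @param region Optional character vector of region labels (e.g.
#'   "autosomes", "PAR", "SDR"), recycled against `pi_s`.
#' @return A tibble: region, pi_s, mu, Ne, Ne_low, Ne_high (bounds NA when
#'   no interval is available).
#' @examples
#' effective_population_size(c(autosomes = 0.00323),
#'                           rate = mutation_rate(2, 163675306, I = 30))
#' @export
effective_population_size <- function(pi_s, mu = NULL, rate = NULL,
                                      region = NULL) {
  if (!is.numeric(pi_s) || length(pi_s) < 1 || any(pi_s < 0)) {
    abort("`pi_s` must be non-negative diversity value(s)")
  }
  ci <- c(NA_real_, NA_real_)
  if (!is.null(rate)) {
    if (!inherits(rate, "rate_estimate")) {
      abort("`rate` must be a rate_estimate from mutation_rate()")
    }
    mu <- rate$mu
    ci <- c(rate$ci_low, rate$ci_high)
  }
  if (is.null(mu)) abort("supply either `mu` or `rate`")
  check_number(mu, "mu", min = 0)
  if (mu <= 0) abort("`mu` must be > 0")
  if (is.null(region)) {
    region <- names(pi_s) %||% paste0("region_", seq_along(pi_s))
  }
  tibble(
    region = rep_len(region, length(pi_s)),
    pi_s = unname(pi_s),
    mu = mu,
    Ne = unname(pi_s) / (4 * mu),
    Ne_low = if (is.finite(ci[2]) && ci[2] > 0) unname(pi_s) / (4 * ci[2]) else NA_real_,
    Ne_high = if (is.finite(ci[1]) && ci[1] > 0) unname(pi_s) / (4 * ci[1]) else NA_real_
  )
}
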