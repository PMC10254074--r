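# Haploid de novo mutation candidate filtering.
#
# Variant tables are tidy and long: one row per site x individual, with
# columns chrom, pos (1-based), ref, alt, var_class ("SNV", "indel" or
# "SV"), individual, total_depth, alt_depth, lq_alt_count. Multi-allelic
# sites are simply several (chrom, pos, ref, alt) keys, so the per-allele
# criteria apply without an explicit decomposition step.

validate_variants <- function(variants, design, include_checks = FALSE) {
  needed <- c("chrom", "pos", "ref", "alt", "var_class", "individual",
              "total_depth", "alt_depth", "lq_alt_count")
  missing <- setdiff(needed, names(variants))
  if (length(missing)) {
    abort(sprintf("variant table lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(variants) == 0) return(invisible(variants))
  if (any(variants$pos < 1)) abort("`pos` must be >= 1 (1-based coordinates)")
  if (any(variants$alt == variants$ref)) abort("`alt` must differ from `ref`")
  if (any(variants$alt_depth > variants$total_depth)) {
    abort("`alt_depth` must not exceed `total_depth`")
  }
  if (any(variants$alt_depth < 0) || any(variants$lq_alt_count < 0)) {
    abort("read counts must be >= 0")
  }
  ids <- design_individuals(design, include_checks)
  extra <- setdiff(unique(variants$individual), ids)
  if (length(extra)) {
    abort(sprintf("variant table contains individual(s) absent from the design: %s",
                  paste(extra, collapse = ", ")))
  }
  invisible(variants)
}

# rejection reasons in their fixed evaluation order
denovo_reasons <- c("not_callable", "shared_carriers", "partial_fraction",
                    "alt_in_others", "proximity")

# shared engine: classify every (chrom, pos, ref, alt) key against the
# haploid criteria, with the carrier alt-fraction threshold as a parameter
# (1.0 for the strict filter, lower for the stringency sweep)
classify_denovo <- function(variants, mask, design, fraction_threshold = 1,
                            include_checks = FALSE) {
  validate_variants(variants, design, include_checks)
  ids <- design_individuals(design, include_checks)
  progeny <- design$progeny

  site_key <- c("chrom", "pos", "ref", "alt", "var_class")
  if (nrow(variants) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), var_class = character(),
                  carrier = character(), alt_fraction = numeric(),
                  status = character(), reason = character()))
  }

  # every design individual must have a support row at every site
  per_site <- variants |>
    dplyr::group_by(dplyr::across(dplyr::all_of(site_key))) |>
    dplyr::summarise(
      n_rows = dplyr::n(),
      n_distinct_ind = dplyr::n_distinct(.data$individual),
      .groups = "drop"
    )
  if (any(per_site$n_rows != length(ids)) ||
      any(per_site$n_distinct_ind != length(ids))) {
    bad <- per_site[per_site$n_rows != length(ids) |
                      per_site$n_distinct_ind != length(ids), ][1, ]
    abort(sprintf(
      "site %s:%d %s>%s lacks support rows for some design individuals",
      bad$chrom, bad$pos, bad$ref, bad$alt
    ))
  }

  prog_tbl <- variants[variants$individual %in% progeny, , drop = FALSE]
  carrier_info <- prog_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(site_key))) |>
    dplyr::summarise(
      n_carriers = sum(.data$alt_depth > 0),
      carrier = if (sum(.data$alt_depth > 0) == 1)
        .data$individual[.data$alt_depth > 0] else NA_character_,
      .groups = "drop"
    )

  carrier_support <- prog_tbl |>
    dplyr::inner_join(carrier_info |> dplyr::filter(!is.na(.data$carrier)),
                      by = c(site_key, individual = "carrier")) |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(site_key)),
      carrier = .data$individual,
      carrier_total = .data$total_depth,
      carrier_alt = .data$alt_depth
    )

  others_alt <- variants |>
    dplyr::left_join(carrier_info[, c(site_key, "carrier")], by = site_key) |>
    dplyr::filter(is.na(.data$carrier) | .data$individual != .data$carrier) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(site_key))) |>
    dplyr::summarise(
      any_other_alt = any(.data$alt_depth > 0 | .data$lq_alt_count > 0),
      .groups = "drop"
    )

  res <- carrier_info |>
    dplyr::left_join(carrier_support, by = c(site_key, "carrier")) |>
    dplyr::left_join(others_alt, by = site_key) |>
    dplyr::mutate(
      callable = positions_callable(mask, .data$chrom, .data$pos),
      alt_fraction = dplyr::if_else(
        !is.na(.data$carrier) & .data$carrier_total > 0,
        .data$carrier_alt / .data$carrier_total, NA_real_
      ),
      reason = dplyr::case_when(
        !callable ~ "not_callable",
        n_carriers != 1 ~ "shared_carriers",
        is.na(alt_fraction) | alt_fraction < fraction_threshold ~ "partial_fraction",
        any_other_alt ~ "alt_in_others",
        TRUE ~ NA_character_
      ),
      status = dplyr::if_else(is.na(.data$reason), "accepted", "rejected")
    ) |>
    dplyr::select(dplyr::all_of(site_key), "carrier", "alt_fraction",
                  "status", "reason") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)
  res
}

#' Identify de novo mutation candidates in a haploid pedigree
#'
#' Applies the haploid filtering criteria to a long multi-sample variant
#' table. A candidate is accepted iff, in this order:
#' \enumerate{
#'   \item the position is callable under the supplied mask;
#'   \item exactly one progeny individual carries any (high-quality)
#'     alternative read (`shared_carriers` otherwise — this also covers
#'     sites with no progeny carrier at all, e.g. parent-only variants or
#'     artifact sites with only low-quality support);
#'   \item in that carrier the alternative allele is 100% of the coverage
#'     (`alt_depth == total_depth`; the genome is haploid, so any reference
#'     read indicates a somatic rather than germline mutation);
#'   \item no other individual — progeny, parent, or optional check
#'     individual — has any alternative read, even at low quality
#'     (`alt_in_others`), guarding against repeat-driven mismapping.
#' }
#' Every site receives exactly one status; a rejected site records the
#' first criterion it failed, so reports are deterministic.
#'
#' @param variants Long variant table (see [simulate_pedigree()] for the
#'   column contract). SNVs and short indels share identical criteria.
#' @param mask A `callable_mask` on the same coordinate system.
#' @param design A [pedigree_design()].
#' @param include_checks Also require zero alternative reads in the design's
#'   check individuals (their rows must then be present in `variants`).
#' @return A tibble with one row per (chrom, pos, ref, alt) candidate:
#'   carrier, alt_fraction, status ("accepted"/"rejected") and reason.
#' @examples
#' sim <- simulate_pedigree(synth_config(genome_length = 5e4, n_chromosomes = 2,
#'                                       n_progeny = 4, seed = 7))
#' mask <- callable_mask_strict(sim$tracks, min_depth = 10)
#' cands <- find_denovo_candidates(sim$variants, mask, sim$design)
#' table(cands$status)
#' @export
find_denovo_candidates <- function(variants, mask, design, include_checks = FALSE) {
  classify_denovo(variants, mask, design, fraction_threshold = 1,
                  include_checks = include_checks)
}

#' Filter structural variant candidates with a proximity veto
#'
#' Structural candidates pass the same haploid criteria as nucleotide
#' variants, plus one more: a candidate unique to one individual is rejected
#' (`proximity`) when another individual shows a same-class variant within
#' `proximity_window` nucleotides, since clustered calls across individuals
#' betray a locally unreliable region rather than a de novo event.
#'
#' @inheritParams find_denovo_candidates
#' @param sv_variants Long variant table with `var_class = "SV"` rows only.
#' @param proximity_window Window in nucleotides (each side) for the
#'   cross-individual proximity veto.
#' @return As [find_denovo_candidates()], with `proximity` as an additional
#'   possible rejection reason.
#' @export
filter_structural_candidates <- function(sv_variants, proximity_window = 1000,
                                         design, mask, include_checks = FALSE) {
  check_number(proximity_window, "proximity_window", min = 0)
  if (nrow(sv_variants) > 0 && any(sv_variants$var_class != "SV")) {
    abort("`sv_variants` must contain var_class = \"SV\" records only")
  }
  res <- classify_denovo(sv_variants, mask, design, fraction_threshold = 1,
                         include_checks = include_checks)
  if (nrow(res) == 0) return(res)

  # evidence of an SV in any individual: any alt support, even low quality
  evidence <- sv_variants |>
    dplyr::filter(.data$alt_depth > 0 | .data$lq_alt_count > 0) |>
    dplyr::distinct(.data$chrom, .data$pos, .data$individual)

  acc <- which(res$status == "accepted")
  for (k in acc) {
    near <- evidence$chrom == res$chrom[k] &
      abs(evidence$pos - res$pos[k]) <= proximity_window &
      evidence$individual != res$carrier[k]
    if (any(near)) {
      res$status[k] <- "rejected"
      res$reason[k] <- "proximity"
    }
  }
  res
}

#' Candidate counts across carrier alt-fraction thresholds
#'
#' Re-runs the de novo acceptance with the carrier's required alternative
#' allele fraction relaxed from 1.0 down to each supplied threshold, so the
#' robustness of the count to the stringency choice can be checked (on clean
#' haploid data, relaxing from 1.0 to 0.9 should recover no additional
#' mutations).
#'
#' @inheritParams find_denovo_candidates
#' @param thresholds Numeric vector of alt-fraction thresholds in (0, 1].
#' @return A tibble: threshold, n_accepted.
#' @export
sensitivity_sweep <- function(variants, mask, design,
                              thresholds = c(0.9, 1.0),
                              include_checks = FALSE) {
  if (any(thresholds <= 0 | thresholds > 1)) {
    abort("`thresholds` must lie in (0, 1]")
  }
  purrr::map_dfr(thresholds, function(th) {
    res <- classify_denovo(variants, mask, design, fraction_threshold = th,
                           include_checks = include_checks)
    tibble(threshold = th, n_accepted = sum(res$status == "accepted"))
  })
}
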