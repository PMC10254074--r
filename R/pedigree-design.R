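#' Describe a haploid pedigree sequencing design
#'
#' A pedigree design names the sequenced individuals and their roles: the two
#' (haploid) parents whose cross produced the diploid sporophyte, the meiotic
#' haploid progeny used to count de novo mutations, and optionally extra
#' "check" individuals (e.g. grandparents or uncles) that are only used to
#' veto candidates, never to carry them. `generations` is the number of
#' meioses separating each progeny from the parental genotypes (g = 1 for a
#' direct parent-offspring design).
#'
#' @param parents Character vector of parent identifiers (usually length 2).
#' @param progeny Character vector of progeny identifiers; their count is the
#'   I of the rate denominator.
#' @param checks Optional character vector of additional individuals used
#'   only to reject candidates (any alternative read in a check individual
#'   disqualifies a candidate, as for parents).
#' @param generations Generations per progeny (g), a positive integer.
#'
#' @return An object of class `pedigree_design`.
#' @examples
#' pedigree_design(c("par_f", "par_m"), sprintf("prog_%02d", 1:30))
#' @export
pedigree_design <- function(parents, progeny, checks = character(), generations = 1L) {
  if (!is.character(parents) || length(parents) < 1L) {
    abort("`parents` must be a non-empty character vector")
  }
  if (!is.character(progeny) || length(progeny) < 1L) {
    abort("`progeny` must be a non-empty character vector")
  }
  all_ids <- c(parents, progeny, checks)
  if (anyDuplicated(all_ids)) {
    abort(sprintf(
      "individual identifiers must be unique; duplicated: %s",
      paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")
    ))
  }
  check_number(generations, "generations", min = 1, integer = TRUE)
  structure(
    list(
      parents = parents,
      progeny = progeny,
      checks = as.character(checks),
      generations = as.integer(generations)
    ),
    class = "pedigree_design"
  )
}

#' @export
print.pedigree_design <- function(x, ...) {
  cat("<pedigree_design>\n")
  cat("  parents :", paste(x$parents, collapse = ", "), "\n")
  cat("  progeny :", length(x$progeny), "individuals\n")
  if (length(x$checks)) cat("  checks  :", paste(x$checks, collapse = ", "), "\n")
  cat("  g       :", x$generations, "generation(s) per progeny\n")
  invisible(x)
}

# individuals whose read support is inspected when filtering, in role order
design_individuals <- function(design, include_checks = FALSE) {
  c(design$parents, design$progeny, if (include_checks) design$checks)
}
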