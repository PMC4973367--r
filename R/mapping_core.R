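#' Locus filter configuration
#'
#' `min_coverage` is the minimum number of informative reads (`ref + alt`
#' from AD) required in *each* of the two samples; the default of 20
#' matches the exome-mapping practice of requiring coverage of at least 20
#' in both the affected pool and the parental DNA. `hom_alt_fraction`
#' operationalizes "homozygous for the variant allele" from read counts:
#' a sample is called alt-homozygous when its alt fraction is at least
#' this value; 0.95 tolerates ~1% sequencing error at depth 20 without
#' misclassifying a true homozygote.
#'
#' @param min_coverage Minimum per-sample informative depth (>= 1).
#' @param hom_alt_fraction Alt fraction at or above which a sample counts
#'   as homozygous alt (in (0.5, 1]).
#' @return A validated list of class `"filter_config"`.
#' @export
filter_config <- function(min_coverage = 20, hom_alt_fraction = 0.95) {
  if (min_coverage < 1) stop("min_coverage must be >= 1", call. = FALSE)
  if (hom_alt_fraction <= 0.5 || hom_alt_fraction > 1)
    stop("hom_alt_fraction must be in (0.5, 1]", call. = FALSE)
  structure(list(min_coverage = min_coverage,
                 hom_alt_fraction = hom_alt_fraction),
            class = "filter_config")
}

#' Classify a locus against the mapping filters
#'
#' A locus fails `low_coverage_pool` if the pool's informative depth is
#' below `min_coverage` (checked first), then `low_coverage_parents`
#' likewise, then `shared_homozygous` if the alt fraction reaches
#' `hom_alt_fraction` in *both* samples (such loci are uninformative
#' strain background, homozygous alt in mutants and parents alike);
#' otherwise it passes. Vectorized over loci.
#'
#' @param pool_ref,pool_alt,parents_ref,parents_alt Non-negative counts.
#' @param cfg A [filter_config()].
#' @return Character vector: `"pass"`, `"low_coverage_pool"`,
#'   `"low_coverage_parents"` or `"shared_homozygous"`.
#' @export
filter_locus <- function(pool_ref, pool_alt, parents_ref, parents_alt,
                         cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (any(c(pool_ref, pool_alt, parents_ref, parents_alt) < 0))
    stop("negative allele counts", call. = FALSE)
  pool_tot <- pool_ref + pool_alt
  par_tot <- parents_ref + parents_alt
  status <- rep("pass", length(pool_tot))
  hom_both <- pool_alt >= cfg$hom_alt_fraction * pool_tot &
    parents_alt >= cfg$hom_alt_fraction * par_tot
  status[hom_both] <- "shared_homozygous"
  status[par_tot < cfg$min_coverage] <- "low_coverage_parents"
  status[pool_tot < cfg$min_coverage] <- "low_coverage_pool"
  status
}

#' Allele-frequency difference at a locus
#'
#' The mapping statistic: the percentage of reads showing the variant in
#' the parental sample subtracted from the percentage in the affected
#' pool, in absolute value. Vectorized over loci.
#'
#' @param pool_ref,pool_alt,parents_ref,parents_alt Counts; both totals
#'   must be positive (filter first).
#' @return A tibble with `pool_af`, `parent_af` (percent) and `delta`
#'   (percentage points).
#' @export
#' @examples
#' delta_af(0, 40, 20, 20)   # causal-locus pattern: 100% vs 50% -> 50
delta_af <- function(pool_ref, pool_alt, parents_ref, parents_alt) {
  pool_tot <- pool_ref + pool_alt
  par_tot <- parents_ref + parents_alt
  if (any(pool_tot <= 0) || any(par_tot <= 0))
    stop("undefined allele frequency: zero total depth; ",
         "apply the coverage filter first", call. = FALSE)
  pool_af <- 100 * pool_alt / pool_tot
  parent_af <- 100 * parents_alt / par_tot
  tibble::tibble(pool_af = pool_af, parent_af = parent_af,
                 delta = abs(pool_af - parent_af))
}

#' Filter loci and compute the mapping statistic
#'
#' Annotates every input locus with its filter status and computes
#' `pool_af`, `parent_af` and `delta` for passing loci (`NA` otherwise).
#' Input order is preserved.
#'
#' @param records A `pooled_counts` tibble from [read_paired_vcf()] or
#'   [simulate_cross()].
#' @param cfg A [filter_config()].
#' @param verbose Log a per-status summary via `message()`.
#' @return The input tibble with columns `filter_status`, `pool_af`,
#'   `parent_af`, `delta` appended; class `"mapping_records"`.
#' @export
run_mapping <- function(records, cfg = filter_config(), verbose = TRUE) {
  out <- records
  out$filter_status <- if (nrow(out) == 0L) character() else
    filter_locus(out$pool_ref, out$pool_alt,
                 out$parents_ref, out$parents_alt, cfg)
  out$pool_af <- NA_real_
  out$parent_af <- NA_real_
  out$delta <- NA_real_
  ok <- out$filter_status == "pass"
  if (any(ok)) {
    af <- delta_af(out$pool_ref[ok], out$pool_alt[ok],
                   out$parents_ref[ok], out$parents_alt[ok])
    out$pool_af[ok] <- af$pool_af
    out$parent_af[ok] <- af$parent_af
    out$delta[ok] <- af$delta
  }
  if (verbose) {
    tab <- table(factor(out$filter_status,
                        levels = c("pass", "low_coverage_pool",
                                   "low_coverage_parents",
                                   "shared_homozygous")))
    message("run_mapping: ", paste(names(tab), tab, sep = "=",
                                   collapse = ", "))
  }
  class(out) <- unique(c("mapping_records", class(out)))
  out
}
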