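#' Expected allele-frequency difference under recessive selection
#'
#' Analytic expectation of the mapping statistic in the infinite-pool,
#' infinite-depth limit, obtained by enumerating the four equally likely
#' parental-haplotype transmissions and conditioning on affected
#' (homozygous-mutant) offspring. Each parent transmits its mutant or
#' non-mutant causal haplotype with probability 1/2; only mut/mut
#' offspring enter the pool. At a locus with recombination fraction \eqn{r}
#' to the causal mutation, the transmitted allele comes from the
#' transmitted causal haplotype with probability `1 - r` and from the
#' other with probability \eqn{r}.
#'
#' Canonical cases (\eqn{r = 0} unless noted): a variant on the mutant
#' haplotype of both parents gives 50 pp (pool 100% vs parents 50%); on
#' the mutant haplotype of exactly one parent, 25 pp (pool 50% vs parents
#' 25%); an unlinked variant (\eqn{r = 0.5}) heterozygous in both parents,
#' 0 pp (pool and parents both 50%).
#'
#' @param alt_on Logical (or 0/1) vector of length 4 naming which parental
#'   haplotypes carry the alt allele, in order `p1_mut`, `p1_other`,
#'   `p2_mut`, `p2_other` ("mut" = the haplotype bearing the causal
#'   mutation).
#' @param r Recombination fraction between the locus and the causal
#'   mutation (0 = complete linkage, 0.5 = unlinked).
#' @return Expected delta in percentage points.
#' @export
#' @examples
#' expected_delta_recessive(c(1, 0, 1, 0), r = 0)    # 50
#' expected_delta_recessive(c(1, 0, 0, 0), r = 0)    # 25
#' expected_delta_recessive(c(1, 0, 1, 0), r = 0.5)  # 0
expected_delta_recessive <- function(alt_on, r = 0) {
  stopifnot(length(alt_on) == 4L, r >= 0, r <= 0.5)
  alt_on <- as.numeric(alt_on)
  p1 <- alt_on[1:2]  # (mut, other) of parent 1
  p2 <- alt_on[3:4]
  haps <- c("mut", "other")
  total_w <- 0
  dosage <- 0
  for (h1 in haps) for (h2 in haps) {
    w <- 0.25  # each transmission pattern equally likely
    if (h1 != "mut" || h2 != "mut") next  # offspring not affected
    total_w <- total_w + w
    # P(alt transmitted | transmitted causal haplotype)
    a1 <- (1 - r) * p1[match(h1, haps)] + r * p1[match(setdiff(haps, h1), haps)]
    a2 <- (1 - r) * p2[match(h2, haps)] + r * p2[match(setdiff(haps, h2), haps)]
    dosage <- dosage + w * (a1 + a2)
  }
  pool_frac <- dosage / total_w / 2
  parent_frac <- sum(alt_on) / 4
  100 * abs(pool_frac - parent_frac)
}

#' Canonical recessive-linkage expectations
#'
#' The three textbook scenarios behind the heat-map signature of a linked
#' region: background loci pile up near 0 pp while the linked peak shows
#' loci at 25 and 50 pp.
#'
#' @return A tibble with columns `scenario`, \eqn{r}, and `expected_delta_pp`.
#' @export
expected_delta_scenarios <- function() {
  tibble::tibble(
    scenario = c("causal_or_cis_both_parents", "cis_one_parent", "unlinked"),
    r = c(0, 0, 0.5),
    expected_delta_pp = c(
      expected_delta_recessive(c(1, 0, 1, 0), r = 0),
      expected_delta_recessive(c(1, 0, 0, 0), r = 0),
      expected_delta_recessive(c(1, 0, 1, 0), r = 0.5)
    )
  )
}

#' Haldane map function
#'
#' Recombination fraction for a genetic distance `d` in Morgans under
#' crossover counts that are Poisson without interference:
#' \eqn{r = (1 - e^{-2d})/2}.
#'
#' @param d_morgans Genetic distance in Morgans.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_morgans) (1 - exp(-2 * d_morgans)) / 2
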