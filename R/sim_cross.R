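#' Configuration of a simulated recessive F2 intercross
#'
#' Parameterizes a cross of two carrier parents, each heterozygous for the
#' causal mutation, from which `n_affected` homozygous-mutant offspring are
#' pooled and sequenced together with the parental DNA. Defaults emulate a
#' zebrafish-scale experiment: 25 chromosomes of 50 Mb, ~2 cM/Mb, an
#' exome-scale set of 20,000 biallelic variant loci, a pool of 20 affected
#' embryos and mean per-locus depth 30 with 1% per-read error.
#'
#' By convention haplotype "mut" of each parent is the one carrying the
#' causal alt allele. `n_cis_markers_both` / `n_cis_markers_one` place
#' additional marker loci at `causal_pos_bp + 1, + 2, ...` (distinct
#' positions one base apart, i.e. effectively complete linkage) on the
#' mutant haplotype of both parents or of parent 1 only; these are the
#' loci whose expected delta is 50 resp. 25 percentage points, and they are
#' flagged in the truth table for parameter-recovery tests.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths_bp Integer vector of chromosome lengths in bp.
#' @param cm_per_mb Genetic-map density, centimorgan per megabase.
#' @param n_variant_loci Number of candidate biallelic loci scattered
#'   uniformly over the genome. Positions are deduplicated and loci whose
#'   alt allele lands on no parental chromosome are dropped (a variant
#'   caller never sees them), so the realized locus count is lower: about
#'   `1 - (1 - het_rate_per_parent)^2` of the candidates.
#' @param het_rate_per_parent Probability that a non-causal locus is
#'   heterozygous in a given parent.
#' @param causal_chrom,causal_pos_bp Location of the causal mutation;
#'   defaults to the middle of chromosome 6 (or of the last chromosome for
#'   smaller karyotypes).
#' @param n_affected Number of pooled affected offspring.
#' @param mean_depth Mean per-locus per-sample sequencing depth (Poisson).
#' @param seq_error Per-read allele misread probability (symmetric flip).
#' @param n_cis_markers_both,n_cis_markers_one Counts of fully linked cis
#'   markers heterozygous in both parents / in parent 1 only.
#' @param master_seed Integer master seed; all stages derive substreams
#'   from it (see [stage_seed()]).
#' @param max_rejection_draws Cap on offspring draws during rejection
#'   sampling of affected individuals.
#' @return A validated list of class `"cross_config"`.
#' @export
#' @examples
#' cfg <- cross_config(n_variant_loci = 500, master_seed = 1)
cross_config <- function(n_chromosomes = 25,
                         chrom_lengths_bp = rep(50e6, n_chromosomes),
                         cm_per_mb = 2,
                         n_variant_loci = 20000,
                         het_rate_per_parent = 0.3,
                         causal_chrom = min(6, n_chromosomes),
                         causal_pos_bp = floor(chrom_lengths_bp[causal_chrom] / 2),
                         n_affected = 20,
                         mean_depth = 30,
                         seq_error = 0.01,
                         n_cis_markers_both = 0,
                         n_cis_markers_one = 0,
                         master_seed = 1,
                         max_rejection_draws = 10000 * n_affected) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths_bp = as.numeric(chrom_lengths_bp),
    cm_per_mb = as.numeric(cm_per_mb),
    n_variant_loci = as.integer(n_variant_loci),
    het_rate_per_parent = as.numeric(het_rate_per_parent),
    causal_chrom = as.integer(causal_chrom),
    causal_pos_bp = as.numeric(causal_pos_bp),
    n_affected = as.integer(n_affected),
    mean_depth = as.numeric(mean_depth),
    seq_error = as.numeric(seq_error),
    n_cis_markers_both = as.integer(n_cis_markers_both),
    n_cis_markers_one = as.integer(n_cis_markers_one),
    master_seed = as.integer(master_seed),
    max_rejection_draws = as.numeric(max_rejection_draws)
  )
  if (cfg$n_chromosomes < 1L)
    stop("configuration error: need at least one chromosome", call. = FALSE)
  if (length(cfg$chrom_lengths_bp) != cfg$n_chromosomes)
    stop("configuration error: chrom_lengths_bp length != n_chromosomes",
         call. = FALSE)
  if (any(cfg$chrom_lengths_bp <= 0))
    stop("configuration error: zero-length chromosome", call. = FALSE)
  if (cfg$n_affected < 1L)
    stop("configuration error: n_affected must be >= 1", call. = FALSE)
  if (cfg$het_rate_per_parent < 0 || cfg$het_rate_per_parent > 1)
    stop("configuration error: het_rate_per_parent must be in [0, 1]",
         call. = FALSE)
  if (cfg$seq_error < 0 || cfg$seq_error >= 0.5)
    stop("configuration error: seq_error must be in [0, 0.5)", call. = FALSE)
  if (cfg$causal_chrom < 1L || cfg$causal_chrom > cfg$n_chromosomes)
    stop("configuration error: causal_chrom out of range", call. = FALSE)
  if (cfg$causal_pos_bp < 1 ||
      cfg$causal_pos_bp > cfg$chrom_lengths_bp[cfg$causal_chrom])
    stop("configuration error: causal_pos_bp outside causal chromosome",
         call. = FALSE)
  if (cfg$cm_per_mb < 0)
    stop("configuration error: cm_per_mb must be >= 0", call. = FALSE)
  if (cfg$mean_depth < 0)
    stop("configuration error: mean_depth must be >= 0", call. = FALSE)
  structure(cfg, class = "cross_config")
}

# Random ref base and a distinct alt base per locus.
sample_ref_alt <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Place variant loci and assign parental haplotypes
#'
#' Loci are scattered uniformly over the genome (chromosome chosen
#' proportional to its length, position uniform, duplicated positions
#' dropped). Each non-causal locus is independently heterozygous in each
#' parent with probability `het_rate_per_parent`, the alt allele landing on
#' a uniformly chosen haplotype. The causal locus carries the alt allele on
#' exactly one haplotype of each parent (the "mut" haplotype); requested
#' cis markers are added next to it (see [cross_config()]).
#'
#' @param cfg A [cross_config()].
#' @return A tibble of class `"parent_genomes"`, one row per locus, with
#'   columns `chrom` (factor, karyotype order), `pos`, `ref`, `alt`,
#'   logical alt-presence flags `p1_mut`, `p1_other`, `p2_mut`, `p2_other`
#'   for the four parental haplotypes, and flags `is_causal`,
#'   `is_cis_both`, `is_cis_one`.
#' @export
build_parent_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "cross_config"))
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  causal_chrom <- chrom_names[cfg$causal_chrom]

  with_stage_seed(cfg$master_seed, "parents", {
    # reserved positions: causal + cis markers, one base apart
    n_cis <- cfg$n_cis_markers_both + cfg$n_cis_markers_one
    reserved_pos <- cfg$causal_pos_bp + seq_len(n_cis)
    if (n_cis > 0 &&
        max(reserved_pos) > cfg$chrom_lengths_bp[cfg$causal_chrom])
      stop("configuration error: cis markers exceed causal chromosome",
           call. = FALSE)

    ci <- sample.int(cfg$n_chromosomes, cfg$n_variant_loci, replace = TRUE,
                     prob = cfg$chrom_lengths_bp)
    pos <- floor(runif(cfg$n_variant_loci) * cfg$chrom_lengths_bp[ci]) + 1
    keep <- !duplicated(paste0(ci, ":", pos)) &
      !(ci == cfg$causal_chrom & pos %in% c(cfg$causal_pos_bp, reserved_pos))
    ci <- ci[keep]; pos <- pos[keep]
    n <- length(pos)

    het1 <- runif(n) < cfg$het_rate_per_parent
    het2 <- runif(n) < cfg$het_rate_per_parent
    on_mut1 <- runif(n) < 0.5
    on_mut2 <- runif(n) < 0.5

    loci <- tibble::tibble(
      chrom_idx = ci, pos = pos,
      p1_mut = het1 & on_mut1, p1_other = het1 & !on_mut1,
      p2_mut = het2 & on_mut2, p2_other = het2 & !on_mut2,
      is_causal = FALSE, is_cis_both = FALSE, is_cis_one = FALSE
    )
    # a locus carried by no parental chromosome is invisible to a variant
    # caller; only polymorphic loci enter the call set
    loci <- loci[loci$p1_mut | loci$p1_other | loci$p2_mut | loci$p2_other, ,
                 drop = FALSE]

    special <- tibble::tibble(
      chrom_idx = cfg$causal_chrom,
      pos = c(cfg$causal_pos_bp, reserved_pos),
      p1_mut = TRUE,
      p1_other = FALSE,
      p2_mut = c(TRUE, rep(TRUE, cfg$n_cis_markers_both),
                 rep(FALSE, cfg$n_cis_markers_one)),
      p2_other = FALSE,
      is_causal = c(TRUE, rep(FALSE, n_cis)),
      is_cis_both = c(FALSE, rep(TRUE, cfg$n_cis_markers_both),
                      rep(FALSE, cfg$n_cis_markers_one)),
      is_cis_one = c(FALSE, rep(FALSE, cfg$n_cis_markers_both),
                     rep(TRUE, cfg$n_cis_markers_one))
    )

    loci <- dplyr::bind_rows(loci, special)
    loci <- loci[order(loci$chrom_idx, loci$pos), , drop = FALSE]
    ra <- sample_ref_alt(nrow(loci))
    out <- tibble::tibble(
      chrom = factor(chrom_names[loci$chrom_idx], levels = chrom_names),
      pos = loci$pos, ref = ra$ref, alt = ra$alt,
      p1_mut = loci$p1_mut, p1_other = loci$p1_other,
      p2_mut = loci$p2_mut, p2_other = loci$p2_other,
      is_causal = loci$is_causal,
      is_cis_both = loci$is_cis_both, is_cis_one = loci$is_cis_one
    )
    class(out) <- c("parent_genomes", class(out))
    out
  })
}

#' Simulate one gamete from a pair of parental haplotypes
#'
#' Meiosis under the Haldane model: the crossover count on a chromosome is
#' Poisson with mean equal to its genetic length in Morgans
#' (`length_bp * cm_per_mb / 100 / 1e6`), crossover positions are uniform
#' and interference-free, and the gamete alternates source haplotype at
#' each crossover, starting from either haplotype with probability 1/2.
#' Uses the current RNG state.
#'
#' @param h1,h2 Logical vectors: alt-allele presence on each haplotype at
#'   the loci in `pos`.
#' @param pos Base-pair positions of the loci (need not be sorted).
#' @param chrom_length_bp Chromosome length in bp.
#' @param cm_per_mb Map density in cM/Mb.
#' @return Logical vector of alt-allele presence on the gamete.
#' @export
simulate_gamete <- function(h1, h2, pos, chrom_length_bp, cm_per_mb) {
  stopifnot(length(h1) == length(h2), length(pos) == length(h1))
  morgans <- chrom_length_bp * cm_per_mb / 100 / 1e6
  n_xo <- rpois(1L, morgans)
  start_h1 <- runif(1) < 0.5
  if (n_xo == 0L) {
    return(if (start_h1) h1 else h2)
  }
  cuts <- sort(runif(n_xo, 0, chrom_length_bp))
  seg <- findInterval(pos, cuts)
  use_h1 <- xor(seg %% 2L == 1L, start_h1)
  ifelse(use_h1, h1, h2)
}

#' Simulate the phenotype-selected affected pool
#'
#' Draws offspring as one gamete per parent and keeps only those homozygous
#' for the causal alt allele (rejection sampling; acceptance probability
#' 1/4 in expectation) until `n_affected` are pooled. Returns true
#' chromosome counts at every locus for both the pool (out of
#' `2 * n_affected` chromosomes) and the parents (out of 4).
#'
#' @param cfg A [cross_config()].
#' @param parents Optional precomputed [build_parent_genomes()] result;
#'   built from `cfg` if missing.
#' @return A tibble of class `"pool_truth"`: the parent-genome columns plus
#'   `parent_alt_count`, `pool_alt_count`, `parent_alt_frac`,
#'   `pool_alt_frac`.
#' @export
simulate_affected_pool <- function(cfg, parents = build_parent_genomes(cfg)) {
  stopifnot(inherits(cfg, "cross_config"))
  chrom_levels <- levels(parents$chrom)
  idx_by_chrom <- split(seq_len(nrow(parents)), parents$chrom)
  causal_row <- which(parents$is_causal)
  stopifnot(length(causal_row) == 1L)
  causal_chrom <- as.character(parents$chrom[causal_row])
  ci_idx <- idx_by_chrom[[causal_chrom]]
  causal_within <- match(causal_row, ci_idx)
  causal_len <- cfg$chrom_lengths_bp[match(causal_chrom, chrom_levels)]

  pool_count <- integer(nrow(parents))
  with_stage_seed(cfg$master_seed, "pool", {
    accepted <- 0L
    draws <- 0L
    while (accepted < cfg$n_affected) {
      draws <- draws + 1L
      if (draws > cfg$max_rejection_draws)
        stop("simulation error: rejection-sampling cap exceeded (",
             cfg$max_rejection_draws, " draws)", call. = FALSE)
      # causal chromosome first; other chromosomes only if offspring kept
      g1 <- simulate_gamete(parents$p1_mut[ci_idx], parents$p1_other[ci_idx],
                            parents$pos[ci_idx], causal_len, cfg$cm_per_mb)
      g2 <- simulate_gamete(parents$p2_mut[ci_idx], parents$p2_other[ci_idx],
                            parents$pos[ci_idx], causal_len, cfg$cm_per_mb)
      if (!(g1[causal_within] && g2[causal_within])) next
      accepted <- accepted + 1L
      pool_count[ci_idx] <- pool_count[ci_idx] + g1 + g2
      for (ch in chrom_levels) {
        if (ch == causal_chrom) next
        idx <- idx_by_chrom[[ch]]
        if (length(idx) == 0L) next
        len <- cfg$chrom_lengths_bp[match(ch, chrom_levels)]
        o1 <- simulate_gamete(parents$p1_mut[idx], parents$p1_other[idx],
                              parents$pos[idx], len, cfg$cm_per_mb)
        o2 <- simulate_gamete(parents$p2_mut[idx], parents$p2_other[idx],
                              parents$pos[idx], len, cfg$cm_per_mb)
        pool_count[idx] <- pool_count[idx] + o1 + o2
      }
    }
  })

  out <- parents
  out$parent_alt_count <- as.integer(
    parents$p1_mut + parents$p1_other + parents$p2_mut + parents$p2_other)
  out$pool_alt_count <- pool_count
  out$parent_alt_frac <- out$parent_alt_count / 4
  out$pool_alt_frac <- out$pool_alt_count / (2 * cfg$n_affected)
  class(out) <- c("pool_truth", setdiff(class(parents), "parent_genomes"))
  out
}

#' Sample sequencing read counts at a locus
#'
#' The alt read count is binomial with success probability
#' `f * (1 - e) + (1 - f) * e`, the true alt-chromosome fraction `f`
#' perturbed by a symmetric per-read misread probability `e`. Vectorized;
#' uses the current RNG state.
#'
#' @param true_alt_fraction True alt fraction(s) in `[0, 1]`.
#' @param depth Total read depth(s), non-negative.
#' @param seq_error Per-read misread probability.
#' @return A list with integer vectors `ref` and `alt` (`ref + alt = depth`).
#' @export
sample_read_counts <- function(true_alt_fraction, depth, seq_error = 0) {
  if (any(true_alt_fraction < 0 | true_alt_fraction > 1))
    stop("true_alt_fraction must be in [0, 1]", call. = FALSE)
  if (any(depth < 0)) stop("depth must be >= 0", call. = FALSE)
  p <- true_alt_fraction * (1 - seq_error) +
    (1 - true_alt_fraction) * seq_error
  n <- max(length(true_alt_fraction), length(depth))
  depth <- rep_len(as.integer(depth), n)
  p <- rep_len(p, n)
  alt <- rbinom(n, depth, p)
  list(ref = depth - alt, alt = alt)
}

# Draw per-sample depths and read counts for a simulated truth table,
# under the "reads" substream. Returns a pooled_counts tibble.
sample_pool_reads <- function(truth, cfg) {
  with_stage_seed(cfg$master_seed, "reads", {
    n <- nrow(truth)
    pool_dp <- rpois(n, cfg$mean_depth)
    par_dp <- rpois(n, cfg$mean_depth)
    pool <- sample_read_counts(truth$pool_alt_frac, pool_dp, cfg$seq_error)
    par <- sample_read_counts(truth$parent_alt_frac, par_dp, cfg$seq_error)
    new_pooled_counts(tibble::tibble(
      chrom = as.character(truth$chrom), pos = truth$pos,
      ref = truth$ref, alt = truth$alt,
      pool_ref = pool$ref, pool_alt = pool$alt,
      parents_ref = par$ref, parents_alt = par$alt
    ), chrom_levels = levels(truth$chrom))
  })
}

vcf_header_lines <- function(sample_name, chrom_names, chrom_lengths) {
  c("##fileformat=VCFv4.2",
    "##source=poolmap_simulator",
    sprintf("##contig=<ID=%s,length=%d>", chrom_names,
            as.integer(chrom_lengths)),
    paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
           "Description=\"Read depth\">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths for the ref and alt alleles\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
}

write_sim_vcf <- function(counts, ref_col, alt_col, sample_name, path,
                          chrom_names, chrom_lengths) {
  rd <- counts[[ref_col]]
  ad <- counts[[alt_col]]
  rows <- paste(counts$chrom, format(counts$pos, scientific = FALSE,
                                     trim = TRUE),
                ".", counts$ref, counts$alt, ".", "PASS", ".",
                "DP:AD",
                paste0(rd + ad, ":", rd, ",", ad), sep = "\t")
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(c(vcf_header_lines(sample_name, chrom_names, chrom_lengths),
               rows), con, sep = "\n")
  invisible(path)
}

#' Write simulated pool and parent VCFs plus a truth table
#'
#' Emits one VCF 4.2 file per sample set (FORMAT `DP:AD`, depths drawn
#' Poisson(`mean_depth`) under the `"reads"` substream, records sorted by
#' chromosome then position) and a tab-separated truth table with the true
#' alt fractions and the causal/cis-marker flags.
#'
#' @param truth A [simulate_affected_pool()] result.
#' @param cfg The [cross_config()] used to generate `truth`.
#' @param out_pool,out_parents,out_truth Output file paths.
#' @return Invisibly, a list with the three paths and the sampled
#'   `counts` tibble.
#' @export
emit_vcfs <- function(truth, cfg, out_pool, out_parents,
                      out_truth = file.path(dirname(out_pool), "truth.tsv")) {
  stopifnot(inherits(truth, "pool_truth"))
  counts <- sample_pool_reads(truth, cfg)
  chrom_names <- levels(truth$chrom)
  write_sim_vcf(counts, "pool_ref", "pool_alt", "affected_pool", out_pool,
                chrom_names, cfg$chrom_lengths_bp)
  write_sim_vcf(counts, "parents_ref", "parents_alt", "parents", out_parents,
                chrom_names, cfg$chrom_lengths_bp)
  truth_tab <- tibble::tibble(
    chrom = as.character(truth$chrom), pos = truth$pos,
    ref = truth$ref, alt = truth$alt,
    parent_alt_frac = truth$parent_alt_frac,
    pool_alt_frac = truth$pool_alt_frac,
    is_causal = truth$is_causal,
    is_cis_both = truth$is_cis_both, is_cis_one = truth$is_cis_one
  )
  readr::write_tsv(truth_tab, out_truth, progress = FALSE)
  invisible(list(pool = out_pool, parents = out_parents, truth = out_truth,
                 counts = counts))
}

#' Run the full cross simulation
#'
#' Convenience wrapper: builds the parental genomes, segregates the
#' affected pool, samples read counts, and (optionally) writes the VCF and
#' truth files. The same `master_seed` yields byte-identical files.
#'
#' @param cfg A [cross_config()].
#' @param out_dir Output directory for `pool.vcf`, `parents.vcf`,
#'   `truth.tsv`; if `NULL` nothing is written.
#' @return A list with `truth` (tibble incl. true fractions), `counts`
#'   (per-locus sampled read counts, [read_paired_vcf()]-compatible),
#'   `paths` (or `NULL`), and `cfg`.
#' @export
#' @examples
#' sim <- simulate_cross(cross_config(n_variant_loci = 200, master_seed = 7))
#' head(sim$counts)
simulate_cross <- function(cfg, out_dir = NULL) {
  truth <- simulate_affected_pool(cfg)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- emit_vcfs(truth, cfg,
                       out_pool = file.path(out_dir, "pool.vcf"),
                       out_parents = file.path(out_dir, "parents.vcf"),
                       out_truth = file.path(out_dir, "truth.tsv"))
    counts <- paths$counts
    paths$counts <- NULL
  } else {
    counts <- sample_pool_reads(truth, cfg)
  }
  list(truth = truth, counts = counts, paths = paths, cfg = cfg)
}
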