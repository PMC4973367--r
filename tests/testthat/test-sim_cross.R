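test_that("cross_config rejects invalid parameterizations", {
  expect_error(cross_config(n_chromosomes = 2, chrom_lengths_bp = c(1e6, 0)),
               "zero-length")
  expect_error(cross_config(seq_error = 0.5), "seq_error")
  expect_error(cross_config(het_rate_per_parent = 1.2), "het_rate")
  expect_error(cross_config(causal_chrom = 3, n_chromosomes = 2,
                            chrom_lengths_bp = rep(1e6, 2)),
               "causal_chrom")
  expect_error(cross_config(causal_pos_bp = 2e6, n_chromosomes = 1,
                            chrom_lengths_bp = 1e6), "causal_pos")
})

test_that("parental genomes respect the carrier design", {
  # degenerate het rate: only the causal locus is polymorphic
  cfg0 <- small_cross_cfg(1, n_loci = 300, het_rate_per_parent = 0)
  pg0 <- build_parent_genomes(cfg0)
  expect_equal(nrow(pg0), 1L)
  expect_true(pg0$is_causal)

  # causal locus: alt on exactly one haplotype of each parent (2 of 4)
  cfg <- small_cross_cfg(2, n_loci = 500)
  pg <- build_parent_genomes(cfg)
  causal <- pg[pg$is_causal, ]
  expect_equal(causal$p1_mut + causal$p1_other +
                 causal$p2_mut + causal$p2_other, 2)
  expect_true(causal$p1_mut && causal$p2_mut)
  expect_false(any(duplicated(paste(pg$chrom, pg$pos))))
  expect_true(all(pg$ref != pg$alt))

  # degenerate het rate 1: every locus heterozygous in parent 1
  cfg1 <- small_cross_cfg(3, n_loci = 1000, het_rate_per_parent = 1)
  pg1 <- build_parent_genomes(cfg1)
  expect_equal(mean(pg1$p1_mut | pg1$p1_other), 1.0)
})

test_that("gametes follow the Haldane meiosis model", {
  # zero map length: gamete is one intact parental haplotype
  h1 <- rep(TRUE, 10); h2 <- rep(FALSE, 10)
  pos <- sort(runif(10, 1, 1e6))
  withr::with_seed(1, {
    g <- simulate_gamete(h1, h2, pos, 1e6, cm_per_mb = 0)
    expect_true(all(g) || all(!g))
  })

  # loci at identical positions are always co-inherited
  withr::with_seed(2, {
    for (i in 1:200) {
      g <- simulate_gamete(c(TRUE, TRUE), c(FALSE, FALSE), c(5e6, 5e6),
                           1e7, cm_per_mb = 4)
      expect_equal(g[1], g[2])
    }
  })
})

test_that("recombination fraction matches Haldane's map function", {
  # two loci 50 cM apart (25 Mb at 2 cM/Mb): r = (1 - exp(-1)) / 2
  n <- 20000
  withr::with_seed(7, {
    rec <- vapply(seq_len(n), function(i) {
      g <- simulate_gamete(c(TRUE, TRUE), c(FALSE, FALSE),
                           c(1, 25e6 + 1), 30e6, cm_per_mb = 2)
      g[1] != g[2]
    }, NA)
  })
  r_exp <- haldane_r(0.5)
  se <- sqrt(r_exp * (1 - r_exp) / n)
  expect_lt(abs(mean(rec) - r_exp), 3 * se)
})

test_that("affected pool is fixed for the causal allele", {
  cfg <- small_cross_cfg(4, n_loci = 300, n_affected = 12)
  truth <- simulate_affected_pool(cfg)
  expect_equal(truth$pool_alt_count[truth$is_causal], 2L * 12L)
  expect_equal(truth$parent_alt_count[truth$is_causal], 2L)
  expect_true(all(truth$pool_alt_count >= 0 &
                    truth$pool_alt_count <= 2 * cfg$n_affected))
  expect_true(all(truth$parent_alt_count >= 1 &
                    truth$parent_alt_count <= 4))
})

test_that("unlinked loci segregate randomly into the pool", {
  # hand-built parents: causal on chr1, one unlinked het-both locus on chr2
  parents <- tibble::tibble(
    chrom = factor(c("chr1", "chr2"), levels = c("chr1", "chr2")),
    pos = c(5e5, 5e5), ref = c("A", "G"), alt = c("T", "C"),
    p1_mut = c(TRUE, TRUE), p1_other = c(FALSE, FALSE),
    p2_mut = c(TRUE, TRUE), p2_other = c(FALSE, FALSE),
    is_causal = c(TRUE, FALSE),
    is_cis_both = FALSE, is_cis_one = FALSE)
  n_rep <- 200
  fracs <- vapply(seq_len(n_rep), function(i) {
    cfg <- cross_config(n_chromosomes = 2, chrom_lengths_bp = rep(1e6, 2),
                        causal_chrom = 1, causal_pos_bp = 5e5,
                        n_affected = 5, master_seed = 1000 + i)
    simulate_affected_pool(cfg, parents)$pool_alt_frac[2]
  }, 0)
  # per replicate: Binomial(2 * 5, 1/2) / 10
  se <- sqrt(0.25 / (2 * 5) / n_rep)
  expect_lt(abs(mean(fracs) - 0.5), 3 * se)
})

test_that("fully linked cis locus tracks the mutant haplotype exactly", {
  parents <- tibble::tibble(
    chrom = factor("chr1"), pos = c(4e5, 5e5), ref = c("A", "G"),
    alt = c("T", "C"),
    p1_mut = c(TRUE, TRUE), p1_other = FALSE,
    p2_mut = c(FALSE, TRUE), p2_other = FALSE,
    is_causal = c(FALSE, TRUE), is_cis_both = FALSE, is_cis_one = FALSE)
  cfg <- cross_config(n_chromosomes = 1, chrom_lengths_bp = 1e6,
                      causal_chrom = 1, causal_pos_bp = 5e5,
                      cm_per_mb = 0, n_affected = 8, master_seed = 9)
  truth <- simulate_affected_pool(cfg, parents)
  expect_equal(truth$pool_alt_frac[1], 0.5)
})

test_that("read sampling follows the binomial error model", {
  withr::with_seed(1, {
    expect_equal(sample_read_counts(1, 30, 0), list(ref = 0L, alt = 30L))
    expect_equal(sample_read_counts(0.5, 0, 0.01), list(ref = 0L, alt = 0L))
    expect_error(sample_read_counts(0.5, -1), "depth")
    expect_error(sample_read_counts(1.5, 10), "alt_fraction")
    # symmetric error model leaves a 50% site unbiased
    m <- vapply(1:100, function(i) {
      rc <- sample_read_counts(0.5, 1e4, 0.01)
      rc$alt / 1e4
    }, 0)
    se <- sqrt(0.25 / 1e4 / 100)
    expect_lt(abs(mean(m) - 0.5), 3 * se)
  })
})

test_that("emitted VCFs conserve loci, depth scale, and are deterministic", {
  cfg <- small_cross_cfg(5, n_loci = 800, mean_depth = 40)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_cross(cfg, d1)
  s2 <- simulate_cross(cfg, d2)

  n_loci <- nrow(s1$truth)
  pool_lines <- readLines(file.path(d1, "pool.vcf"))
  parents_lines <- readLines(file.path(d1, "parents.vcf"))
  n_header <- sum(startsWith(pool_lines, "#"))
  expect_equal(length(pool_lines) - n_header, n_loci)
  expect_equal(length(parents_lines) - n_header, n_loci)

  # Poisson depth: mean DP within 3 SE of mean_depth
  dp <- with(s1$counts, c(pool_ref + pool_alt, parents_ref + parents_alt))
  expect_lt(abs(mean(dp) - 40), 3 * sqrt(40 / length(dp)))

  # same master seed: byte-identical outputs
  for (f in c("pool.vcf", "parents.vcf", "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }

  # round trip through the reader recovers the emitted AD values
  counts <- read_paired_vcf(file.path(d1, "pool.vcf"),
                            file.path(d1, "parents.vcf"), verbose = FALSE)
  expect_equal(nrow(counts), n_loci)
  expect_identical(counts$pool_alt, s1$counts$pool_alt)
  expect_identical(counts$parents_ref, s1$counts$parents_ref)
})
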