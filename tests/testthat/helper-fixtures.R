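# Fixtures are built in code at test time; no binary data on disk.

# Write a minimal VCF 4.2 with DP:AD for one or more samples.
# `samples` is a named list; each element a data.frame/list with ref and
# alt depth vectors aligned to the rows of `sites` (chrom, pos, ref, alt).
write_test_vcf <- function(sites, samples, path,
                           format = "DP:AD", ad_in_format = TRUE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", names(samples)), collapse = "\t"))
  cols <- lapply(samples, function(s) {
    if (ad_in_format) paste0(s$ref + s$alt, ":", s$ref, ",", s$alt)
    else as.character(s$ref + s$alt)
  })
  rows <- if (nrow(sites) == 0L) character() else
    do.call(paste, c(list(
      sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS", ".",
      if (ad_in_format) format else "DP"), cols, list(sep = "\t")))
  writeLines(c(hdr, rows), path)
  path
}

# Paired pool/parents VCFs from a pooled-counts-like data frame. The
# default tempdir is scoped to the *caller* so the files outlive this call.
write_paired_test_vcfs <- function(df,
                                   dir = withr::local_tempdir(
                                     .local_envir = parent.frame())) {
  pool <- file.path(dir, "pool.vcf")
  parents <- file.path(dir, "parents.vcf")
  sites <- df[, c("chrom", "pos", "ref", "alt")]
  write_test_vcf(sites, list(pool = list(ref = df$pool_ref,
                                         alt = df$pool_alt)), pool)
  write_test_vcf(sites, list(parents = list(ref = df$parents_ref,
                                            alt = df$parents_alt)), parents)
  list(pool = pool, parents = parents)
}

# A three-exon toy gene on a random 600-bp chromosome, with the spliced
# CDS derived from the genome sequence so projection can be checked by an
# exhaustive walk. Exons 51-100, 151-229, 301-360 (189 nt = 63 codons).
make_toy_three_exon_gene <- function(strand = "+", seed = 42) {
  genome <- withr::with_seed(seed,
    sample(c("A", "C", "G", "T"), 600, replace = TRUE))
  exons <- data.frame(start = c(51, 151, 301), end = c(100, 229, 360))
  if (strand == "+") {
    genome[51:53] <- c("A", "T", "G")
  } else {
    genome[358:360] <- c("C", "A", "T")  # revcomp -> ATG
  }
  spliced <- unlist(lapply(seq_len(nrow(exons)), function(i)
    genome[exons$start[i]:exons$end[i]]))
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    spliced <- rev(unname(comp[spliced]))
  }
  model <- gene_model("toyg", "toyg.t1", "chrT", strand,
                      exons = exons, cds_seq = paste(spliced, collapse = ""))
  list(model = model, genome = genome, exons = exons)
}

# Single-exon plus-strand gene whose CDS is 300 CAG codons, anchored at
# genomic position 101. Glutamine repeat: any C>T at a codon start makes
# a TAG stop.
make_cag_gene <- function() {
  suppressWarnings(gene_model("cag300", "cag300.t1", "chrQ", "+",
                              exons = data.frame(start = 101, end = 1000),
                              cds_seq = strrep("CAG", 300)))
}

quiet_mapping <- function(...) run_mapping(..., verbose = FALSE)

small_cross_cfg <- function(seed, n_loci = 1500, ...) {
  cross_config(n_chromosomes = 4, chrom_lengths_bp = rep(25e6, 4),
               n_variant_loci = n_loci, causal_chrom = 2,
               causal_pos_bp = 12.5e6, master_seed = seed, ...)
}
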