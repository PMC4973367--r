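# Exhaustive walk oracle: assemble the CDS coordinate of every genomic
# base by walking the transcript base by base.
walk_cds_map <- function(model) {
  gpos <- unlist(lapply(seq_len(nrow(model$cds)), function(i)
    model$cds$start[i]:model$cds$end[i]))
  if (model$strand == "-") gpos <- rev(gpos)
  setNames(seq_along(gpos), gpos)
}

test_that("CDS projection agrees with an exhaustive transcript walk", {
  for (strand in c("+", "-")) {
    toy <- make_toy_three_exon_gene(strand)
    m <- toy$model
    cds_map <- walk_cds_map(m)
    for (pos in 40:380) {
      prj <- project_to_cds(m, pos)
      in_exon <- any(pos >= m$exons$start & pos <= m$exons$end)
      if (pos < 51 || pos > 360) {
        expect_equal(prj$type, "noncoding")
      } else if (in_exon) {
        expect_equal(prj$type, "cds")
        expect_equal(prj$cds_pos, unname(cds_map[as.character(pos)]))
      } else {
        expect_equal(prj$type, "intronic")
        # brute-force signed distance to the nearest exon boundary
        d_after <- pos - m$exons$end
        d_before <- pos - m$exons$start
        cands <- c(d_after[d_after > 0], d_before[d_before < 0])
        expect_equal(prj$distance, cands[which.min(abs(cands))])
      }
    }
    # projected base agrees with the genome (strand-aware)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (pos in c(60, 200, 350)) {
      prj <- project_to_cds(m, pos)
      g <- toy$genome[pos]
      expected <- if (strand == "-") comp[[g]] else g
      expect_equal(substr(m$cds_seq, prj$cds_pos, prj$cds_pos), expected)
    }
  }
})

test_that("a C-to-T transition in a glutamine run creates Q254*", {
  gm <- make_cag_gene()
  # spliced CDS position 760 = first base of codon 254 (CAG -> TAG)
  eff <- classify_variant(gm, pos = 101 + 759, ref = "C", alt = "T")
  expect_equal(eff$category, "nonsense")
  expect_equal(eff$cds_pos, 760L)
  expect_equal(eff$codon_index, 254L)
  expect_equal(eff$notation_dna, "C760T")
  expect_equal(eff$notation_protein, "Q254*")
  expect_equal(eff$codon_index, as.integer(ceiling(eff$cds_pos / 3)))
})

test_that("substitutions classify by codon effect and BLOSUM score", {
  gm <- gene_model("t", "t.1", "chr1", "+",
                   exons = data.frame(start = 1, end = 12),
                   cds_seq = "ATGGCTGATTAG")  # M A D *
  # wobble position: GCT -> GCC is synonymous (Ala)
  syn <- classify_variant(gm, pos = 6, ref = "T", alt = "C")
  expect_equal(syn$category, "synonymous")
  expect_equal(syn$notation_protein, "A2A")
  # GAT -> GAA: Asp -> Glu, positive BLOSUM62 score, conservative
  cons <- classify_variant(gm, pos = 9, ref = "T", alt = "A")
  expect_equal(cons$category, "missense_conservative")
  expect_equal(cons$notation_protein, "D3E")
  # GAT -> GCT: Asp -> Ala, negative score, non-conservative
  noncons <- classify_variant(gm, pos = 8, ref = "A", alt = "C")
  expect_equal(noncons$category, "missense_nonconservative")
  # reference mismatch is an error naming the locus
  expect_error(classify_variant(gm, pos = 6, ref = "G", alt = "C"),
               "reference mismatch")
  expect_error(classify_variant(gm, pos = 6, ref = "TT", alt = "C"),
               "single-base")
})

test_that("splice-site calls respect the intronic window", {
  toy <- make_toy_three_exon_gene("+")
  m <- toy$model
  # 2 bases past exon 1 end (position 102): within the default window
  expect_equal(classify_variant(m, 102, toy$genome[102],
                                setdiff(c("A", "C", "G", "T"),
                                        toy$genome[102])[1])$category,
               "splice_site")
  # 3 bases past: plain intronic, reported noncoding
  expect_equal(classify_variant(m, 103, toy$genome[103],
                                setdiff(c("A", "C", "G", "T"),
                                        toy$genome[103])[1])$category,
               "noncoding")
  # 2 bases before exon 2 start (position 149)
  expect_equal(classify_variant(m, 149, toy$genome[149],
                                setdiff(c("A", "C", "G", "T"),
                                        toy$genome[149])[1])$category,
               "splice_site")
})

test_that("classification is strand-consistent for mirrored genes", {
  # reverse-complement the whole chromosome: the minus-strand gene over
  # the mirrored intervals encodes the identical transcript, so mirrored
  # variants must classify identically
  plus <- make_toy_three_exon_gene("+")
  L <- length(plus$genome)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m_exons <- data.frame(start = L + 1 - rev(plus$exons$end),
                        end = L + 1 - rev(plus$exons$start))
  minus <- gene_model("mir", "mir.1", "chrT", "-", exons = m_exons,
                      cds_seq = plus$model$cds_seq)
  for (pos in c(51, 60, 102, 155, 200, 310, 360)) {
    ref_p <- plus$genome[pos]
    alt_p <- setdiff(c("A", "C", "G", "T"), ref_p)[1]
    e_plus <- classify_variant(plus$model, pos, ref_p, alt_p)
    e_minus <- classify_variant(minus, L + 1 - pos,
                                comp[[ref_p]], comp[[alt_p]])
    expect_equal(e_minus$category, e_plus$category)
    expect_equal(e_minus$cds_pos, e_plus$cds_pos)
    expect_equal(e_minus$notation_dna, e_plus$notation_dna)
    expect_equal(e_minus$notation_protein, e_plus$notation_protein)
  }
})

test_that("gene models round-trip through GFF3 and FASTA", {
  dir <- withr::local_tempdir()
  toy <- make_toy_three_exon_gene("+")
  gff <- file.path(dir, "m.gff3")
  ex <- toy$exons
  writeLines(c(
    "##gff-version 3",
    paste("chrT", "test", "gene", 51, 360, ".", "+", ".",
          "ID=toyg", sep = "\t"),
    paste("chrT", "test", "mRNA", 51, 360, ".", "+", ".",
          "ID=toyg.t1;Parent=toyg", sep = "\t"),
    paste("chrT", "test", "exon", ex$start, ex$end, ".", "+", ".",
          "Parent=toyg.t1", sep = "\t"),
    paste("chrT", "test", "CDS", ex$start, ex$end, ".", "+", "0",
          "Parent=toyg.t1", sep = "\t")), gff)
  fa <- file.path(dir, "m.fa")
  writeLines(c(">toyg.t1 toy transcript", toy$model$cds_seq), fa)
  models <- read_gene_models(gff, fa)
  expect_equal(names(models), "toyg")
  expect_equal(models$toyg$cds_seq, toy$model$cds_seq)
  expect_equal(models$toyg$exons$start, ex$start)
  # projection through the loaded model matches the constructed one
  expect_equal(project_to_cds(models$toyg, 200),
               project_to_cds(toy$model, 200))
})

test_that("candidate filtering keeps damaging, panel-absent variants", {
  dir <- withr::local_tempdir()
  controls <- vapply(1:5, function(i) {
    write_test_vcf(
      data.frame(chrom = "chr6", pos = if (i == 3) c(100, 500) else 500,
                 ref = "C", alt = "T"),
      list(s = list(ref = rep(10, if (i == 3) 2 else 1),
                    alt = rep(10, if (i == 3) 2 else 1))),
      file.path(dir, paste0("control", i, ".vcf")))
  }, "")
  cfg <- annotation_config(control_panels = controls)
  effects <- tibble::tibble(
    chrom = "chr6", pos = c(100, 200, 300), ref = "C", alt = "T",
    category = c("nonsense", "synonymous", "nonsense"))
  rep <- filter_candidates(effects, cfg = cfg)
  by_pos <- rep[order(rep$pos), ]
  # nonsense but present in 1 of 5 controls
  expect_false(by_pos$kept[1])
  expect_equal(by_pos$exclusion_reason[1], "in_control_panel")
  # synonymous, absent from controls: wrong effect class
  expect_false(by_pos$kept[2])
  expect_equal(by_pos$exclusion_reason[2], "effect_class")
  # nonsense, absent from all controls: the causal-call pattern
  expect_true(by_pos$kept[3])

  # idempotent on its own kept output
  again <- filter_candidates(rep[rep$kept, names(effects)], cfg = cfg)
  expect_true(all(again$kept))

  expect_error(filter_candidates(effects, cfg = annotation_config(
    control_panels = file.path(dir, "missing.vcf"))), "I/O error")

  # region restriction
  region <- tibble::tibble(chrom = "chr6", start = 250, end = 400)
  reg <- filter_candidates(effects, region = region, cfg = cfg)
  expect_equal(reg$exclusion_reason[match(100, reg$pos)], "outside_region")
})
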