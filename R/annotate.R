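#' Annotation configuration
#'
#' @param splice_window Intronic distance (bases) from an exon boundary
#'   treated as a splice-site hit; the default 2 covers the canonical
#'   donor/acceptor dinucleotides.
#' @param conservative_min_score Substitution-matrix score strictly above
#'   which a missense change counts as conservative (default 0, i.e.
#'   positive BLOSUM62 score).
#' @param control_panels Character vector of VCF paths for unrelated
#'   control exomes used to exclude shared background variants.
#' @return A validated list of class `"annotation_config"`.
#' @export
annotation_config <- function(splice_window = 2,
                              conservative_min_score = 0,
                              control_panels = character()) {
  if (splice_window < 1) stop("splice_window must be >= 1", call. = FALSE)
  structure(list(splice_window = splice_window,
                 conservative_min_score = conservative_min_score,
                 control_panels = control_panels),
            class = "annotation_config")
}

# Standard BLOSUM62 substitution matrix, from Biostrings' bundled data.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("untranslatable codon: ", codon, call. = FALSE)
  aa
}

#' Classify a single-base substitution against a gene model
#'
#' Categories follow the standard protein-level consequence ladder:
#' `splice_site` for intronic positions within `splice_window` of an exon
#' boundary; `noncoding` outside the CDS; otherwise the reference and
#' alternate codons are translated with the standard genetic code and the
#' change is `nonsense` (alt codon is a stop), `synonymous` (same
#' residue), `missense_conservative` (BLOSUM62 score above
#' `conservative_min_score`) or `missense_nonconservative`.
#'
#' @param model A [gene_model()].
#' @param pos 1-based genomic position of the substitution.
#' @param ref,alt Single reference/alternate bases (genomic strand).
#' @param cfg An [annotation_config()].
#' @return A one-row tibble: `gene_id`, `category`, `cds_pos`,
#'   `codon_index`, `ref_aa`, `alt_aa`, `notation_dna` (CDS-strand, e.g.
#'   `"C760T"`), `notation_protein` (e.g. `"Q254*"`).
#' @export
#' @examples
#' gm <- gene_model("toy", "toy.t1", "chr1", "+",
#'                  exons = data.frame(start = 101, end = 1000),
#'                  cds_seq = strrep("CAG", 300))
#' classify_variant(gm, pos = 101 + 759, ref = "C", alt = "T")
classify_variant <- function(model, pos, ref, alt,
                             cfg = annotation_config()) {
  stopifnot(inherits(model, "gene_model"))
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L ||
      !ref %in% names(comp_base) || !alt %in% names(comp_base))
    stop("only single-base substitutions are supported", call. = FALSE)
  if (ref == alt) stop("ref and alt alleles are identical", call. = FALSE)

  effect <- function(category, cds_pos = NA_integer_,
                     codon_index = NA_integer_, ref_aa = NA_character_,
                     alt_aa = NA_character_, notation_dna = NA_character_,
                     notation_protein = NA_character_) {
    tibble::tibble(gene_id = model$gene_id, category = category,
                   cds_pos = cds_pos, codon_index = codon_index,
                   ref_aa = ref_aa, alt_aa = alt_aa,
                   notation_dna = notation_dna,
                   notation_protein = notation_protein)
  }

  prj <- project_to_cds(model, pos)
  if (prj$type == "intronic") {
    if (abs(prj$distance) <= cfg$splice_window)
      return(effect("splice_site"))
    return(effect("noncoding"))
  }
  if (prj$type == "noncoding") return(effect("noncoding"))

  cds_pos <- prj$cds_pos
  ref_c <- if (model$strand == "-") comp_base[[ref]] else ref
  alt_c <- if (model$strand == "-") comp_base[[alt]] else alt
  cds_ref <- substr(model$cds_seq, cds_pos, cds_pos)
  if (cds_ref != ref_c)
    stop("reference mismatch at ", model$chrom, ":", pos,
         " (CDS position ", cds_pos, " is ", cds_ref, ", variant ref is ",
         ref_c, ")", call. = FALSE)

  codon_index <- as.integer(ceiling(cds_pos / 3))
  within <- cds_pos - (codon_index - 1L) * 3L
  codon <- substr(model$cds_seq, (codon_index - 1L) * 3L + 1L,
                  codon_index * 3L)
  alt_codon <- codon
  substr(alt_codon, within, within) <- alt_c
  ref_aa <- translate_codon(codon)
  alt_aa <- translate_codon(alt_codon)

  category <- if (alt_aa == "*" && ref_aa != "*") {
    "nonsense"
  } else if (ref_aa == alt_aa) {
    "synonymous"
  } else {
    score <- blosum62()[ref_aa, alt_aa]
    if (score > cfg$conservative_min_score) "missense_conservative"
    else "missense_nonconservative"
  }
  effect(category, cds_pos = cds_pos, codon_index = codon_index,
         ref_aa = ref_aa, alt_aa = alt_aa,
         notation_dna = paste0(ref_c, cds_pos, alt_c),
         notation_protein = paste0(ref_aa, codon_index, alt_aa))
}

#' Classify all variants in a set against gene models
#'
#' Maps each variant to the first gene model whose chromosome matches and
#' whose exon span contains it; variants hitting no model are
#' `noncoding`.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @param models Named list of [gene_model()] objects.
#' @param cfg An [annotation_config()].
#' @return `variants` with the [classify_variant()] columns appended.
#' @export
classify_region_variants <- function(variants, models,
                                     cfg = annotation_config()) {
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    hit <- NULL
    for (m in models) {
      if (m$chrom != v$chrom) next
      if (v$pos >= min(m$exons$start) && v$pos <= max(m$exons$end)) {
        hit <- m
        break
      }
    }
    if (is.null(hit)) {
      return(tibble::tibble(gene_id = NA_character_,
                            category = "noncoding",
                            cds_pos = NA_integer_,
                            codon_index = NA_integer_,
                            ref_aa = NA_character_, alt_aa = NA_character_,
                            notation_dna = NA_character_,
                            notation_protein = NA_character_))
    }
    classify_variant(hit, v$pos, v$ref, v$alt, cfg)
  })
  dplyr::bind_cols(variants, dplyr::bind_rows(rows))
}

# Variant identity keys (chrom:pos:ref:alt) present in a VCF, with
# multi-allelic records split.
read_vcf_sites <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) return(character())
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  rec <- rep.int(seq_len(nrow(fix)), lengths(alts))
  paste(fix[rec, "CHROM"], fix[rec, "POS"], fix[rec, "REF"],
        unlist(alts, use.names = FALSE), sep = ":")
}

#' Filter candidate variants by effect class and control panels
#'
#' Reproduces the candidate-narrowing step of a mapping study: within the
#' linked region, keep only variants whose predicted protein-level effect
#' is damaging (`nonsense`, `missense_nonconservative` or `splice_site`)
#' and which are absent, by exact `(chrom, pos, ref, alt)` match, from
#' every control-panel exome. All variants are reported with their
#' exclusion reason so the filtering is auditable.
#'
#' @param effects A [classify_region_variants()] result (columns `chrom`,
#'   `pos`, `ref`, `alt`, `category`).
#' @param region Optional single-row region (`chrom`, `start`, `end`),
#'   e.g. the top row of [call_linked_regions()]; variants outside it are
#'   excluded with reason `outside_region`.
#' @param cfg An [annotation_config()]; its `control_panels` VCFs are read
#'   here.
#' @return `effects` with logical `kept` and character `exclusion_reason`
#'   (`"."` for kept variants) appended; kept rows first.
#' @export
filter_candidates <- function(effects, region = NULL,
                              cfg = annotation_config()) {
  deleterious <- c("nonsense", "missense_nonconservative", "splice_site")
  control_keys <- character()
  for (p in cfg$control_panels) {
    if (!file.exists(p))
      stop("I/O error: cannot read control panel ", p, call. = FALSE)
    control_keys <- c(control_keys, read_vcf_sites(p))
  }
  key <- paste(effects$chrom, effects$pos, effects$ref, effects$alt,
               sep = ":")
  reason <- rep(".", nrow(effects))
  if (!is.null(region)) {
    outside <- effects$chrom != region$chrom[1] |
      effects$pos < region$start[1] | effects$pos > region$end[1]
    reason[outside] <- "outside_region"
  }
  bad_class <- reason == "." & !(effects$category %in% deleterious)
  reason[bad_class] <- "effect_class"
  in_panel <- reason == "." & key %in% control_keys
  reason[in_panel] <- "in_control_panel"
  out <- effects
  out$kept <- reason == "."
  out$exclusion_reason <- reason
  out[order(!out$kept), , drop = FALSE]
}
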