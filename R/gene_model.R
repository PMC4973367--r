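#' Construct a gene model
#'
#' A minimal transcript model for consequence calling: ordered exon
#' intervals, the CDS intervals they contain, and the spliced CDS
#' sequence. Intervals are genomic, 1-based inclusive; for minus-strand
#' genes the spliced CDS runs through the intervals in descending genomic
#' order with complemented bases.
#'
#' @param gene_id,tx_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end`: exon intervals,
#'   non-overlapping.
#' @param cds Data frame with columns `start`, `end`: CDS intervals (a
#'   subset of the exon footprint). Defaults to `exons`.
#' @param cds_seq Spliced CDS sequence (character or `DNAString`), 5' to
#'   3' on the coding strand; length must equal the summed CDS interval
#'   widths and be divisible by 3. A CDS not starting with ATG draws a
#'   warning, not an error.
#' @return A list of class `"gene_model"`.
#' @export
#' @examples
#' gm <- gene_model("g1", "tx1", "chr1", "+",
#'                  exons = data.frame(start = 11, end = 19),
#'                  cds_seq = "ATGAAATAG")
gene_model <- function(gene_id, tx_id = gene_id, chrom, strand,
                       exons, cds = exons, cds_seq) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  cds <- as.data.frame(cds)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (any(exons$end < exons$start) || any(cds$end < cds$start))
    stop("malformed intervals in gene model ", gene_id, call. = FALSE)
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in gene model ", gene_id, call. = FALSE)
  cds_seq <- toupper(as.character(cds_seq))
  cds_len <- sum(cds$end - cds$start + 1)
  if (nchar(cds_seq) != cds_len)
    stop("CDS sequence length (", nchar(cds_seq),
         ") does not match CDS intervals (", cds_len, ") for ", gene_id,
         call. = FALSE)
  if (cds_len %% 3 != 0)
    stop("CDS length not divisible by 3 for ", gene_id, call. = FALSE)
  if (substr(cds_seq, 1, 3) != "ATG")
    warning("CDS of ", gene_id, " does not begin with ATG", call. = FALSE)
  structure(list(gene_id = gene_id, tx_id = tx_id, chrom = chrom,
                 strand = strand, exons = exons, cds = cds,
                 cds_seq = cds_seq),
            class = "gene_model")
}

#' Read gene models from GFF3 and CDS FASTA
#'
#' Supports the GFF3 subset of `gene`, `mRNA`/`transcript`, `exon` and
#' `CDS` features linked by `ID`/`Parent` attributes. The first mRNA per
#' gene is used (a warning names genes with more). CDS sequences come
#' from a FASTA keyed by mRNA ID (text before the first space in the
#' header).
#'
#' @param gff_path Path to the GFF3 file.
#' @param cds_fasta_path Path to the FASTA of spliced CDS sequences.
#' @return A named list of [gene_model()] objects (by gene ID).
#' @export
read_gene_models <- function(gff_path, cds_fasta_path) {
  gr <- rtracklayer::import(gff_path)
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")
  seqs <- Biostrings::readDNAStringSet(cds_fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  models <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrnas[mrnas$Parent == gid, , drop = FALSE]
    if (nrow(tx) == 0L) next
    if (nrow(tx) > 1L)
      warning("gene ", gid, " has ", nrow(tx),
              " transcripts; using the first", call. = FALSE)
    tid <- tx$ID[1]
    ex <- df[df$type == "exon" & df$Parent == tid, c("start", "end")]
    cd <- df[df$type == "CDS" & df$Parent == tid, c("start", "end")]
    if (nrow(cd) == 0L) cd <- ex
    if (!tid %in% names(seqs))
      stop("no CDS sequence for transcript ", tid, " in ",
           basename(cds_fasta_path), call. = FALSE)
    models[[gid]] <- gene_model(
      gene_id = gid, tx_id = tid,
      chrom = as.character(genes$seqnames[i]),
      strand = as.character(genes$strand[i]),
      exons = ex, cds = cd, cds_seq = seqs[[tid]])
  }
  models
}

#' Project a genomic position onto the spliced CDS
#'
#' Maps a 1-based genomic coordinate through the model's CDS intervals to
#' a 1-based position in the spliced CDS, strand-aware (minus-strand
#' genes traverse intervals in descending genomic order). Positions in an
#' intron report the signed base-pair distance to the nearest exon
#' boundary (positive past an exon end, negative before an exon start, in
#' genomic orientation); positions outside the gene span or in
#' non-coding exonic sequence are `"noncoding"`.
#'
#' @param model A [gene_model()].
#' @param pos 1-based genomic position (scalar).
#' @return A list with `type` (`"cds"`, `"intronic"` or `"noncoding"`),
#'   `cds_pos` (for `"cds"`), and `distance` (for `"intronic"`).
#' @export
project_to_cds <- function(model, pos) {
  stopifnot(inherits(model, "gene_model"), length(pos) == 1L)
  ex <- model$exons
  cd <- model$cds
  span <- c(min(ex$start), max(ex$end))
  if (pos < span[1] || pos > span[2])
    return(list(type = "noncoding", cds_pos = NA_integer_,
                distance = NA_integer_))
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (!in_exon) {
    # intronic: signed distance to the nearest exon boundary
    d_after <- pos - ex$end    # > 0 when past an exon end
    d_before <- ex$start - pos # > 0 when before an exon start
    cand <- c(d_after[d_after > 0], -d_before[d_before > 0])
    distance <- cand[which.min(abs(cand))]
    return(list(type = "intronic", cds_pos = NA_integer_,
                distance = as.integer(distance)))
  }
  k <- which(pos >= cd$start & pos <= cd$end)
  if (length(k) == 0L)
    return(list(type = "noncoding", cds_pos = NA_integer_,
                distance = NA_integer_))
  widths <- cd$end - cd$start + 1
  if (model$strand == "+") {
    cds_pos <- sum(widths[seq_len(k - 1)]) + (pos - cd$start[k] + 1)
  } else {
    after <- if (k < nrow(cd)) sum(widths[(k + 1):nrow(cd)]) else 0
    cds_pos <- after + (cd$end[k] - pos + 1)
  }
  list(type = "cds", cds_pos = as.integer(cds_pos), distance = NA_integer_)
}
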