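# Karyotype-aware chromosome ordering: numeric-suffix names ("chr1", "2")
# sort numerically, anything else alphabetically after them.
chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  u[order(is.na(num), num, u)]
}

new_pooled_counts <- function(df, chrom_levels = chrom_order(df$chrom)) {
  df$chrom <- as.character(df$chrom)
  df <- df[order(match(df$chrom, chrom_levels), df$pos, df$ref, df$alt), ,
           drop = FALSE]
  attr(df, "chrom_levels") <- chrom_levels
  class(df) <- unique(c("pooled_counts", class(df)))
  df
}

# Parse one VCF into biallelic per-locus counts, summing AD over samples.
# Multi-allelic records are split into one row per alt allele.
read_vcf_counts <- function(path, role) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          ref = character(), alt = character(),
                          ref_depth = integer(), alt_depth = integer()))
  }
  fmt <- v@gt[, 1]
  if (!all(grepl("(^|:)AD(:|$)", fmt)))
    stop("format error: record without AD field in ", basename(path),
         " (first at ", fix[which(!grepl("(^|:)AD(:|$)", fmt))[1], "CHROM"],
         ":", fix[which(!grepl("(^|:)AD(:|$)", fmt))[1], "POS"], ")",
         call. = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (anyNA(ad)) {
    bad <- which(apply(is.na(ad), 1, any))[1]
    stop("format error: missing AD value in ", basename(path), " at ",
         fix[bad, "CHROM"], ":", fix[bad, "POS"], call. = FALSE)
  }
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  # per record x sample: integer AD vectors, summed across samples
  ad_sum <- matrix(0L, nrow = n, ncol = max(n_alt) + 1L)
  for (s in seq_len(ncol(ad))) {
    parts <- strsplit(ad[, s], ",", fixed = TRUE)
    if (any(lengths(parts) != n_alt + 1L))
      stop("format error: AD arity does not match ALT in ", basename(path),
           call. = FALSE)
    for (k in seq_len(ncol(ad_sum))) {
      has <- lengths(parts) >= k
      ad_sum[has, k] <- ad_sum[has, k] +
        as.integer(vapply(parts[has], `[`, "", k))
    }
  }
  rec <- rep.int(seq_len(n), n_alt)
  alt_idx <- sequence(n_alt)
  out <- tibble::tibble(
    chrom = fix[rec, "CHROM"],
    pos = as.numeric(fix[rec, "POS"]),
    ref = fix[rec, "REF"],
    alt = unlist(alts, use.names = FALSE),
    ref_depth = ad_sum[rec, 1L],
    alt_depth = ad_sum[cbind(rec, alt_idx + 1L)]
  )
  key <- paste(out$chrom, out$pos, out$ref, out$alt)
  if (anyDuplicated(key))
    stop("format error: duplicate record in ", basename(path), " at ",
         key[duplicated(key)][1], call. = FALSE)
  out
}

#' Read and join the pool and parental VCFs
#'
#' Parses both files (VCF 4.2 with per-sample `AD`; `DP` is ignored in
#' favour of `ref + alt` informative reads), splits multi-allelic records
#' into biallelic rows, sums allelic depths across samples within a file
#' (so two individually sequenced parent libraries behave like one pooled
#' library, see [merge_parent_samples()]), and outer-joins the two sides on
#' `(chrom, pos, ref, alt)`. Loci absent from one file are retained with
#' zero counts for the missing side, so a variant seen only in the parents
#' still contributes a difference; such zero-depth sides then fail the
#' downstream coverage filter unless the locus was genuinely covered.
#'
#' @param pool_path Path to the affected-pool VCF.
#' @param parents_path Path to the parental VCF.
#' @param verbose Log join statistics via `message()`.
#' @return A tibble of class `"pooled_counts"` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `pool_ref`, `pool_alt`, `parents_ref`, `parents_alt`,
#'   sorted by chromosome (karyotype order) then position.
#' @export
read_paired_vcf <- function(pool_path, parents_path, verbose = TRUE) {
  pool <- read_vcf_counts(pool_path, "pool")
  par <- read_vcf_counts(parents_path, "parents")
  names(pool)[names(pool) == "ref_depth"] <- "pool_ref"
  names(pool)[names(pool) == "alt_depth"] <- "pool_alt"
  names(par)[names(par) == "ref_depth"] <- "parents_ref"
  names(par)[names(par) == "alt_depth"] <- "parents_alt"
  joined <- dplyr::full_join(pool, par,
                             by = c("chrom", "pos", "ref", "alt"))
  for (col in c("pool_ref", "pool_alt", "parents_ref", "parents_alt"))
    joined[[col]][is.na(joined[[col]])] <- 0L
  if (verbose) {
    message("read_paired_vcf: ", nrow(joined), " loci (",
            sum(joined$parents_ref + joined$parents_alt == 0L),
            " pool-only, ",
            sum(joined$pool_ref + joined$pool_alt == 0L), " parents-only)")
  }
  new_pooled_counts(joined)
}

#' Sum per-sample allele counts into one parental pool
#'
#' Covers the two-parent-library design: when each parent was sequenced as
#' its own library, their allelic depths are summed element-wise so the
#' pair behaves as a single 4-chromosome pool.
#'
#' @param counts A list of `c(ref, alt)` pairs, or a 2-column matrix with
#'   one row per sample.
#' @return Named numeric vector `c(ref = , alt = )`.
#' @export
#' @examples
#' merge_parent_samples(list(c(5, 5), c(7, 3)))
merge_parent_samples <- function(counts) {
  if (is.matrix(counts)) counts <- asplit(counts, 1)
  if (length(counts) == 0L)
    stop("merge_parent_samples: need at least one sample", call. = FALSE)
  stopifnot(all(lengths(counts) == 2L))
  m <- do.call(rbind, counts)
  c(ref = sum(m[, 1]), alt = sum(m[, 2]))
}

#' Write mapping records to TSV
#'
#' One row per input locus: `chrom, pos, ref, alt, pool_af, parent_af,
#' delta, filter_status, fail_reason`. Percentages are rounded to one
#' decimal place at output only; missing values are written as `.`.
#'
#' @param records A [run_mapping()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mapping_records <- function(records, path) {
  out <- tibble::tibble(
    chrom = records$chrom, pos = records$pos,
    ref = records$ref, alt = records$alt,
    pool_af = round(records$pool_af, 1),
    parent_af = round(records$parent_af, 1),
    delta = round(records$delta, 1),
    filter_status = ifelse(records$filter_status == "pass", "pass", "fail"),
    fail_reason = ifelse(records$filter_status == "pass", NA,
                         records$filter_status)
  )
  readr::write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Write a density map as long-format TSV
#'
#' Columns `chrom, pos_bin_start, delta_bin_start, count`, one row per
#' non-empty cell, bin starts 1-based (position) and in percentage points
#' (delta).
#'
#' @param dm A [build_density_map()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_density_map <- function(dm, path) {
  readr::write_tsv(dm$cells, path, progress = FALSE)
  invisible(path)
}

#' Write called linkage regions as BED and TSV
#'
#' The BED file is BED6 with 0-based half-open intervals and
#' `score = round(1000 * fraction of informative loci)`; the TSV report
#' keeps 1-based inclusive coordinates and full precision.
#'
#' @param regions A [call_linked_regions()] result.
#' @param bed_path,tsv_path Output file paths.
#' @return Invisibly, a list with both paths.
#' @export
write_regions <- function(regions, bed_path, tsv_path) {
  bed <- tibble::tibble(
    chrom = regions$chrom,
    start = as.integer(regions$start - 1),
    end = as.integer(regions$end),
    name = paste0("region_", regions$rank),
    score = as.integer(round(1000 * regions$score)),
    strand = "."
  )
  readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  readr::write_tsv(regions, tsv_path, progress = FALSE)
  invisible(list(bed = bed_path, tsv = tsv_path))
}
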