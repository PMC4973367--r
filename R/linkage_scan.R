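passing_records <- function(records) {
  if (!is.null(records$filter_status))
    records <- records[records$filter_status == "pass", , drop = FALSE]
  if (any(is.na(records$delta)))
    stop("records contain NA delta values", call. = FALSE)
  records
}

records_chrom_levels <- function(records, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) return(names(chrom_lengths))
  lv <- attr(records, "chrom_levels")
  if (is.null(lv)) lv <- chrom_order(records$chrom)
  lv
}

infer_chrom_lengths <- function(records, chrom_lengths, levels) {
  if (!is.null(chrom_lengths)) {
    stopifnot(!is.null(names(chrom_lengths)))
    return(chrom_lengths[levels])
  }
  mx <- vapply(split(records$pos, factor(records$chrom, levels = levels)),
               function(p) if (length(p)) max(p) else 1, 0)
  setNames(mx, levels)
}

#' Build a position-by-difference density map
#'
#' Tallies passing loci into a 2-D histogram over genomic-position bins
#' and allele-frequency-difference bins, the numeric backbone of the
#' genome-wide and per-chromosome heat maps in which a linked region shows
#' low density at 0 pp but high density at 25-50 pp. Each locus falls in
#' exactly one cell; a delta of exactly 100 is assigned to the top bin.
#' The genome scope concatenates chromosomes in karyotype order.
#'
#' @param records A [run_mapping()] result (non-passing loci are dropped).
#' @param scope `"genome"` or a single chromosome name.
#' @param pos_bin_bp Position bin width in bp (default 1 Mb).
#' @param delta_bin_pp Delta bin width in percentage points (default 5).
#' @param chrom_lengths Optional named vector of chromosome lengths in bp
#'   (defines the karyotype order); inferred from the data if absent.
#' @return A list of class `"density_map"` with `scope`, bin edges,
#'   `counts` (matrix, position bin x delta bin), and `cells` (long-format
#'   tibble of non-empty cells: `chrom`, `pos_bin_start`,
#'   `delta_bin_start`, `count`).
#' @export
build_density_map <- function(records, scope = "genome",
                              pos_bin_bp = 1e6, delta_bin_pp = 5,
                              chrom_lengths = NULL) {
  stopifnot(pos_bin_bp > 0, delta_bin_pp > 0)
  levels <- records_chrom_levels(records, chrom_lengths)
  rec <- passing_records(records)
  if (!identical(scope, "genome")) {
    stopifnot(length(scope) == 1L)
    if (!scope %in% unique(c(levels, rec$chrom)))
      stop("unknown chromosome: ", scope, call. = FALSE)
    levels <- scope
    rec <- rec[rec$chrom == scope, , drop = FALSE]
  }
  lens <- infer_chrom_lengths(rec, chrom_lengths, levels)

  bad <- !(rec$chrom %in% levels)
  if (any(bad))
    stop("record outside known chromosomes: ", rec$chrom[bad][1], ":",
         rec$pos[bad][1], call. = FALSE)
  out_of_bounds <- rec$pos < 1 | rec$pos > lens[rec$chrom]
  if (any(out_of_bounds))
    stop("record outside chromosome bounds: ",
         rec$chrom[out_of_bounds][1], ":", rec$pos[out_of_bounds][1],
         call. = FALSE)
  if (any(rec$delta < 0 | rec$delta > 100))
    stop("delta outside [0, 100]", call. = FALSE)

  n_pos_bins <- setNames(pmax(1L, as.integer(ceiling(lens / pos_bin_bp))),
                         levels)
  n_delta_bins <- as.integer(ceiling(100 / delta_bin_pp))
  offsets <- cumsum(c(0L, head(n_pos_bins, -1L)))
  names(offsets) <- levels

  pos_bin_local <- pmin(floor((rec$pos - 1) / pos_bin_bp) + 1L,
                        n_pos_bins[rec$chrom])
  pos_bin <- offsets[rec$chrom] + pos_bin_local
  delta_bin <- pmin(floor(rec$delta / delta_bin_pp) + 1L, n_delta_bins)

  counts <- matrix(0L, nrow = sum(n_pos_bins), ncol = n_delta_bins)
  bin_chrom <- rep.int(levels, n_pos_bins)
  bin_start <- unlist(lapply(n_pos_bins, function(k)
    (seq_len(k) - 1L) * pos_bin_bp + 1), use.names = FALSE)
  rownames(counts) <- paste0(bin_chrom, ":", format(bin_start, trim = TRUE,
                                                    scientific = FALSE))
  colnames(counts) <- format((seq_len(n_delta_bins) - 1L) * delta_bin_pp,
                             trim = TRUE)
  if (nrow(rec)) {
    tab <- table(factor(pos_bin, levels = seq_len(nrow(counts))),
                 factor(delta_bin, levels = seq_len(n_delta_bins)))
    counts[] <- as.integer(tab)
  }

  nz <- which(counts > 0, arr.ind = TRUE)
  cells <- tibble::tibble(
    chrom = bin_chrom[nz[, 1]],
    pos_bin_start = bin_start[nz[, 1]],
    delta_bin_start = (nz[, 2] - 1) * delta_bin_pp,
    count = counts[nz]
  )
  cells <- cells[order(match(cells$chrom, levels), cells$pos_bin_start,
                       cells$delta_bin_start), , drop = FALSE]
  structure(list(scope = scope,
                 chrom_lengths = lens,
                 pos_bin_bp = pos_bin_bp, delta_bin_pp = delta_bin_pp,
                 pos_bin_edges = c(bin_start - 1, sum(lens)),
                 delta_bin_edges = seq(0, n_delta_bins * delta_bin_pp,
                                       by = delta_bin_pp),
                 counts = counts, cells = cells,
                 n_loci = nrow(rec)),
            class = "density_map")
}

#' Plot a density map heat map
#'
#' Cosmetic companion to [build_density_map()]: position vs delta tiles
#' shaded by `log1p(count)`. Requires ggplot2.
#'
#' @param dm A [build_density_map()] result.
#' @return A ggplot object.
#' @export
plot_density_map <- function(dm) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  cells <- dm$cells
  cells$chrom <- factor(cells$chrom, levels = names(dm$chrom_lengths))
  ggplot2::ggplot(cells, ggplot2::aes(
    x = .data$pos_bin_start / 1e6,
    y = .data$delta_bin_start,
    fill = log1p(.data$count))) +
    ggplot2::geom_tile(width = dm$pos_bin_bp / 1e6,
                       height = dm$delta_bin_pp) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "|pool AF - parent AF| (pp)",
                  fill = "log(1+n)") +
    ggplot2::theme_minimal()
}

#' Call candidate linkage regions with a sliding-window scan
#'
#' Formalizes the visual identification of the linked peak: windows slide
#' along each chromosome and are scored by the fraction of their loci
#' whose delta is at or above `informative_delta_pp` (default 20 pp, just
#' below the 25 pp analytic minimum for linked loci, leaving room for
#' sampling noise at depth ~20). Windows meeting `min_score` and
#' `min_loci` are kept, overlapping keeps are merged (scores recomputed
#' over the merged span), and merged regions are ranked by score, ties
#' broken by locus count, then leftmost position.
#'
#' @param records A [run_mapping()] result.
#' @param window_bp,step_bp Window size and step in bp (`window >= step > 0`).
#' @param informative_delta_pp Delta threshold (pp) above which a locus
#'   counts as informative for linkage.
#' @param min_score Minimum fraction of informative loci in a window.
#' @param min_loci Minimum loci per window.
#' @param chrom_lengths Optional named chromosome lengths (bp).
#' @return A tibble of class `"linkage_calls"`: `chrom`, `start`, `end`
#'   (1-based inclusive), `n_loci`, `n_informative`, `score`, `rank`.
#' @export
call_linked_regions <- function(records, window_bp = 5e6, step_bp = 1e6,
                                informative_delta_pp = 20,
                                min_score = 0.5, min_loci = 5,
                                chrom_lengths = NULL) {
  if (!(window_bp >= step_bp && step_bp > 0))
    stop("need window_bp >= step_bp > 0", call. = FALSE)
  levels <- records_chrom_levels(records, chrom_lengths)
  rec <- passing_records(records)
  lens <- infer_chrom_lengths(rec, chrom_lengths, levels)

  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_loci = integer(),
                          n_informative = integer(), score = numeric(),
                          rank = integer())
  kept <- list()
  for (ch in levels) {
    p <- rec$pos[rec$chrom == ch]
    d <- rec$delta[rec$chrom == ch]
    if (length(p) == 0L) next
    o <- order(p)
    p <- p[o]; d <- d[o]
    starts <- seq(1, max(1, lens[[ch]]), by = step_bp)
    lo <- findInterval(starts - 1, p)          # loci strictly before window
    hi <- findInterval(pmin(starts + window_bp - 1, lens[[ch]]), p)
    inf_cum <- c(0, cumsum(d >= informative_delta_pp))
    n <- hi - lo
    n_inf <- inf_cum[hi + 1] - inf_cum[lo + 1]
    score <- ifelse(n > 0, n_inf / n, 0)
    ok <- which(n >= min_loci & score >= min_score)
    if (length(ok) == 0L) next
    # merge overlapping kept windows
    ws <- starts[ok]
    we <- pmin(ws + window_bp - 1, lens[[ch]])
    grp <- cumsum(c(1, as.integer(ws[-1] > we[-length(we)] + 0)))
    for (g in unique(grp)) {
      s <- min(ws[grp == g]); e <- max(we[grp == g])
      in_reg <- p >= s & p <= e
      kept[[length(kept) + 1L]] <- tibble::tibble(
        chrom = ch, start = s, end = e,
        n_loci = sum(in_reg),
        n_informative = sum(d[in_reg] >= informative_delta_pp),
        score = sum(d[in_reg] >= informative_delta_pp) / sum(in_reg))
    }
  }
  if (length(kept) == 0L) {
    class(empty) <- unique(c("linkage_calls", class(empty)))
    return(empty)
  }
  out <- dplyr::bind_rows(kept)
  ord <- order(-out$score, -out$n_loci, match(out$chrom, levels), out$start)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  class(out) <- unique(c("linkage_calls", class(out)))
  out
}

#' Per-chromosome mapping summary
#'
#' @param records A [run_mapping()] result.
#' @param informative_delta_pp Delta threshold (pp) for the informative
#'   fraction.
#' @return A tibble with one row per chromosome: `chrom`, `n_loci`,
#'   `median_delta`, `frac_informative`.
#' @export
summarize_genome <- function(records, informative_delta_pp = 20) {
  levels <- records_chrom_levels(records, NULL)
  rec <- passing_records(records)
  rec$chrom <- factor(rec$chrom, levels = levels)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(rec), .data$chrom, .drop = FALSE),
    n_loci = dplyr::n(),
    median_delta = median(.data$delta),
    frac_informative = mean(.data$delta >= informative_delta_pp),
    .groups = "drop"
  )
}
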