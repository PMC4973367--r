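pipeline_sections <- function() list(
  top = c("out_dir", "master_seed", "log_level", "simulate", "input",
          "filters", "scan", "annotate"),
  simulate = names(formals(cross_config)),
  input = c("pool", "parents"),
  filters = c("min_coverage", "hom_alt_fraction"),
  scan = c("pos_bin_bp", "delta_bin_pp", "window_bp", "step_bp",
           "informative_delta_pp", "min_score", "min_loci"),
  annotate = c("gff", "cds_fasta", "controls", "splice_window",
               "conservative_min_score", "region_rank")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("config error: unknown key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
}

#' Run the mapping pipeline end to end
#'
#' Executes simulate (optional) -> map -> scan -> annotate (optional) from
#' one nested configuration, writing every artifact plus the resolved
#' configuration and a log into `out_dir`. The configuration is a nested
#' list (or path to a YAML file) with sections `simulate` *or* `input`
#' (paths `pool`/`parents`), `filters`, `scan`, `annotate` (optional:
#' `gff`, `cds_fasta`, `controls`, ...), and top-level `out_dir` and
#' `master_seed`. Unknown keys are rejected. Runs with the same
#' configuration and seed produce byte-identical tabular outputs.
#'
#' @param config Nested list or path to a YAML config file.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with `records`, `density`, `regions`,
#'   `summary`, `candidates` (or `NULL`) and `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sections <- pipeline_sections()
  check_keys(config, sections$top, "config")
  for (s in c("simulate", "input", "filters", "scan", "annotate"))
    if (!is.null(config[[s]]))
      check_keys(config[[s]], sections[[s]], s)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir missing", call. = FALSE)
  config$out_dir <- out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- character()
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  chrom_lengths <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$master_seed)) sim_args$master_seed <- config$master_seed
    cfg <- stage("simulate", do.call(cross_config, sim_args))
    sim <- stage("simulate", simulate_cross(cfg, out_dir = out_dir))
    log_msg("simulate: ", nrow(sim$counts), " loci written to pool.vcf/",
            "parents.vcf (seed ", cfg$master_seed, ")")
    pool_path <- sim$paths$pool
    parents_path <- sim$paths$parents
    chrom_lengths <- setNames(cfg$chrom_lengths_bp,
                              paste0("chr", seq_len(cfg$n_chromosomes)))
  } else {
    if (is.null(config$input))
      stop("config error: need either a simulate or an input section",
           call. = FALSE)
    pool_path <- config$input$pool
    parents_path <- config$input$parents
  }

  fcfg <- do.call(filter_config, config$filters %||% list())
  counts <- stage("map", read_paired_vcf(pool_path, parents_path,
                                         verbose = FALSE))
  records <- stage("map", run_mapping(counts, fcfg, verbose = FALSE))
  n_pass <- sum(records$filter_status == "pass")
  log_msg("map: ", nrow(records), " loci, ", n_pass, " passing")
  write_mapping_records(records, file.path(out_dir, "records.tsv"))

  scan_cfg <- config$scan %||% list()
  dm <- stage("scan", do.call(build_density_map, c(
    list(records = records, scope = "genome",
         chrom_lengths = chrom_lengths),
    scan_cfg[intersect(names(scan_cfg), c("pos_bin_bp", "delta_bin_pp"))])))
  write_density_map(dm, file.path(out_dir, "density.tsv"))
  regions <- stage("scan", do.call(call_linked_regions, c(
    list(records = records, chrom_lengths = chrom_lengths),
    scan_cfg[intersect(names(scan_cfg),
                       c("window_bp", "step_bp", "informative_delta_pp",
                         "min_score", "min_loci"))])))
  summary_tab <- summarize_genome(
    records, scan_cfg$informative_delta_pp %||% 20)
  write_regions(regions, file.path(out_dir, "regions.bed"),
                file.path(out_dir, "regions.tsv"))
  readr::write_tsv(summary_tab, file.path(out_dir, "summary.tsv"),
                   progress = FALSE)
  log_msg("scan: ", nrow(regions), " candidate region(s)")

  candidates <- NULL
  if (!is.null(config$annotate)) {
    an <- config$annotate
    acfg <- annotation_config(
      splice_window = an$splice_window %||% 2,
      conservative_min_score = an$conservative_min_score %||% 0,
      control_panels = unlist(an$controls) %||% character())
    models <- stage("annotate", read_gene_models(an$gff, an$cds_fasta))
    region <- if (nrow(regions)) regions[an$region_rank %||% 1, ] else NULL
    in_region <- if (is.null(region)) rep(FALSE, nrow(records)) else
      records$chrom == region$chrom & records$pos >= region$start &
      records$pos <= region$end
    variants <- records[in_region & records$filter_status == "pass",
                        c("chrom", "pos", "ref", "alt")]
    effects <- stage("annotate",
                     classify_region_variants(variants, models, acfg))
    candidates <- stage("annotate",
                        filter_candidates(effects, region, acfg))
    readr::write_tsv(candidates, file.path(out_dir, "candidates.tsv"),
                     na = ".", progress = FALSE)
    log_msg("annotate: ", nrow(candidates), " region variant(s), ",
            sum(candidates$kept), " candidate(s) kept")
  }

  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(records = records, density = dm, regions = regions,
                 summary = summary_tab, candidates = candidates,
                 paths = list(out_dir = out_dir,
                              pool = pool_path, parents = parents_path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
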