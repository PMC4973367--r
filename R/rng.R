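#' Derive a deterministic per-stage seed from a master seed
#'
#' Each simulation stage (parent genomes, pool segregation, read sampling)
#' draws from its own substream so that stages are independently
#' reproducible: changing the read-sampling stage cannot perturb the
#' segregation of the cross. The substream seed is a small string hash of
#' the stage name folded into the master seed, kept below 2^31 - 1.
#'
#' @param master_seed Single integer master seed.
#' @param stage Character stage label, e.g. `"parents"`.
#' @return A single integer seed.
#' @export
#' @examples
#' stage_seed(1, "parents")
stage_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- (abs(as.double(master_seed)) + 1) %% 2147483647
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Evaluate code under a stage substream without touching the global RNG.
with_stage_seed <- function(master_seed, stage, code) {
  withr::with_seed(stage_seed(master_seed, stage), code)
}
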