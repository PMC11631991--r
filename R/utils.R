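# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

vl_assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_sd_triple <- function(x) {
  is.numeric(x) && length(x) == 3L && all(is.finite(x)) && all(x >= 0)
}

#' Derive a stage-specific seed from a global seed
#'
#' All pipeline stages draw their randomness from one global seed. Each stage
#' gets `global_seed * 8 + stage index`, which keeps reruns of a single stage
#' reproducible without sharing RNG streams between stages. The result is
#' reduced modulo 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param global_seed integer global seed.
#' @param stage one of `"simulate"`, `"construct"`, `"fit"`, `"derive"`,
#'   `"compare"`, `"plan"`.
#' @return an integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  stages <- c("simulate", "construct", "fit", "derive", "compare", "plan")
  idx <- match(stage, stages)
  vl_assert(!is.na(idx), "unknown stage '%s'", stage)
  as.integer((abs(as.numeric(global_seed)) * 8 + idx) %% (2^31 - 1))
}

# FNV-1a hash of a character scalar, returned as 8 hex digits; used only to
# fingerprint configurations in run manifests.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# central 95% interval helper
ci95 <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
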