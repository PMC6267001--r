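## Internal helpers: error signalling and seed streams.

stop_skinmwas <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "skinmwas_error"), ...)
}

#' Derive a per-stage child seed from the master seed
#'
#' A single integer master seed drives every stochastic stage; each stage
#' (cohort, taxa, genes, ...) draws from its own stream derived by a fixed
#' labelled offset, so that stages are independently reproducible and
#' inserting an extra draw in one stage cannot perturb another.
#'
#' @param seed Integer master seed.
#' @param stage Stage label, e.g. `"cohort"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stage) {
  offsets <- c(
    cohort = 101L, taxa = 211L, genes = 307L, ordination = 401L,
    pipeline = 503L, replicate = 601L
  )
  if (!stage %in% names(offsets)) {
    stop_skinmwas(paste0("unknown seed stage '", stage, "'"),
                  "skinmwas_error_config")
  }
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

## round-half-even free formatting for TSV output; keeps round-trips lossless
## well past 6 significant digits
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

`%||%` <- rlang::`%||%`
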