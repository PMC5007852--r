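#' Derive a reproducible child seed
#'
#' A single top-level seed is split deterministically per stage and index so
#' that each stage (or scene) can be re-run independently yet reproducibly.
#' Uses a Lehmer-style multiplicative hash over the stage name; all arithmetic
#' stays below 2^31.
#'
#' @param seed integer top-level seed.
#' @param stage character stage name (e.g. "simulate", "flow").
#' @param index integer sub-index (scene number, replicate, ...).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage, index = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647              # 2^31 - 1 (prime)
  h <- (as.double(seed) %% m)
  codes <- utf8ToInt(stage)
  for (k in c(codes, as.integer(index))) {
    h <- (h * 48271 + as.double(k) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
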