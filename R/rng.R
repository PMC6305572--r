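#' Named random substreams
#'
#' Every stage of the generator seeds R's RNG from the master seed and a
#' stage name, so stages are individually reproducible and inserting a new
#' stage does not perturb the draws of existing ones.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, stage) {
  chars <- utf8ToInt(stage)
  # small multiplicative hash, kept within 32-bit integer range
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

use_substream <- function(seed, stage) {
  set.seed(substream_seed(seed, stage))
}
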