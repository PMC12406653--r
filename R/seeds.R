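#' Derive a named substream seed
#'
#' Expands one global integer seed into independent named substreams so that
#' each simulation stage (cohort draw, random effects, residual error, ...)
#' has its own reproducible stream and adding a stage does not perturb the
#' others.
#'
#' @param seed Global integer seed.
#' @param label Character label of the stage.
#' @return A positive integer below 2^31, deterministic in `(seed, label)`.
#' @examples
#' substream_seed(1, "cohort") != substream_seed(1, "eta")
#' @export
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":"))) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) %% 1000000007 * 69069 + h) %% 2147483647) + 1L
}
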