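#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages (surrogate construction, rewired nulls, Louvain runs,
#' synthetic data) draw their seed from a single master seed through this
#' deterministic splitting scheme, so any stage or subject can be recomputed
#' independently with identical results. The scheme folds the master seed and
#' an arbitrary sequence of string/numeric tags into a 31-bit integer with a
#' polynomial (base-31) hash over the tags' characters.
#'
#' @param master integer master seed.
#' @param ... tags identifying the stage (stage name, subject id, timepoint,
#'   replicate index, ...); coerced to character.
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' child_seed(1, "surrogate", "S1", "baseline")
#' @export
child_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(abs(master)) %% m
  for (tag in list(...)) {
    for (code in utf8ToInt(paste(as.character(tag), collapse = "|"))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h)
}
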