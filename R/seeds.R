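#' Derive a reproducible child seed from a master seed
#'
#' Fans a single master seed out to independent per-stage, per-species seeds
#' by stable string hashing, so that adding or removing one species never
#' reshuffles the random draws of the others.
#'
#' @param master Integer master seed.
#' @param ... Stage labels and identifiers (coerced to character) that name
#'   the consumer of the child seed, e.g. `child_seed(seed, "sdm", "sp07")`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "pca")
#' child_seed(1, "sdm", "sp01")
child_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  # Horner hash mod 2^31 - 1; 31 * (2^31) + 255 < 2^53 so doubles are exact
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
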