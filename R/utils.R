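# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a global seed
#'
#' Stages of the pipeline draw their randomness from seeds derived
#' deterministically from one global seed and the stage name, so any stage can
#' be rerun in isolation with identical output.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- as.double(seed) %% 2147483647
  for (k in seq_along(codes)) {
    h <- (h * 31 + codes[k] * k) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

# global coordinate helpers: chromosomes are laid end to end so a single
# numeric axis orders all sites; offsets leave a 1bp gap between chromosomes
chrom_offsets <- function(chrom_len) {
  stopifnot(!is.null(names(chrom_len)))
  off <- c(0, cumsum(as.double(chrom_len) + 1))[seq_along(chrom_len)]
  names(off) <- names(chrom_len)
  off
}

global_pos <- function(chrom, pos, chrom_len) {
  off <- chrom_offsets(chrom_len)
  unname(off[chrom]) + as.double(pos)
}

# simple non-cryptographic content hash for run manifests
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  codes <- utf8ToInt(txt)
  h <- 2166136261
  for (c in codes) h <- (bitwXor(as.integer(h %% 2^31), c) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
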