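# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Bitmask encoding of nucleotides; IUPAC two-base ambiguity codes carry the
# union of their bases so that a masked comparison treats an ambiguity
# position as matching either base.
.BASE_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  N = 15L
)

#' @noRd
base_mask <- function(chars) {
  m <- .BASE_MASK[chars]
  m[is.na(m)] <- 0L
  unname(m)
}

#' @noRd
seq_to_mask <- function(seq) base_mask(strsplit(seq, "", fixed = TRUE)[[1]])

# Complement preserving ambiguity codes (R<->Y, K<->M, S and W self).
.COMP_FROM <- "ACGTRYSWKMN"
.COMP_TO   <- "TGCAYRSWMKN"

#' Reverse-complement a nucleotide string (IUPAC-aware)
#' @param seq character scalar over ACGT plus two-base ambiguity codes.
#' @return the reverse complement, same alphabet.
#' @noRd
revcomp <- function(seq) {
  paste(rev(strsplit(chartr(.COMP_FROM, .COMP_TO, seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' @noRd
comp_base <- function(base) chartr(.COMP_FROM, .COMP_TO, base)

# Deterministic per-generator sub-seeds: a single root seed drives named
# substreams so adding one generator never perturbs another's draws.
.STREAM_OFFSET <- c(
  reference = 101L, genes = 211L, candidates = 307L,
  legacy = 401L, callsets = 503L, partition = 601L, misc = 701L
)

#' @noRd
stream_seed <- function(seed, stream) {
  off <- .STREAM_OFFSET[[stream]]
  if (is.null(off)) stopf("unknown random stream '%s'", stream)
  as.integer((as.numeric(seed) %% 65536 * 31013 + off * 97) %% 2147483647)
}

#' @noRd
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  force(expr)
}

#' Round half away from zero, matching how rates are printed in reports
#' (base round() is banker's rounding, which turns 97.45 into 97.4).
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
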