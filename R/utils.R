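# Internal helpers shared across modules.

# Round half away from zero to the nearest integer (round() in R rounds
# half-to-even, which is not what is wanted for reported bp lengths).
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Reverse-complement an upper-case nucleotide string, IUPAC-aware.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

stopifnot_scalar_fraction <- function(x, name, allow_one = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0 &&
    (if (allow_one) x <= 1 else x < 1)
  if (!ok) {
    stop(sprintf("`%s` must be a single proportion in (0, 1%s]",
                 name, if (allow_one) "" else ")"), call. = FALSE)
  }
  invisible(x)
}

# assemble a data.frame without string mangling
df <- function(...) data.frame(..., stringsAsFactors = FALSE)
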