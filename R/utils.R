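#' @keywords internal
"_PACKAGE"

#' @importFrom stats dhyper p.adjust rbinom rmultinom runif setNames
#' @importFrom utils read.table write.table head tail packageVersion
NULL

# Validation helper: stop with a consistent message prefix.
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}

# Deterministic 32-bit stream seed derived from a master seed and a string
# key, so per-locus random streams survive reordering of loci.
derive_seed <- function(master, key) {
  h <- 0
  for (v in utf8ToInt(as.character(key))) {
    h <- (h * 131 + v) %% 1000000007
  }
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

# Reverse complement for plain character vectors of DNA.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
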