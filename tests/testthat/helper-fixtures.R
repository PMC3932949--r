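# small shared fixtures; heavier data is generated inside the tests that use it

tiny_hairpins <- function() {
  tibble::tibble(
    id = c("h1", "h2"),
    sequence = c("GCGCAAAGCGC", "AUGCUAGCUAGGCUA"),
    structure = c("((((...))))", "((..((...))..))"),
    mfe = c(-8.2, -4.1)
  )
}

# enumerate every valid dot-bracket string of length n (exhaustive oracle aid)
enumerate_structures <- function(n) {
  grow <- function(prefix, open, left) {
    if (left == 0L) return(if (open == 0L) prefix else character(0))
    out <- character(0)
    if (left > open) out <- c(out, grow(paste0(prefix, "."), open, left - 1L))
    if (left - 1L >= open + 1L) {
      out <- c(out, grow(paste0(prefix, "("), open + 1L, left - 1L))
    }
    if (open > 0L) out <- c(out, grow(paste0(prefix, ")"), open - 1L, left - 1L))
    out
  }
  grow("", 0L, n)
}
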