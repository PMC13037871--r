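# Shared constants and small helpers.

#' Length of the standard human mtDNA reference coordinate system (rCRS)
#' @export
RCRS_LENGTH <- 16569L

DNA_BASES <- c("A", "C", "G", "T")

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# 1-based circular position arithmetic on a reference of length n.
wrap_pos <- function(pos, n) ((pos - 1L) %% n) + 1L

# Phred+33 encode/decode.
qual_to_chr <- function(q) intToUtf8(pmin(q, 93L) + 33L, multiple = FALSE)
chr_to_qual <- function(s) utf8ToInt(s) - 33L

seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
chars_to_seq <- function(x) paste0(x, collapse = "")

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[x]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)
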