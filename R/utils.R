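# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed; keeps every draw
# reproducible while letting stages consume randomness independently.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

BASES <- c("A", "C", "G", "T")

# reverse complement of plain character sequences (vectorized)
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1L))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

# Translate a coding sequence codon-by-codon under the standard code.
translate_cds <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}
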