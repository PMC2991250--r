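# Internal helpers shared across modules.

# Unit separator keeps keys unambiguous even if gene ids contain punctuation.
pair_key <- function(a, b) paste(a, b, sep = "\x1f")

new_pairs <- function(a = character(), b = character()) {
  data.frame(a = as.character(a), b = as.character(b), stringsAsFactors = FALSE)
}

# Lexicographically smaller gene first; used for all unordered pair storage.
canonicalize_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  swap <- pairs$a > pairs$b
  if (any(swap)) {
    tmp <- pairs$a[swap]
    pairs$a[swap] <- pairs$b[swap]
    pairs$b[swap] <- tmp
  }
  pairs
}

dedup_pairs <- function(pairs) {
  pairs[!duplicated(pair_key(pairs$a, pairs$b)), , drop = FALSE]
}

flip_pairs <- function(pairs) new_pairs(pairs$b, pairs$a)

pair_genes <- function(pairs) unique(c(pairs$a, pairs$b))

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
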