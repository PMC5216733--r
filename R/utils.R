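# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical unordered-pair keys: lexicographically smaller symbol first.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Order a two-column pair frame canonically (symbol_a < symbol_b) and sort rows.
canonicalize_pairs <- function(df) {
  if (nrow(df) == 0) return(df)
  swap <- df$symbol_a > df$symbol_b
  if (any(swap)) {
    tmp <- df$symbol_a[swap]
    df$symbol_a[swap] <- df$symbol_b[swap]
    df$symbol_b[swap] <- tmp
  }
  df <- df[order(df$symbol_a, df$symbol_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Derived per-block seeds so adding draws in one logical block does not
# perturb another. Kept below 2^31 - 1.
block_seed <- function(seed, block) {
  offsets <- c(
    noise_control  = 101L, noise_tumor   = 211L,
    modules_control = 307L, modules_tumor = 401L,
    coupling       = 503L, extra         = 601L
  )
  off <- offsets[[block]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
}
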