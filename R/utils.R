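# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state (the global .Random.seed is saved and restored). The seed
# promise is forced *before* the state is saved: callers may pass an
# RNG-consuming expression (e.g. a derived seed) and its draw must not be
# rolled back on exit.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

rev_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# n random ACGT strings with the given lengths (vectorised; zero lengths
# yield "").
random_dna <- function(lengths) {
  total <- sum(lengths)
  if (total == 0L) return(rep("", length(lengths)))
  pool <- paste(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                collapse = "")
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  out <- substring(pool, starts, ends)
  out[lengths == 0L] <- ""
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
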