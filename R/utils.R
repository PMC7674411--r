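# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

random_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute bases at `positions` (0-based) with a uniformly chosen
# different base; returns list(seq, positions, old, new).
mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  old <- ch[positions + 1L]
  new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  ch[positions + 1L] <- new
  list(seq = paste(ch, collapse = ""), positions = positions,
       old = unname(old), new = unname(new))
}

# Bernoulli(rate) positions along a sequence of length n (0-based).
bernoulli_positions <- function(n, rate) {
  if (rate <= 0 || n == 0L) return(integer(0))
  which(runif(n) < rate) - 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_interval <- function(iv, len, what) {
  if (length(iv) != 2L || iv[1] < 0 || iv[2] <= iv[1] || iv[2] > len)
    stopf("%s must be a 0-based half-open interval within [0, %d)", what, len)
  invisible(iv)
}

interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

iupac_two <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")[[key]]
}

`%||%` <- function(x, y) if (is.null(x)) y else x
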