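clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic small-integer seed derivation for replicate/value grids;
# stays below 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (k in seq_along(idx)) {
    s <- (s * 7919 + as.double(idx[k]) * 104729 + 12345) %% 2147483629
  }
  as.integer(s)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards. Used where a config carries its own seed.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# write-then-rename so interrupted runs never leave corrupt files
atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
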