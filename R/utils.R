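# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards so library calls never
# perturb user-level reproducibility.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# 32-bit FNV-1a over a character vector; returns a hex string. Used for
# config stamping and labeled seed derivation (kept below 2^31).
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stable labeled-hash scheme: the same (seed, label) pair always yields
#' the same derived seed, so pipeline stages can be rerun in isolation.
#'
#' @param seed global integer seed.
#' @param label stage label.
#' @return an integer seed in \[0, 2^31).
#' @export
derive_seed <- function(seed, label) {
  h <- strtoi(substr(fnv1a(c(format(seed), label)), 1, 7), 16L)
  (as.integer(seed) %% 1013904223L + h) %% 2147483647L
}
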