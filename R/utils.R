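## Internal helpers: validation, seed derivation, truncated sampling.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.finite(seed) || seed < 0 || seed != trunc(seed))
    stopf("`seed` must be a single non-negative integer (got %s)",
          paste(format(seed), collapse = ", "))
  as.integer(seed)
}

## Derive n child seeds from one parent seed without touching the caller's RNG
## state. All package-level randomness flows through this, so one config seed
## fully determines a run.
derive_seeds <- function(seed, n) {
  seed <- check_seed(seed)
  withr::with_seed(seed, sample.int(2147483646L, n))
}

## Truncated normal via inverse-CDF; vectorized over n. lo/hi may be infinite.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, lo), hi)
}

## Dirichlet draw via gamma representation; alpha entries of 0 yield exact 0.
rdirichlet1 <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  s <- sum(g)
  if (s == 0) stopf("degenerate Dirichlet draw: all concentrations zero")
  g / s
}

## Tiny stable content hash (FNV-1a, 32-bit) for run manifests; avoids an
## extra dependency for a non-cryptographic fingerprint.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    ## 32-bit modular multiply in doubles (split to stay under 2^53)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 2^32
  }
  paste0(format(as.hexmode(as.integer(h %/% 65536)), width = 4),
         format(as.hexmode(as.integer(h %% 65536)), width = 4))
}

## order() wrapper: descending numeric with lexicographic tie-break.
order_desc_then_name <- function(value, name) order(-value, name, method = "radix")

is_count_vector <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)
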