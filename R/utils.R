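# internal helpers

SPECIES <- c("p", "a", "b", "t")

species_code <- function(x) {
  m <- match(x, SPECIES)
  if (anyNA(m)) {
    stop("unknown species label(s): ",
         paste(unique(x[is.na(m)]), collapse = ", "),
         " (must be one of p, a, b, t)")
  }
  m - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a finite numeric scalar")
  }
  if (positive && x <= 0) stop("'", name, "' must be positive")
  invisible(x)
}

# deterministic 31-bit seed for a sweep cell, independent of execution order
mix_seed <- function(base_seed, phi, epsilon, replicate) {
  h <- (as.double(base_seed) +
          round(phi * 1000) * 7919 +
          round(epsilon * 1000) * 104729 +
          as.double(replicate) * 1299709) %% 2147483629
  as.integer(h) + 1L
}
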