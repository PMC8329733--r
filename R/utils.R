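# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Coordinates (pixel centres, micrometres) along one axis: centre of pixel i
# is (i - 0.5) * spacing, i = 1..n.
axis_coords <- function(n, spacing) (seq_len(n) - 0.5) * spacing

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}

# logical/integer array -> integer vector for the C++ kernels
as_int_mask <- function(mask) {
  storage.mode(mask) <- "integer"
  mask
}

# deterministic derived seed, kept well below .Machine$integer.max
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (k in idx) s <- (s * 131 + as.double(k)) %% 2147480000
  as.integer(s)
}

pixel_measure <- function(spacing) prod(spacing)

`%||%` <- function(a, b) if (is.null(a)) b else a
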