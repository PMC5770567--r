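#' @useDynLib bilayerdomains, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef fft lm nls pf rnorm runif sd var complete.cases
#' @importFrom utils head read.csv write.csv tail
NULL

# Run `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All public generators route their randomness
# through this, so identical seeds give identical output regardless of what
# the session did before.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# wrap coordinates into [0, L)
wrap_box <- function(v, L) {
  out <- v %% L
  out[out == L] <- 0
  out
}

# minimum-image separation on the torus
min_image <- function(d, L) d - L * round(d / L)

# derive a stream of child seeds from one root seed (keeps values < 2^31)
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 69069 + 12345 + 1000003 * seq_len(n)) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
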