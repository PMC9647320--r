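#' @keywords internal
"_PACKAGE"

#' @importFrom stats mad rnorm sd median setNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard pressure (Torr) and temperature (K) used for K0 normalization
#' @name standard-conditions
#' @keywords internal
.P0_TORR <- 760
.T0_K <- 273.15

#' Sentinel used in the reference library for unidentified compounds
#' @keywords internal
.NI <- "N.I."

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed below 2^31 derived from a root seed and a stream
# index tuple (location, replicate, purpose). Plain integer mixing; streams
# for distinct tuples are distinct in all uses that matter here.
mix_seed <- function(seed, a = 0L, b = 0L, c = 0L) {
  m <- 2147483587
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(a) * 16807 + 11) %% m
  s <- (s * 48271 + as.numeric(b) * 69621 + 7) %% m
  s <- (s * 48271 + as.numeric(c) * 16807 + 3) %% m
  as.integer(s)
}

# Domain-error helper: every physical argument must be a positive finite
# number; the error names the offending argument.
check_positive <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    x <- args[[i]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
      stop(sprintf("'%s' must be strictly positive and finite", nm[i]),
           call. = FALSE)
  }
  invisible(TRUE)
}
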