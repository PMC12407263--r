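# Internal helpers shared across modules.

#' Evaluate an expression with a local, restored RNG state
#'
#' All stochastic operations in the package take an explicit seed and are
#' pure functions of (inputs, seed): the caller's global RNG stream is left
#' untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Linear resampling of a numeric vector to a fixed length
#' @param x numeric vector (length >= 2).
#' @param n output length.
#' @keywords internal
resample_linear <- function(x, n) {
  stopifnot(length(x) >= 2L, n >= 2L)
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n),
                method = "linear", rule = 2)$y
}

# djb2 string hash, hex-encoded; used only for provenance stamps in reports.
hash_string <- function(s) {
  b <- utf8ToInt(s)
  h <- 5381
  for (v in b) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", as.integer(h))
}

# Stable provenance hash of an R object (via its canonical JSON form).
hash_config <- function(x) {
  hash_string(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10))
}

#' Unit helpers: microlitres to cubic metres and back, millimetres to metres
#'
#' The fluidics design equations work in SI internally; device volumes are
#' conventionally quoted in microlitres and channel dimensions in
#' millimetres.
#'
#' @param x numeric values to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
ul_to_m3 <- function(x) x * 1e-9

#' @rdname units
#' @export
m3_to_ul <- function(x) x * 1e9

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname units
#' @export
m_to_mm <- function(x) x * 1e3

stop_domain <- function(msg) stop(msg, call. = FALSE)
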