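# Internal helpers: classed conditions and seed hygiene.

cm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("castmove_", class), "castmove_error")))
}

cm_assert <- function(cond, msg, class) {
  if (!isTRUE(cond)) cm_stop(msg, class)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# Seeds are always explicit arguments in this package, never global state.
with_seed <- function(seed, expr) {
  cm_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "seed must be a single finite number", "config_error")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h) + 1L
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

is_point_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && ncol(x) == 3L
}

as_point_matrix <- function(x, what = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) x <- matrix(x, 1L, 3L)
  cm_assert(is_point_matrix(x), sprintf("%s must be an N x 3 numeric matrix", what),
            "config_error")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}
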