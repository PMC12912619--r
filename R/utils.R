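# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stop_("`%s` must be TRUE or FALSE", name)
}

is_symmetric <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# Derive a per-stage seed from a global seed so pipeline stages are
# independently reproducible. Polynomial rolling hash over the stage name
# (position-sensitive, so "rec12"/"rec21" differ) mixed with the seed;
# result stays inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483629
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

# trapezoidal rule on an (x, y) grid; NAs in y are dropped pairwise with
# their x so partially-undefined metrics still integrate over the defined part
trapz <- function(x, y) {
  keep <- is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(NA_real_)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}
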