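# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @importFrom rlang abort
stop_polardrum <- function(msg, class) {
  rlang::abort(msg, class = c(class, "polardrum_error"))
}

# Wrap degrees into [0, 360).
wrap360 <- function(x) x %% 360

# Wrap degrees into [0, 180) (angle-of-polarization convention).
wrap180 <- function(x) x %% 180

# Unwrap a wrapped angular time series (degrees): remove 360-deg jumps.
unwrap_deg <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  x[1] + c(0, cumsum(d))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL runs in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Centered moving average with edge shrinkage (window clipped at ends).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# 2x2 mean-pooling of a (2H x 2W) matrix down to (H x W).
pool2 <- function(m) {
  r <- nrow(m); c <- ncol(m)
  (m[seq(1, r, 2), seq(1, c, 2)] + m[seq(2, r, 2), seq(1, c, 2)] +
    m[seq(1, r, 2), seq(2, c, 2)] + m[seq(2, r, 2), seq(2, c, 2)]) / 4
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
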