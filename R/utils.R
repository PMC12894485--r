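# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so sub-streams stay independent of call order.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Deterministic sub-stream seed for component k of a run seeded with `seed`.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + k * 10007) %% 2147483647L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round disability scores to the clinical EDSS grid
#'
#' The Expanded Disability Status Scale is scored as 0 or in half-point steps
#' from 1.0 to 10.0; there is no step between 0 and 1.0. Continuous values are
#' rounded to the nearest attainable grid point (half-up on exact midpoints);
#' values in (0, 1) go to 0 or 1.0, whichever is nearer (0.5 rounds up to 1.0).
#'
#' @param x numeric vector of continuous EDSS-scale values; clamped to [0, 10].
#' @return numeric vector on the grid \{0, 1.0, 1.5, ..., 10.0\}.
#' @export
#' @examples
#' edss_grid_round(c(0.3, 0.5, 1.24, 1.25, 9.9))
edss_grid_round <- function(x) {
  x <- clamp(x, 0, 10)
  # half-up rounding to 0.5 steps (round() is banker's rounding, so do it by hand)
  g <- floor(x * 2 + 0.5) / 2
  # 0.5 is not an attainable score: send it to the nearer of 0 and 1.0
  mid <- !is.na(g) & g == 0.5
  g[mid] <- ifelse(x[mid] < 0.5, 0, 1)
  g
}

# Numerically stable roots of a*x^2 + b*x + c = 0 (a may be 0 -> linear).
quad_roots <- function(a, b, c) {
  if (a == 0) {
    if (b == 0) return(numeric(0))
    return(-c / b)
  }
  disc <- b * b - 4 * a * c
  if (disc < 0) {
    if (disc > -1e-12 * max(b * b, 1)) disc <- 0 else return(numeric(0))
  }
  sq <- sqrt(disc)
  q <- -(b + sign(b + (b == 0)) * sq) / 2
  r1 <- q / a
  r2 <- if (q != 0) c / q else -b / a - r1
  c(r1, r2)
}

# Deterministic per-protein baseline log-abundance, a pure function of the
# identifier so that all cohorts generated for the same protein universe share
# intercepts (they cancel in ratio features, but must not drift across cohorts).
protein_baseline_log <- function(proteins) {
  h <- vapply(proteins, function(p) {
    s <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    ((s * 2654435.0) %% 997) / 997
  }, numeric(1))
  6.5 + 2 * h
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_csf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_csf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
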