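# Internal numeric helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sliding-window extremum over a centred window of odd width w, computed with
# the two-pass block (prefix/suffix cumulative extremum) algorithm: O(n) in
# vectorised operations, no per-point loop.
running_extremum <- function(x, w, which = c("min", "max")) {
  which <- match.arg(which)
  stopifnot(w >= 1L, w %% 2L == 1L)
  if (w == 1L) return(x)
  n <- length(x)
  if (w > n) stop("window width exceeds signal length")
  pad <- if (which == "min") Inf else -Inf
  cumfun <- if (which == "min") cummin else cummax
  pairfun <- if (which == "min") pmin else pmax
  h <- (w - 1L) %/% 2L
  m <- n + 2L * h
  nb <- ceiling(m / w)
  xp <- c(rep(pad, h), x, rep(pad, nb * w - n - h))
  mat <- matrix(xp, nrow = w)
  pre <- as.vector(apply(mat, 2L, cumfun))
  suf <- as.vector(apply(mat[w:1L, , drop = FALSE], 2L, cumfun)[w:1L, , drop = FALSE])
  i <- seq_len(n)
  # window for x[i] spans xp[i .. i + w - 1]
  pairfun(suf[i], pre[i + w - 1L])
}

running_min <- function(x, w) running_extremum(x, w, "min")
running_max <- function(x, w) running_extremum(x, w, "max")

# Centred moving average with edge replication, odd width.
moving_average <- function(x, w) {
  stopifnot(w >= 1L, w %% 2L == 1L)
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[(h + 1L):(h + length(x))]
}

# Local median over a centred odd window (runmed keeps endpoints sensible).
local_median <- function(x, w) {
  w <- min(w, if (length(x) %% 2L == 0L) length(x) - 1L else length(x))
  if (w < 3L) return(x)
  as.numeric(stats::runmed(x, w, endrule = "median"))
}

# Robust noise scale of a detrended signal: MAD computed from the lower
# (noise-dominated) side only, so dense peak structure above the local
# median does not inflate the estimate.
noise_scale <- function(det) {
  lower <- det[det <= 0]
  s <- 1.4826 * stats::median(abs(lower))
  if (!is.finite(s) || s == 0) s <- stats::mad(det)
  if (!is.finite(s) || s == 0) s <- stats::sd(det)
  s
}

# Stable descending order: by value, ties broken by original position.
order_desc_stable <- function(x) order(-x, seq_along(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
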