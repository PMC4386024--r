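# Internal helpers shared across modules.

# Acquisition constants. 32 s stimulus epochs, imaging at 1.8 Hz (57 whole
# frames per epoch), eye tracking at 60 Hz. The visual-response-vector window
# is the first 38 frames of each epoch (18 stimuli x 38 frames = 684 points).
EPOCH_S <- 32
IMG_HZ <- 1.8
EYE_HZ <- 60
FRAMES_PER_EPOCH <- 57L
VRV_FRAMES <- 38L
N_STIM <- 18L
N_SPOT <- 16L

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not perturb the caller's
#' random stream. With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Truncated-normal draws by inverse-CDF (vectorised, exact).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Centered running mean with window `k` samples (k rounded up to odd).
running_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  y <- stats::filter(x, rep(1 / k, k), sides = 2)
  y <- as.numeric(y)
  # shrink the window at the edges instead of returning NA
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(x)
  for (i in seq_len(min(h, n))) {
    y[i] <- cs[min(n, i + h)] / min(n, i + h)
    j <- n - i + 1L
    lo <- max(1L, j - h)
    y[j] <- (cs[n] - if (lo > 1L) cs[lo - 1L] else 0) / (n - lo + 1L)
  }
  y
}

# Circular mean / SD of angles in degrees.
circ_mean_deg <- function(x) {
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

circ_sd_deg <- function(x) {
  r <- x * pi / 180
  R <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  R <- min(max(R, .Machine$double.eps), 1)
  sqrt(-2 * log(R)) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
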