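# Internal helpers shared across modules.

# Parameter-validation error naming the offending field.
abort_param <- function(field, msg) {
  abort(paste0("invalid parameter `", field, "`: ", msg), class = "cardiophen_param_error")
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_param(field, "must be a single finite value > 0")
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_param(field, "must be a single finite value >= 0")
  }
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    abort_param(field, paste0("must be an integer >= ", min))
  }
  invisible(as.integer(x))
}

# Evaluate expr with a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one base seed (keeps each below 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Raised-cosine bump with compact support [center - halfwidth, center + halfwidth].
# Analytic landmarks (support edges, extremum at `center`) make it the building
# block of the synthetic beat templates.
rc_bump <- function(t, center, halfwidth, amp) {
  u <- (t - center) / halfwidth
  out <- numeric(length(t))
  inside <- abs(u) < 1
  out[inside] <- amp * 0.5 * (1 + cos(pi * u[inside]))
  out
}

# Sample coefficient of variation (n - 1 denominator), shared definition.
sample_cv <- function(x) stats::sd(x) / mean(x)

# Centered finite-difference derivative on a uniform grid.
central_diff <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}

# Moving-average smoother with odd window length (samples).
moving_average <- function(y, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width <= 1L) return(y)
  k <- rep(1 / width, width)
  n <- length(y)
  pad <- (width - 1L) %/% 2L
  yp <- c(rep(y[1], pad), y, rep(y[n], pad))
  as.numeric(stats::filter(yp, k, sides = 2))[(pad + 1L):(pad + n)]
}

# Savitzky-Golay smoothing with width given in ms; degrades gracefully on
# very short inputs.
sgolay_smooth <- function(y, sampling_rate, width_ms = 9, order = 3) {
  n_w <- round(width_ms * sampling_rate / 1000)
  if (n_w %% 2 == 0) n_w <- n_w + 1
  n_w <- max(n_w, order + 2 + (order %% 2 == 0))
  if (n_w %% 2 == 0) n_w <- n_w + 1
  if (length(y) <= n_w) return(y)
  as.numeric(signal::sgolayfilt(y, p = order, n = n_w))
}

is_uniform_time <- function(time, tol = 0.01) {
  dt <- diff(time)
  m <- stats::median(dt)
  all(abs(dt - m) <= tol * m)
}
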