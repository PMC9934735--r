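#' @title Variance-preserving noise schedules
#' @name noise_schedule
#' @description
#' Tables of signal and noise levels \eqn{\alpha_t, \sigma_t} over `T` steps
#' satisfying the variance-preserving identity \eqn{\alpha_t^2+\sigma_t^2=1},
#' with \eqn{\alpha_0\approx 1} (clean data) and \eqn{\alpha_T\approx 0}
#' (pure noise). Two parametric families are provided: the polynomial
#' \eqn{\alpha^2}-schedule (default) and the cosine schedule; both clamp the
#' endpoints by a small `precision` so no level is exactly 0 or 1, and both
#' clip per-step ratios so the chain never loses more than a fixed fraction
#' of signal in one step.
NULL

#' Build a variance-preserving noise schedule
#'
#' @param kind "polynomial" or "cosine".
#' @param T_steps number of diffusion steps (default 1000, the step count
#'   used for high-quality generation).
#' @param precision small endpoint clamp (default 1e-5).
#' @param power exponent of the polynomial schedule (default 2).
#' @return object of class `noise_schedule` with fields `T`, `alphas`,
#'   `sigmas` (numeric vectors of length `T+1`, entry `t+1` holding level
#'   \eqn{\alpha_t}).
#' @export
make_schedule <- function(kind = c("polynomial", "cosine"), T_steps = 1000L,
                          precision = 1e-5, power = 2) {
  kind <- match.arg(kind)
  if (T_steps < 1L) stop("T_steps must be >= 1")
  steps <- T_steps + 1L
  alphas2 <- switch(kind,
    polynomial = {
      x <- seq(0, 1, length.out = steps)
      clip_schedule((1 - x^power)^2)
    },
    cosine = {
      s <- 0.008
      x <- seq(0, 1, length.out = steps)
      f <- cos((x + s) / (1 + s) * pi / 2)^2
      clip_schedule(f / f[1])
    })
  alphas2 <- (1 - 2 * precision) * alphas2 + precision
  structure(list(kind = kind, T = T_steps, precision = precision,
                 alphas = sqrt(alphas2), sigmas = sqrt(1 - alphas2)),
            class = "noise_schedule")
}

# Clip per-step alpha^2 ratios to [0.001, 1] so single steps never collapse.
clip_schedule <- function(alphas2) {
  ratios <- alphas2[-1] / alphas2[-length(alphas2)]
  ratios <- pmin(pmax(ratios, 0.001), 1)
  cumprod(c(1, ratios))
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> %s, T=%d, alpha_T=%.3g\n",
              x$kind, x$T, x$alphas[x$T + 1]))
  invisible(x)
}

#' Signal and noise levels at a schedule step
#'
#' Accessors for \eqn{\alpha_t} and \eqn{\sigma_t} (vectorized over `t`,
#' valid for `t` in `0..T`).
#'
#' @param schedule a `noise_schedule`.
#' @param t integer step(s).
#' @return numeric vector of levels.
#' @export
sched_alpha <- function(schedule, t) schedule$alphas[t + 1L]

#' @rdname sched_alpha
#' @export
sched_sigma <- function(schedule, t) schedule$sigmas[t + 1L]

#' Transition coefficients between two schedule steps
#'
#' For steps `s < t`, the conditional \eqn{q(z_t | z_s)} is Gaussian with
#' signal coefficient \eqn{\alpha_{t|s} = \alpha_t/\alpha_s} and variance
#' \eqn{\sigma_{t|s}^2 = \sigma_t^2 - \alpha_{t|s}^2 \sigma_s^2}. The squared
#' \eqn{\alpha_{t|s}} in the variance is required for Gaussian composition
#' (composing \eqn{q(z_s|z_0)} with \eqn{q(z_t|z_s)} must reproduce
#' \eqn{q(z_t|z_0)}); this identity is verified by a Monte-Carlo oracle in
#' the test suite.
#'
#' @param schedule a `noise_schedule`.
#' @param s,t integer steps with `0 <= s < t <= T`.
#' @return list with `alpha_ts` and `sigma_ts` (standard deviation).
#' @export
transition_coeffs <- function(schedule, s, t) {
  if (s < 0 || t > schedule$T || s >= t)
    stop("need 0 <= s < t <= T")
  a <- sched_alpha(schedule, t) / sched_alpha(schedule, s)
  var <- sched_sigma(schedule, t)^2 - a^2 * sched_sigma(schedule, s)^2
  list(alpha_ts = a, sigma_ts = sqrt(max(var, 0)))
}
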