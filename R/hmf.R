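#' Hartley Modulating Function machinery
#'
#' The expression dynamics of every (organ, gene) node are modelled by the
#' linear system dE/dt = K E over a record window t in [0, T].  Multiplying
#' the system by modulating functions phi_m that vanish at both ends of the
#' record and integrating converts coefficient estimation into a linear
#' regression between frequency-domain quantities:
#'
#'   Hbar1(m w0)  =  sum_j Hbar_j(m w0) * k_j
#'
#' where Hbar and Hbar1 are the HMF spectra of a profile and of its first
#' derivative.  No numerical differentiation of the sampled data is ever
#' required; all integrals are evaluated in closed form for the
#' piecewise-linear interpolant of the sampled profile.
#'
#' @name hmf
NULL

# cas kernel of the Hartley transform
cas <- function(x) sin(x) + cos(x)

# derivative of cas
cas_deriv <- function(x) cos(x) - sin(x)

#' Modulating-function specification
#'
#' Fixes the record length `T` (in weeks; last minus first sample age), the
#' fundamental frequency `omega0 = 2*pi/T`, and the system order `n` (1 for
#' the first-order expression model).  The degenerate frequency index
#' `n + m - j = 0` (arising at m = -1 and m = 0) is replaced by `eps_freq`
#' so the corresponding spectral terms stay informative rather than
#' collapsing to the analytically degenerate case.
#'
#' @param T_record record length, last minus first sample time (weeks).
#' @param n system order; only first-order systems (`n = 1`) are supported
#'   downstream.
#' @param eps_freq replacement for a zero frequency index.
#' @return an object of class `"hmf_spec"`: list with `n`, `T`, `omega0`,
#'   `eps_freq`.
#' @export
hmf_spec <- function(T_record, n = 1L, eps_freq = 1e-6) {
  stopifnot(is.numeric(T_record), T_record > 0, n >= 1)
  structure(
    list(n = as.integer(n), T = as.numeric(T_record),
         omega0 = 2 * pi / T_record, eps_freq = eps_freq),
    class = "hmf_spec"
  )
}

# frequency indices n + m - j for j = 0..n, with the degenerate 0 replaced
# by eps_freq
freq_indices <- function(m, spec) {
  idx <- spec$n + m - (0:spec$n)
  idx[idx == 0] <- spec$eps_freq
  idx
}

#' Evaluate a modulating function
#'
#' phi_m(t) = sum_{j=0..n} (-1)^j choose(n, j) cas((n + m - j) omega0 t).
#' For n = 1 every phi_m vanishes at t = 0 and t = T (exactly for
#' non-degenerate m; to within `eps_freq` when the index substitution is in
#' force).
#'
#' @param t time(s) within `[0, T]`, measured from the start of the record.
#' @param m integer modulating-function index.
#' @param spec an [hmf_spec()].
#' @return phi_m evaluated at `t` (vectorized over `t`).
#' @export
modulating_function <- function(t, m, spec) {
  idx <- freq_indices(m, spec)
  j <- 0:spec$n
  out <- 0
  for (jj in seq_along(j)) {
    out <- out + (-1)^j[jj] * choose(spec$n, j[jj]) *
      cas(idx[jj] * spec$omega0 * t)
  }
  out
}

# time derivative of phi_m, used by the independent oracle
modulating_function_deriv <- function(t, m, spec) {
  idx <- freq_indices(m, spec)
  j <- 0:spec$n
  out <- 0
  for (jj in seq_along(j)) {
    out <- out + (-1)^j[jj] * choose(spec$n, j[jj]) *
      idx[jj] * spec$omega0 * cas_deriv(idx[jj] * spec$omega0 * t)
  }
  out
}

# closed-form integral of (a*t + b) * cas(w*t) over [t0, t1]; w may be 0.
# For |w t| << 1 the exact antiderivative cancels catastrophically (1/w^2
# terms), so a truncated cas power series is integrated term-wise instead;
# at the switch point |w t| = 1e-2 the truncation error is ~1e-18.
segment_cas_integral <- function(a, b, w, t0, t1) {
  if (w == 0) {
    return(a * (t1^2 - t0^2) / 2 + b * (t1 - t0))
  }
  if (abs(w) * max(abs(t0), abs(t1)) < 1e-2) {
    # cas(x) = sum_k c_k x^k with c from interleaved sin/cos series
    ck <- c(1, 1, -1 / 2, -1 / 6, 1 / 24, 1 / 120, -1 / 720, -1 / 5040)
    k <- seq_along(ck) - 1
    term <- function(t) sum(ck * w^k * (a * t^(k + 2) / (k + 2) +
                                          b * t^(k + 1) / (k + 1)))
    return(term(t1) - term(t0))
  }
  F1 <- function(t) (t / w) * (sin(w * t) - cos(w * t)) +
    (cos(w * t) + sin(w * t)) / w^2          # antiderivative of t*cas(wt)
  F0 <- function(t) (sin(w * t) - cos(w * t)) / w  # antiderivative of cas(wt)
  a * (F1(t1) - F1(t0)) + b * (F0(t1) - F0(t0))
}

#' Hartley transform of a piecewise-linear profile
#'
#' H(w) = integral over the record of E(t) cas(w t) dt, evaluated exactly
#' for the linear interpolant between adjacent sample points.  Times are
#' shifted so the first sample sits at t = 0; a profile with an interior
#' sample missing (e.g. one organ lacking one age) simply integrates over
#' its own, longer segments.
#'
#' @param times strictly increasing sample times (weeks).
#' @param values profile values at `times`.
#' @param omega angular frequency (rad/week); `omega = 0` gives the plain
#'   area under the interpolant.
#' @return the transform value H(omega), a single number.
#' @export
hartley_transform <- function(times, values, omega) {
  stopifnot(length(times) == length(values), length(times) >= 2,
            all(diff(times) > 0), all(is.finite(values)))
  tau <- times - times[1]
  total <- 0
  for (s in seq_len(length(tau) - 1)) {
    t0 <- tau[s]; t1 <- tau[s + 1]
    a <- (values[s + 1] - values[s]) / (t1 - t0)
    b <- values[s] - a * t0
    total <- total + segment_cas_integral(a, b, omega, t0, t1)
  }
  total
}

#' HMF spectral component of a profile
#'
#' Hbar(m w0) = sum_{j=0..n} (-1)^j choose(n, j) H((n + m - j) w0), the
#' frequency-domain evaluation of the inner product of the profile with
#' phi_m.  Equivalent (for the piecewise-linear interpolant) to the
#' time-domain integral of phi_m(t) E(t).
#'
#' @inheritParams hartley_transform
#' @param m integer modulating-function index.
#' @param spec an [hmf_spec()].
#' @return the spectral value, a single number.
#' @export
hmf_spectrum <- function(times, values, m, spec) {
  idx <- freq_indices(m, spec)
  j <- 0:spec$n
  out <- 0
  for (jj in seq_along(j)) {
    out <- out + (-1)^j[jj] * choose(spec$n, j[jj]) *
      hartley_transform(times, values, idx[jj] * spec$omega0)
  }
  out
}

# Sign convention of the derivative spectrum, calibrated once against the
# integration-by-parts oracle: the i-th derivative picks up a factor
# (cas'(pi/2))^i = (-1)^i from the Hartley derivative theorem.
.hmf_deriv_sign <- function(i) (-1)^i

#' HMF spectrum of the first derivative of a profile
#'
#' Hbar1(m w0) = integral of phi_m(t) dE/dt dt, evaluated in the frequency
#' domain:
#'
#'   Hbar1(m w0) = sum_j (-1)^(j+1) choose(n, j) ((n+m-j) w0) H(-(n+m-j) w0)
#'
#' which follows from integration by parts (phi_m vanishes at both record
#' endpoints) together with cas'(x) = cas(-x).  The convention is validated
#' against [derivative_spectrum_oracle()].
#'
#' @inheritParams hmf_spectrum
#' @param i derivative order; only `i = 1` is supported.
#' @return the derivative-spectrum value, a single number.
#' @export
hmf_derivative_spectrum <- function(times, values, m, spec, i = 1L) {
  stopifnot(i == 1L)
  idx <- freq_indices(m, spec)
  j <- 0:spec$n
  out <- 0
  for (jj in seq_along(j)) {
    out <- out + (-1)^j[jj] * choose(spec$n, j[jj]) * .hmf_deriv_sign(i) *
      (idx[jj] * spec$omega0)^i *
      hartley_transform(times, values, (-1)^i * idx[jj] * spec$omega0)
  }
  out
}

#' Independent time-domain oracle for the derivative spectrum
#'
#' Computes -integral of phi_m'(t) E(t) dt by adaptive quadrature over each
#' linear segment of the profile.  Because phi_m vanishes at t = 0 and
#' t = T, this equals the integral of phi_m dE/dt by parts, without ever
#' touching the frequency-domain path used by
#' [hmf_derivative_spectrum()] — it serves as that function's independent
#' cross-check.
#'
#' @inheritParams hmf_spectrum
#' @return the reference value, a single number.
#' @export
derivative_spectrum_oracle <- function(times, values, m, spec) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  tau <- times - times[1]
  total <- 0
  for (s in seq_len(length(tau) - 1)) {
    t0 <- tau[s]; t1 <- tau[s + 1]
    a <- (values[s + 1] - values[s]) / (t1 - t0)
    b <- values[s] - a * t0
    f <- function(t) modulating_function_deriv(t, m, spec) * (a * t + b)
    total <- total + stats::integrate(f, t0, t1, rel.tol = 1e-11,
                                      abs.tol = 1e-13,
                                      subdivisions = 500L)$value
  }
  -total
}
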