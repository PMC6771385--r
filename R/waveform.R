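#' Sum-of-exponentials waveform for pause/body profile rendering
#'
#' Steady states are visualized as a smooth curve with an exponential rise to
#' a promoter-proximal peak followed by decay to a stable gene-body plateau:
#'
#' \deqn{density(bp) = \frac{pk_{pause}}{pk}\left[
#'   \frac{bp}{\tau} e^{-(bp-\tau)/\tau} +
#'   pk_{body}\,(1 - e^{-bp/\tau})\right]}
#'
#' where `tau` (bp) sets the width of the peak. The normalization constant
#' `pk` is chosen with [calibrate_pk()] so that the curve's maximum equals
#' `pk_pause`; the shape parameter `pk_body` is solved with [solve_pk_body()]
#' so the asymptote `pk_body * pk_pause / pk` hits a requested plateau. The
#' curve is zero at the origin and non-negative everywhere.
#'
#' @param bp Position(s) in bp downstream of the start; must be >= 0.
#'   Treated as continuous.
#' @param tau Exponential decay constant in bp (> 0). The default used
#'   throughout the package is 25 bp, which places the peak inside a
#'   sub-100-bp pause window.
#' @param pk_pause Desired peak height (typically a condition's `p_ss`).
#' @param pk_body Plateau shape parameter (>= 0).
#' @param pk Normalization constant; if `NULL` (default) it is computed with
#'   [calibrate_pk()] so that `max(density) = pk_pause`.
#' @return Density value(s) at `bp`.
#' @examples
#' waveform_density(0, tau = 25, pk_pause = 1, pk_body = 0.3)     # 0
#' waveform_density(2500, tau = 25, pk_pause = 1, pk_body = 0.3)  # ~plateau
#' @seealso [peak_location()], [solve_pk_body()], [render_condition_profiles()]
#' @export
waveform_density <- function(bp, tau = 25, pk_pause = 1, pk_body, pk = NULL) {
  if (any(!is.finite(bp)) || any(bp < 0))
    stop("bp must be non-negative", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (pk_body < 0) stop("pk_body must be >= 0", call. = FALSE)
  if (is.null(pk)) pk <- calibrate_pk(tau, pk_body)
  (pk_pause / pk) *
    ((bp / tau) * exp(-(bp - tau) / tau) + pk_body * (1 - exp(-bp / tau)))
}

#' Analytic peak position of the waveform
#'
#' The derivative of the waveform has a single positive root,
#' `bp* = tau * (pk_body + e) / e`, which is the position of the maximum.
#' With `pk_body = 0` this reduces to `bp* = tau`.
#'
#' @inheritParams waveform_density
#' @return Peak position in bp.
#' @examples
#' peak_location(25, 0)    # 25
#' peak_location(25, 0.3)  # 27.759...
#' @export
peak_location <- function(tau, pk_body) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (pk_body < 0) stop("pk_body must be >= 0", call. = FALSE)
  tau * (pk_body + exp(1)) / exp(1)
}

#' Normalization constant that makes the peak equal pk_pause
#'
#' Evaluates the unnormalized waveform bracket at its analytic maximum
#' [peak_location()]; dividing by this value rescales the curve so that its
#' maximum is exactly `pk_pause`.
#'
#' @inheritParams waveform_density
#' @return The normalization constant `pk` (> 0).
#' @examples
#' calibrate_pk(25, 0)  # 1: the first term alone peaks at exactly 1
#' @export
calibrate_pk <- function(tau, pk_body) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (pk_body < 0) stop("pk_body must be >= 0", call. = FALSE)
  bp <- peak_location(tau, pk_body)
  (bp / tau) * exp(-(bp - tau) / tau) + pk_body * (1 - exp(-bp / tau))
}

#' Solve for the plateau shape parameter
#'
#' The asymptotic plateau of the calibrated waveform is
#' `pk_body * pk_pause / pk`, but `pk` itself depends on `pk_body`, so
#' hitting a requested plateau is an implicit one-dimensional root-finding
#' problem. The map `pk_body -> pk_body / pk(pk_body)` is continuous and
#' increasing from 0 towards 1, so a bracketed root always exists for
#' `0 <= plateau_target < pk_pause`; it is located with [stats::uniroot()]
#' at tolerance 1e-10.
#'
#' @param plateau_target Desired asymptotic level (typically `b_ss`);
#'   must satisfy `0 <= plateau_target < pk_pause`.
#' @inheritParams waveform_density
#' @return The value of `pk_body` whose calibrated waveform has asymptote
#'   `plateau_target`.
#' @examples
#' pkb <- solve_pk_body(0.005, pk_pause = 1, tau = 25)
#' wf <- waveform_density(25 * 100, tau = 25, pk_pause = 1, pk_body = pkb)
#' abs(wf - 0.005) < 1e-8
#' @export
solve_pk_body <- function(plateau_target, pk_pause, tau = 25) {
  if (pk_pause <= 0) stop("pk_pause must be > 0", call. = FALSE)
  if (plateau_target < 0)
    stop("plateau_target must be >= 0", call. = FALSE)
  if (plateau_target >= pk_pause)
    stop("infeasible shape: the peak (pk_pause) must exceed the plateau",
         call. = FALSE)
  if (plateau_target == 0) return(0)
  target <- plateau_target / pk_pause  # solve pk_body / pk(pk_body) = target
  g <- function(x) x / calibrate_pk(tau, x) - target
  upper <- 1
  while (g(upper) < 0) upper <- upper * 2
  stats::uniroot(g, lower = 0, upper = upper, tol = 1e-14)$root
}

#' Render smooth profiles for a set of model conditions
#'
#' Draws one calibrated waveform per condition, with the peak set to that
#' condition's steady-state pause density and the plateau to its gene-body
#' density. Scaling `k_init` rescales the whole curve; raising `k_pre`
#' lowers it pointwise.
#'
#' @param conditions A named list of [steady_state()] objects (or a single
#'   one). Each must have `p_ss > b_ss > 0`.
#' @param tau Waveform decay constant in bp; default 25.
#' @param length Extent in bp; the curve is sampled at 1-bp steps on
#'   `0:length`.
#' @return A data.frame with column `bp` and one density column per
#'   condition, named after `conditions`.
#' @examples
#' ref <- steady_state(rate_params(1, 0.5, 0.5, 1))
#' up <- steady_state(perturb_params(rate_params(1, 0.5, 0.5, 1), "k_init", 1.25))
#' prof <- render_condition_profiles(list(reference = ref, init_up = up),
#'                                   length = 1000)
#' @export
render_condition_profiles <- function(conditions, tau = 25, length = 2000) {
  if (inherits(conditions, "steady_state")) conditions <- list(conditions)
  if (length(conditions) == 0) stop("no conditions supplied", call. = FALSE)
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    names(conditions) <- paste0("condition_", seq_along(conditions))
  bp <- seq(0, length, by = 1)
  out <- data.frame(bp = bp)
  for (nm in names(conditions)) {
    ss <- conditions[[nm]]
    if (!is.numeric(ss$p_ss) || !is.numeric(ss$b_ss) ||
        ss$b_ss <= 0 || ss$p_ss <= ss$b_ss)
      stop("infeasible shape for condition '", nm,
           "': need p_ss > b_ss > 0", call. = FALSE)
    pkb <- solve_pk_body(ss$b_ss, pk_pause = ss$p_ss, tau = tau)
    out[[nm]] <- waveform_density(bp, tau = tau, pk_pause = ss$p_ss,
                                  pk_body = pkb)
  }
  out
}
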