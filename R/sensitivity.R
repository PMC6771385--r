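#' @name sensitivity
#' @title Exact parameter-sensitivity algebra for the pausing model
#'
#' @description
#' Because the steady states are closed-form rational functions of the rate
#' constants, the change in `p_ss` or `b_ss` when one constant moves from a
#' low value `k_lo` to a high value `k_hi` is itself available in closed form
#' -- exactly, not merely to first order. With `params` supplying the other
#' (fixed) constants:
#'
#' * `k_init`:  `delta_p = (k_hi - k_lo)/(k_pre + k_rel)` and
#'   `delta_b = r k_rel (k_hi - k_lo) / (k_term (k_pre + k_rel))` -- both
#'   positive, so more initiation raises pause and body together.
#' * `k_pre`:  both changes carry the factor `(k_lo - k_hi) < 0`: faster
#'   premature release drains pause and body together.
#' * `k_rel`:  `delta_p < 0` but `delta_b > 0` (its numerator carries
#'   `k_pre`; when `k_pre = 0` the body is exactly unaffected because every
#'   paused polymerase eventually elongates regardless of how fast).
#' * `k_term`: `delta_p = 0` identically; `delta_b < 0`.
#'
#' The sign table (+/+, -/-, -/+, 0/-) is therefore analytic, never
#' borderline. Infinitesimal sensitivities (partial derivatives at the
#' reference point) are provided alongside via [sensitivity_partials()].
NULL

param_names <- c("k_init", "k_pre", "k_rel", "k_term")

check_perturbation <- function(params, parameter, k_hi, k_lo) {
  parameter <- match.arg(parameter, param_names)
  if (!is.numeric(k_hi) || !is.numeric(k_lo) ||
      length(k_hi) != 1L || length(k_lo) != 1L ||
      !is.finite(k_hi) || !is.finite(k_lo))
    stop("k_hi and k_lo must be single finite numbers", call. = FALSE)
  if (k_hi <= k_lo)
    stop("k_hi must exceed k_lo", call. = FALSE)
  if (parameter %in% c("k_init", "k_pre") && k_lo < 0)
    stop(parameter, " values must be >= 0", call. = FALSE)
  if (parameter %in% c("k_rel", "k_term") && k_lo <= 0)
    stop(parameter, " values must be > 0", call. = FALSE)
  parameter
}

#' Exact change in steady-state pause density under a parameter change
#'
#' @param params A [rate_params()] object holding the unchanged constants
#'   (the entry named by `parameter` is ignored in favour of `k_lo`/`k_hi`).
#' @param parameter Which constant is varied: `"k_init"`, `"k_pre"`,
#'   `"k_rel"` or `"k_term"`.
#' @param k_hi,k_lo High and low values, `k_hi > k_lo`.
#' @return The exact change `p_ss(k_hi) - p_ss(k_lo)`; identically 0 for
#'   `k_term`, which does not enter `p_ss`.
#' @examples
#' pp <- rate_params(1, 0.5, 0.5, 1)
#' delta_p(pp, "k_init", k_hi = 1.25, k_lo = 1)  # 0.25
#' delta_p(pp, "k_term", k_hi = 2, k_lo = 1)     # exactly 0
#' @seealso [delta_b()], [sensitivity_table()], [effect_ratio()]
#' @export
delta_p <- function(params, parameter, k_hi, k_lo) {
  params <- as_rate_params(params)
  parameter <- check_perturbation(params, parameter, k_hi, k_lo)
  with(params, switch(parameter,
    k_init = (k_hi - k_lo) / (k_pre + k_rel),
    k_pre  = k_init * (k_lo - k_hi) / ((k_hi + k_rel) * (k_lo + k_rel)),
    k_rel  = k_init * (k_lo - k_hi) / ((k_pre + k_hi) * (k_pre + k_lo)),
    k_term = 0
  ))
}

#' Exact change in steady-state gene-body density under a parameter change
#'
#' @inheritParams delta_p
#' @return The exact change `b_ss(k_hi) - b_ss(k_lo)`; identically 0 for
#'   `k_rel` when `k_pre = 0`.
#' @examples
#' pp <- rate_params(1, 0.5, 0.5, 1)
#' delta_b(pp, "k_init", k_hi = 1.25, k_lo = 1)  # 0.00125
#' @export
delta_b <- function(params, parameter, k_hi, k_lo) {
  params <- as_rate_params(params)
  parameter <- check_perturbation(params, parameter, k_hi, k_lo)
  with(params, switch(parameter,
    k_init = r * k_rel * (k_hi - k_lo) / (k_term * (k_pre + k_rel)),
    k_pre  = r * k_rel * k_init * (k_lo - k_hi) /
               (k_term * (k_hi + k_rel) * (k_lo + k_rel)),
    k_rel  = r * k_init * k_pre * (k_hi - k_lo) /
               (k_term * (k_pre + k_hi) * (k_pre + k_lo)),
    k_term = r * k_rel * k_init * (k_lo - k_hi) /
               (k_hi * k_lo * (k_pre + k_rel))
  ))
}

#' Partial derivatives of the steady states at the reference parameters
#'
#' @inheritParams delta_p
#' @return Named numeric vector `c(partial_p, partial_b)`: the derivatives of
#'   `p_ss` and `b_ss` with respect to `parameter`, evaluated at `params`.
#' @export
sensitivity_partials <- function(params, parameter) {
  params <- as_rate_params(params)
  parameter <- match.arg(parameter, param_names)
  with(params, {
    a <- k_pre + k_rel
    switch(parameter,
      k_init = c(partial_p = 1 / a,
                 partial_b = r * k_rel / (k_term * a)),
      k_pre  = c(partial_p = -k_init / a^2,
                 partial_b = -r * k_rel * k_init / (k_term * a^2)),
      k_rel  = c(partial_p = -k_init / a^2,
                 partial_b = r * k_init * k_pre / (k_term * a^2)),
      k_term = c(partial_p = 0,
                 partial_b = -r * k_rel * k_init / (k_term^2 * a))
    )
  })
}

sign_label <- function(x) c("-", "0", "+")[sign(x) + 2]

#' Sensitivity summary table for all four rate constants
#'
#' Evaluates the exact finite-change sensitivities [delta_p()] / [delta_b()]
#' and the analytic partials for each rate constant in turn, perturbing each
#' from its current value `k` to `k * fold`, and classifies the signs. For
#' any positive parameter set the sign pattern is
#' `k_init (+,+), k_pre (-,-), k_rel (-,+), k_term (0,-)`; when `k_pre = 0`
#' the `k_rel` row degenerates to `(-,0)`.
#'
#' @param params A [rate_params()] object; `k_init > 0` required for a
#'   non-degenerate table.
#' @param fold Relative increase applied to each parameter (default 1.1,
#'   i.e. +10%). Must be > 1.
#' @return A data.frame with one row per parameter and columns `parameter`,
#'   `k_lo`, `k_hi`, `delta_p`, `delta_b`, `sign_p`, `sign_b`, `partial_p`,
#'   `partial_b`.
#' @examples
#' sensitivity_table(rate_params(1, 0.5, 0.5, 1))
#' @export
sensitivity_table <- function(params, fold = 1.1) {
  params <- as_rate_params(params)
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  rows <- lapply(param_names, function(pn) {
    k_lo <- params[[pn]]
    if (k_lo <= 0 && pn %in% c("k_rel", "k_term"))
      stop(pn, " must be > 0 for the sensitivity table", call. = FALSE)
    if (k_lo == 0) {
      # a zero reference value cannot be scaled; use an absolute step
      k_hi <- fold - 1
    } else {
      k_hi <- k_lo * fold
    }
    dp <- delta_p(params, pn, k_hi = k_hi, k_lo = k_lo)
    db <- delta_b(params, pn, k_hi = k_hi, k_lo = k_lo)
    part <- sensitivity_partials(params, pn)
    data.frame(parameter = pn, k_lo = k_lo, k_hi = k_hi,
               delta_p = dp, delta_b = db,
               sign_p = sign_label(dp), sign_b = sign_label(db),
               partial_p = unname(part["partial_p"]),
               partial_b = unname(part["partial_b"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Effect ratio of a pause-density change to a body-density change
#'
#' For perturbations of `k_init` or `k_pre` -- the two constants that move
#' pause and body in the same direction -- the ratio of the exact changes is
#' independent of the perturbation size and equals the pause index:
#' \deqn{\Delta p / \Delta b = P_i = k_{term}/(r\,k_{rel}).}
#' The pause effect exceeds the body effect (`|delta_p| > |delta_b|`, i.e.
#' `P_i > 1`) exactly when `k_rel / k_term < l_b / l_p`; with a <100 bp pause
#' region and a ~10 kb body, `l_b / l_p` is of order 100, so the condition
#' holds for any plausible rates.
#'
#' @inheritParams delta_p
#' @param parameter `"k_init"` or `"k_pre"`. `k_rel` and `k_term` are
#'   rejected: their perturbations move `p_ss` and `b_ss` in opposite
#'   directions (or not at all), so the identity does not apply.
#' @return An object of class `effect_ratio_report`: list with `ratio`
#'   (`delta_p / delta_b`), `delta_p`, `delta_b`, `pause_index`, and
#'   `condition_met` (`k_rel / k_term < l_b / l_p`).
#' @examples
#' pp <- rate_params(1, 0.5, 0.5, 1)
#' effect_ratio(pp, "k_init", k_hi = 1.25, k_lo = 1)$ratio  # 200
#' effect_ratio(pp, "k_pre", k_hi = 0.8, k_lo = 0.5)$ratio  # 200
#' @export
effect_ratio <- function(params, parameter, k_hi, k_lo) {
  params <- as_rate_params(params)
  if (!parameter %in% c("k_init", "k_pre"))
    stop("effect ratio is defined only for k_init and k_pre perturbations",
         call. = FALSE)
  if (params$k_rel <= 0)
    stop("effect ratio requires k_rel > 0 (otherwise delta_b = 0)",
         call. = FALSE)
  dp <- delta_p(params, parameter, k_hi = k_hi, k_lo = k_lo)
  db <- delta_b(params, parameter, k_hi = k_hi, k_lo = k_lo)
  pi <- params$k_term / (params$r * params$k_rel)
  structure(
    list(parameter = parameter, k_lo = k_lo, k_hi = k_hi,
         delta_p = dp, delta_b = db, ratio = dp / db,
         pause_index = pi,
         condition_met = params$k_rel / params$k_term < params$l_b / params$l_p),
    class = "effect_ratio_report"
  )
}

#' @export
print.effect_ratio_report <- function(x, ...) {
  cat(sprintf("Effect ratio for %s: %g -> %g\n", x$parameter, x$k_lo, x$k_hi))
  cat(sprintf("  delta_p = %g, delta_b = %g, delta_p/delta_b = %g\n",
              x$delta_p, x$delta_b, x$ratio))
  cat(sprintf("  pause index = %g; pause effect dominates: %s\n",
              x$pause_index, x$condition_met))
  invisible(x)
}
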