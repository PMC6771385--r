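#' Two-compartment model of promoter-proximal pausing
#'
#' The model tracks two Pol II densities (polymerases per unit DNA length):
#' `p`, the density in the short promoter-proximal pause region, and `b`, the
#' density in the long gene body. Initiation feeds the pause region at rate
#' `k_init`; paused Pol II leaves either nonproductively (rate constant
#' `k_pre`) or productively into the gene body (`k_rel`); elongating Pol II
#' terminates with rate constant `k_term`. The flux into the body is scaled by
#' the length ratio `r = l_p / l_b` because the same number of polymerases is
#' spread over a much longer segment:
#'
#' \deqn{dp/dt = k_{init} - (k_{pre} + k_{rel})\,p}
#' \deqn{db/dt = r\,k_{rel}\,p - k_{term}\,b}
#'
#' Setting both derivatives to zero gives the closed-form steady state
#' \deqn{p_{ss} = k_{init}/(k_{pre}+k_{rel}), \quad
#'       b_{ss} = r\,k_{rel}\,p_{ss}/k_{term}}
#' and the pause index
#' \deqn{P_i = p_{ss}/b_{ss} = k_{term}/(r\,k_{rel}),}
#' which depends only on termination, productive release and the length
#' ratio -- not on initiation or premature release.
#'
#' @param params A [rate_params()] object with `k_pre + k_rel > 0`.
#' @return An object of class `steady_state`: a list with elements `p_ss`,
#'   `b_ss` and `pause_index` (`NA` if `k_rel = 0`, since the body is then
#'   empty and the index undefined).
#' @examples
#' ss <- steady_state(rate_params(1, 0.5, 0.5, 1))
#' ss$p_ss         # 1
#' ss$b_ss         # 0.005
#' ss$pause_index  # 200
#' @seealso [simulate_dynamics()], [pause_index()], [sensitivity_table()]
#' @export
steady_state <- function(params) {
  params <- as_rate_params(params)
  if (params$k_pre + params$k_rel <= 0)
    stop("steady state undefined: k_pre + k_rel must be > 0", call. = FALSE)
  if (params$k_term <= 0)
    stop("steady state undefined: k_term must be > 0", call. = FALSE)
  p_ss <- params$k_init / (params$k_pre + params$k_rel)
  b_ss <- params$r * params$k_rel * p_ss / params$k_term
  pi <- if (params$k_rel > 0) params$k_term / (params$r * params$k_rel)
        else NA_real_
  structure(list(p_ss = p_ss, b_ss = b_ss, pause_index = pi, params = params),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state: p_ss = %g, b_ss = %g, pause index = %g\n",
              x$p_ss, x$b_ss, x$pause_index))
  invisible(x)
}

#' Pause index from a pair of densities
#'
#' The pause index is the pause-region Pol II density relative to the
#' gene-body density, `p / b`. At steady state it equals
#' `k_term / (r * k_rel)`.
#'
#' @param p Pause-region density (>= 0). Vectorized.
#' @param b Gene-body density; every element must be > 0.
#' @return `p / b`.
#' @examples
#' pause_index(1.0, 0.005)  # 200
#' @export
pause_index <- function(p, b) {
  if (any(!is.finite(b)) || any(b <= 0))
    stop("pause index undefined for gene-body density <= 0", call. = FALSE)
  p / b
}

#' Integrate the pausing model dynamics
#'
#' Solves the linear two-compartment system with a stiff-safe adaptive
#' integrator (deSolve's lsoda, rtol 1e-9 / atol 1e-12) on a user-supplied
#' time grid. Trajectories started from non-negative densities stay
#' non-negative and converge to [steady_state()].
#'
#' @param params A [rate_params()] object.
#' @param init Initial state: numeric length-2 vector `c(p, b)`, both >= 0.
#' @param times Strictly increasing numeric vector of time points at which to
#'   report the state. The first entry is the initial time.
#' @return A data.frame of class `pol_trajectory` with columns `time`, `p`,
#'   `b`, one row per grid point.
#' @examples
#' pp <- rate_params(1, 0.5, 0.5, 1)
#' tr <- simulate_dynamics(pp, init = c(0, 0), times = seq(0, 10, 0.5))
#' tail(tr, 1)  # close to the steady state p_ss = 1, b_ss = 0.005
#' @export
simulate_dynamics <- function(params, init = c(0, 0), times) {
  params <- as_rate_params(params)
  init <- as.numeric(init)
  if (length(init) != 2L || anyNA(init) || any(init < 0))
    stop("init must be two non-negative densities c(p, b)", call. = FALSE)
  if (!is.numeric(times) || length(times) < 2L || any(diff(times) <= 0))
    stop("times must be a strictly increasing numeric vector", call. = FALSE)
  rhs <- function(t, y, parms) {
    dp <- parms$k_init - (parms$k_pre + parms$k_rel) * y[1]
    db <- parms$r * parms$k_rel * y[1] - parms$k_term * y[2]
    list(c(dp, db))
  }
  sol <- deSolve::lsoda(y = c(p = init[1], b = init[2]), times = times,
                        func = rhs, parms = params,
                        rtol = 1e-9, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("time", "p", "b")
  class(out) <- c("pol_trajectory", "data.frame")
  out
}

#' Closed-form solution of the pausing dynamics
#'
#' The system is linear, so its solution is available in closed form; this is
#' used as an exact cross-check of the numerical integrator. With
#' `a = k_pre + k_rel`,
#' `p(t) = p_ss + (p0 - p_ss) exp(-a t)`, and `b(t)` is the matching
#' one- or two-exponential expression (the degenerate case `a == k_term`
#' picks up a `t exp(-a t)` secular term).
#'
#' @inheritParams simulate_dynamics
#' @return A data.frame with columns `time`, `p`, `b`.
#' @keywords internal
#' @export
dynamics_closed_form <- function(params, init = c(0, 0), times) {
  params <- as_rate_params(params)
  a <- params$k_pre + params$k_rel
  kt <- params$k_term
  ss <- steady_state(params)
  p0 <- init[1]; b0 <- init[2]
  cp <- p0 - ss$p_ss
  p <- ss$p_ss + cp * exp(-a * times)
  # db/dt + kt b = r k_rel p(t); particular + homogeneous solution
  rk <- params$r * params$k_rel
  if (abs(a - kt) > 1e-12 * max(a, kt)) {
    # forced term from the exp(-a t) transient of p
    cf <- rk * cp / (kt - a)
    cb <- b0 - ss$b_ss - cf
    b <- ss$b_ss + cf * exp(-a * times) + cb * exp(-kt * times)
  } else {
    cb <- b0 - ss$b_ss
    b <- ss$b_ss + (rk * cp * times + cb) * exp(-kt * times)
  }
  data.frame(time = times, p = p, b = b)
}

#' Write a trajectory or steady state as TSV
#'
#' @param x A `pol_trajectory` data.frame or a `steady_state` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(x, path) {
  if (inherits(x, "steady_state"))
    x <- data.frame(p_ss = x$p_ss, b_ss = x$b_ss, pause_index = x$pause_index)
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
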