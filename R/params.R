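#' Rate parameters for the two-compartment pausing model
#'
#' Bundles the four rate constants of the promoter-proximal pausing model
#' together with the pause-region and gene-body lengths. The length ratio
#' `r = l_p / l_b` is always derived from the two lengths and cannot be set
#' independently, so a `rate_params` object can never carry an inconsistent
#' ratio. All quantities are treated as dimensionless.
#'
#' @param k_init Initiation rate: Pol II density gained per unit time in the
#'   pause region. Must be >= 0 (zero gives the empty-gene special case).
#' @param k_pre Rate constant for premature (nonproductive) release of paused
#'   Pol II. Must be >= 0; zero is the no-premature-release special case.
#' @param k_rel Rate constant for productive pause release into gene-body
#'   elongation. Must be >= 0.
#' @param k_term Rate constant for transcription termination. Must be > 0.
#' @param l_p Pause-region length in bp; default 100.
#' @param l_b Gene-body length in bp; default 10000. Must exceed `l_p`.
#'
#' @return An object of class `rate_params`: a named list with the six
#'   arguments plus the derived ratio `r = l_p / l_b`.
#' @examples
#' pp <- rate_params(k_init = 1, k_pre = 0.5, k_rel = 0.5, k_term = 1)
#' pp$r  # 0.01
#' @seealso [steady_state()], [simulate_dynamics()]
#' @export
rate_params <- function(k_init, k_pre, k_rel, k_term, l_p = 100, l_b = 10000) {
  vals <- c(k_init = k_init, k_pre = k_pre, k_rel = k_rel, k_term = k_term,
            l_p = l_p, l_b = l_b)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals)))
    stop("all rate parameters must be finite numbers", call. = FALSE)
  if (k_init < 0 || k_pre < 0 || k_rel < 0)
    stop("k_init, k_pre and k_rel must be >= 0", call. = FALSE)
  if (k_term <= 0)
    stop("k_term must be > 0", call. = FALSE)
  if (l_p <= 0 || l_b <= 0 || l_p >= l_b)
    stop("lengths must satisfy 0 < l_p < l_b", call. = FALSE)
  structure(
    list(k_init = k_init, k_pre = k_pre, k_rel = k_rel, k_term = k_term,
         l_p = l_p, l_b = l_b, r = l_p / l_b),
    class = "rate_params"
  )
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Two-compartment pausing model parameters\n")
  cat(sprintf("  k_init = %g   k_pre = %g   k_rel = %g   k_term = %g\n",
              x$k_init, x$k_pre, x$k_rel, x$k_term))
  cat(sprintf("  l_p = %g bp   l_b = %g bp   r = l_p/l_b = %g\n",
              x$l_p, x$l_b, x$r))
  invisible(x)
}

#' Read model parameters from a flat JSON file
#'
#' The file must contain the keys `k_init`, `k_pre`, `k_rel`, `k_term` and
#' may contain `l_p` and `l_b` (defaults 100 and 10000 bp otherwise).
#'
#' @param path Path to a JSON file.
#' @return A [rate_params()] object.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k_init", "k_pre", "k_rel", "k_term")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("parameter file ", path, " lacks keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rate_params(k_init = x$k_init, k_pre = x$k_pre, k_rel = x$k_rel,
              k_term = x$k_term,
              l_p = if (!is.null(x$l_p)) x$l_p else 100,
              l_b = if (!is.null(x$l_b)) x$l_b else 10000)
}

#' Write model parameters to a flat JSON file
#'
#' @param params A [rate_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "rate_params"))
  jsonlite::write_json(params[c("k_init", "k_pre", "k_rel", "k_term",
                                "l_p", "l_b")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Perturb one rate constant by a fold change
#'
#' Convenience constructor for a perturbed condition: returns a copy of
#' `params` with one rate constant multiplied by `fold`.
#'
#' @param params A [rate_params()] object.
#' @param parameter One of `"k_init"`, `"k_pre"`, `"k_rel"`, `"k_term"`.
#' @param fold Positive multiplicative factor.
#' @return A new [rate_params()] object.
#' @examples
#' ref <- rate_params(1, 0.5, 0.5, 1)
#' up <- perturb_params(ref, "k_init", 1.25)
#' @export
perturb_params <- function(params, parameter, fold) {
  stopifnot(inherits(params, "rate_params"))
  parameter <- match.arg(parameter, c("k_init", "k_pre", "k_rel", "k_term"))
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) || fold <= 0)
    stop("fold must be a single positive number", call. = FALSE)
  vals <- params
  vals[[parameter]] <- vals[[parameter]] * fold
  rate_params(vals$k_init, vals$k_pre, vals$k_rel, vals$k_term,
              l_p = vals$l_p, l_b = vals$l_b)
}

# internal: check a rate_params-like object, coercing plain lists
as_rate_params <- function(x) {
  if (inherits(x, "rate_params")) return(x)
  rate_params(x$k_init, x$k_pre, x$k_rel, x$k_term,
              l_p = if (!is.null(x$l_p)) x$l_p else 100,
              l_b = if (!is.null(x$l_b)) x$l_b else 10000)
}
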