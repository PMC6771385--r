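#' Map observed density changes onto model mechanisms
#'
#' Applies the model's sign logic to per-gene pause/body log2 fold changes.
#' A coordinate decrease of pause and body density is the signature of
#' reduced initiation or increased premature pause release -- the two are
#' indistinguishable from densities alone, so they are reported as one
#' equivalence class; a coordinate increase maps to the opposite class.
#' Opposite-sign changes implicate productive pause release, and a body
#' change with an (approximately) unchanged pause implicates termination,
#' which cannot move the steady-state pause density at all.
#'
#' Decision rules, with `dp = lfc_pause`, `db = lfc_body` and `tol` the
#' log2 band treated as "no change" (applied to both axes):
#' `|dp| <= tol & |db| <= tol -> none`;
#' `|dp| <= tol & db < 0 -> term_up`; `|dp| <= tol & db > 0 -> term_down`;
#' `dp < 0 & db < 0 -> init_down_or_pre_up`;
#' `dp > 0 & db > 0 -> init_up_or_pre_down`;
#' `dp < 0 & db > 0 -> rel_up`; `dp > 0 & db < 0 -> rel_down`.
#'
#' For the initiation/premature classes the observed effect ratio
#' (linear-scale `delta pause density / delta body density`) is compared
#' with the reference pause index: the model predicts they are equal, so
#' agreement within `ratio_tol` (relative) flags the call as consistent.
#'
#' @param fc A [compare_conditions()] data.frame, or any data.frame with
#'   columns `lfc_pause`, `lfc_body` and the four density columns.
#' @param p_i_ref Reference pause index; by default the median pause index
#'   is taken from the densities in `fc` (condition A).
#' @param tol Log2 fold-change magnitude treated as "no change";
#'   default 0.2. Must be > 0.
#' @param ratio_tol Relative tolerance for the effect-ratio consistency
#'   flag; default 0.5.
#' @param aggregate If `TRUE`, classify the median fold changes across all
#'   genes as a single "aggregate" record instead of per-gene calls.
#' @return A data.frame of class `mechanism_call`: `gene_id`, `sign_p`,
#'   `sign_b`, `call`, `effect_ratio_observed`, `pause_index_reference`,
#'   `consistent`.
#' @examples
#' fc <- data.frame(gene_id = "g1", lfc_pause = -0.4, lfc_body = -0.4,
#'                  pause_density_a = 1, pause_density_b = 0.76,
#'                  body_density_a = 0.005, body_density_b = 0.0038)
#' classify_mechanism(fc, p_i_ref = 200)
#' @export
classify_mechanism <- function(fc, p_i_ref = NULL, tol = 0.2,
                               ratio_tol = 0.5, aggregate = FALSE) {
  if (!is.numeric(tol) || tol <= 0)
    stop("tol must be > 0", call. = FALSE)
  need <- c("lfc_pause", "lfc_body", "pause_density_a", "pause_density_b",
            "body_density_a", "body_density_b")
  if (!all(need %in% names(fc)))
    stop("fc lacks columns: ", paste(setdiff(need, names(fc)), collapse = ", "),
         call. = FALSE)
  if (is.null(p_i_ref))
    p_i_ref <- stats::median(fc$pause_density_a / fc$body_density_a)
  if (!is.finite(p_i_ref) || p_i_ref <= 0)
    stop("p_i_ref must be > 0", call. = FALSE)
  if (aggregate) {
    fc <- data.frame(gene_id = "aggregate",
                     lfc_pause = stats::median(fc$lfc_pause),
                     lfc_body = stats::median(fc$lfc_body),
                     pause_density_a = stats::median(fc$pause_density_a),
                     pause_density_b = stats::median(fc$pause_density_b),
                     body_density_a = stats::median(fc$body_density_a),
                     body_density_b = stats::median(fc$body_density_b))
  }
  dp <- fc$lfc_pause; db <- fc$lfc_body
  if (any(!is.finite(dp)) || any(!is.finite(db)))
    stop("fold changes must be finite", call. = FALSE)
  call <- rep("none", nrow(fc))
  p0 <- abs(dp) <= tol; b0 <- abs(db) <= tol
  call[p0 & !b0 & db < 0] <- "term_up"
  call[p0 & !b0 & db > 0] <- "term_down"
  call[!p0 & dp < 0 & db < 0] <- "init_down_or_pre_up"
  call[!p0 & dp > 0 & db > 0] <- "init_up_or_pre_down"
  call[!p0 & dp < 0 & db > 0 & !b0] <- "rel_up"
  call[!p0 & dp > 0 & db < 0 & !b0] <- "rel_down"
  ratio <- (fc$pause_density_b - fc$pause_density_a) /
           (fc$body_density_b - fc$body_density_a)
  init_class <- call %in% c("init_down_or_pre_up", "init_up_or_pre_down")
  consistent <- init_class & is.finite(ratio) &
    abs(ratio / p_i_ref - 1) <= ratio_tol
  out <- data.frame(
    gene_id = fc$gene_id,
    sign_p = ifelse(p0, "0", ifelse(dp > 0, "+", "-")),
    sign_b = ifelse(b0, "0", ifelse(db > 0, "+", "-")),
    call = call,
    effect_ratio_observed = ratio,
    pause_index_reference = p_i_ref,
    consistent = consistent,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mechanism_call", "data.frame")
  out
}

#' Estimate a rate-constant fold change under an assumed mechanism
#'
#' Under the model, `p_ss` is proportional to `k_init` and inversely
#' proportional to `k_pre + k_rel`, so a pause-density ratio between
#' conditions converts directly into a rate fold change once a mechanism is
#' assumed: for `k_init` the estimate is the pause ratio itself; for the
#' combined exit pool `k_pre + k_rel` it is the inverse pause ratio. The
#' split between `k_pre` and `k_rel` is not identifiable from the two
#' densities and is never attempted.
#'
#' @param fc A [compare_conditions()] data.frame.
#' @param mechanism `"k_init"` or `"combined_k_pre_plus_k_rel"`.
#' @return Numeric vector of per-gene fold-change estimates (B over A).
#' @examples
#' # a noiseless +25% initiation change: pause ratio 1.25
#' @export
estimate_rate_change <- function(fc,
    mechanism = c("k_init", "combined_k_pre_plus_k_rel")) {
  mechanism <- match.arg(mechanism)
  ratio <- fc$pause_density_b / fc$pause_density_a
  switch(mechanism,
         k_init = ratio,
         combined_k_pre_plus_k_rel = 1 / ratio)
}

#' Fit a one-phase exponential decay
#'
#' Nonlinear least-squares fit of
#' `y(t) = (y0 - plateau) * exp(-k t) + plateau` under the constraints
#' `y0 >= plateau >= 0`, `k >= 0` (enforced by fitting `span = y0 - plateau
#' >= 0`). Three documented data-driven starts are tried
#' (Levenberg-Marquardt via minpack.lm) and the lowest-RSS fit is returned:
#' (1) `plateau` = last observation, `span` = first minus last, `k` from a
#' log-linear regression of the first half of the series; (2) `k` set for a
#' half-life of a quarter of the observed span; (3) a slow-decay start.
#'
#' @param tc A data.frame with columns `time` and `signal` (e.g. from
#'   [generate_decay_timecourse()]), at least 4 points.
#' @param fix_plateau Optional: constrain the plateau to this value
#'   (e.g. 0 for complete degradation); `NULL` (default) leaves it free.
#' @return An object of class `decay_fit`: list with `y0`, `plateau`, `k`
#'   (per min), `half_life` (`log(2)/k`, `Inf` when `k = 0`), `rss`,
#'   `fitted`, and the data.
#' @examples
#' tc <- generate_decay_timecourse(1, 0.1, 0.02)
#' fit <- fit_one_phase_decay(tc)
#' fit$half_life  # ~34.66 min
#' @export
fit_one_phase_decay <- function(tc, fix_plateau = NULL) {
  if (!all(c("time", "signal") %in% names(tc)))
    stop("tc must have 'time' and 'signal' columns", call. = FALSE)
  t <- tc$time; y <- tc$signal
  if (length(t) < 4) stop("need at least 4 time points", call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop("times and signals must be finite", call. = FALSE)

  # a constant series is fit exactly by a flat curve; the nonlinear model is
  # unidentifiable there (any k with zero span), so return k = 0 directly
  if (stats::sd(y) == 0) {
    plateau <- if (is.null(fix_plateau)) y[1] else fix_plateau
    return(structure(list(
      y0 = y[1], plateau = plateau, k = 0, half_life = Inf,
      rss = sum((y - y[1])^2), fitted = rep(y[1], length(y)),
      data = data.frame(time = t, signal = y)), class = "decay_fit"))
  }

  # start heuristics
  plat0 <- max(min(y), 0)
  span0 <- max(y[1] - plat0, .Machine$double.eps)
  half <- seq_len(max(4, floor(length(t) / 2)))
  z <- y[half] - plat0
  k0 <- if (all(z > 0) && length(unique(t[half])) > 1)
    max(-unname(stats::coef(stats::lm(log(z) ~ t[half]))[2]), 1e-6)
  else 1e-2
  t_span <- max(t) - min(t)
  starts <- list(
    c(span = span0, plateau = plat0, k = k0),
    c(span = span0, plateau = plat0, k = log(2) / (t_span / 4)),
    c(span = span0, plateau = plat0, k = 0.1 / t_span)
  )

  fit_one <- function(st) {
    tryCatch({
      if (is.null(fix_plateau)) {
        fit <- minpack.lm::nlsLM(
          y ~ span * exp(-k * t) + plateau,
          start = as.list(st),
          lower = c(span = 0, plateau = 0, k = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- stats::coef(fit)
      } else {
        fit <- minpack.lm::nlsLM(
          y ~ span * exp(-k * t) + fix_plateau,
          start = as.list(st[c("span", "k")]),
          lower = c(span = 0, k = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        cf <- c(stats::coef(fit), plateau = fix_plateau)
      }
      pred <- cf[["span"]] * exp(-cf[["k"]] * t) + cf[["plateau"]]
      list(cf = cf, rss = sum((y - pred)^2), fitted = pred)
    }, error = function(e) NULL)
  }

  fits <- Filter(Negate(is.null), lapply(starts, fit_one))
  if (length(fits) == 0)
    stop("one-phase decay fit failed to converge from all ",
         length(starts), " starts (n = ", length(t), " points, signal range ",
         signif(min(y), 4), "..", signif(max(y), 4), ")", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  k <- unname(best$cf[["k"]])
  structure(list(
    y0 = unname(best$cf[["span"]] + best$cf[["plateau"]]),
    plateau = unname(best$cf[["plateau"]]),
    k = k,
    half_life = if (k > 0) log(2) / k else Inf,
    rss = best$rss,
    fitted = best$fitted,
    data = data.frame(time = t, signal = y)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "One-phase decay fit: y0 = %.4g, plateau = %.4g, k = %.4g /min\n",
    x$y0, x$plateau, x$k))
  cat(sprintf("  half-life = %.4g min, RSS = %.4g (n = %d)\n",
              x$half_life, x$rss, nrow(x$data)))
  invisible(x)
}
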