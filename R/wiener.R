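#' Diffusion-model parameter set
#'
#' Bundles the parameters of the two-boundary Wiener diffusion process used
#' throughout the package. The three core parameters are boundary separation
#' (response caution) `a`, drift rate `v` (signed toward the correct, upper
#' boundary under accuracy coding) and non-decision time `t0`. The relative
#' start point is fixed at 0.5 (unbiased responding under accuracy coding)
#' and the within-trial diffusion coefficient is fixed at 1; neither is ever
#' estimated. A fixed proportion `pi_cont` of trials is attributed to a
#' contaminant process, uniform in time with chance responding.
#'
#' @param a boundary separation, in evidence units; must be > 0.
#' @param v drift rate, evidence units per second; positive values drive
#'   toward the upper (correct) boundary.
#' @param t0 non-decision time in seconds; must be >= 0.
#' @param z_rel relative start point; fixed constant 0.5.
#' @param s_diff within-trial diffusion coefficient; fixed constant 1.
#' @param pi_cont contaminant mixture proportion in `[0, 1)`.
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(a = 2, v = 1, t0 = 0.3)
#' choice_probability(p, "upper")
#' @export
ddm_params <- function(a, v, t0, z_rel = 0.5, s_diff = 1, pi_cont = 0.05) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number", call. = FALSE)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("'v' must be a single finite number", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0)
    stop("'t0' must be a single non-negative number", call. = FALSE)
  if (z_rel != 0.5)
    stop("the relative start point is a fixed constant (0.5)", call. = FALSE)
  if (s_diff != 1)
    stop("the diffusion coefficient is a fixed constant (1)", call. = FALSE)
  if (!is.numeric(pi_cont) || length(pi_cont) != 1L ||
      pi_cont < 0 || pi_cont >= 1)
    stop("'pi_cont' must lie in [0, 1)", call. = FALSE)
  structure(list(a = a, v = v, t0 = t0, z_rel = 0.5, s_diff = 1,
                 pi_cont = pi_cont),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "Wiener diffusion parameters: a = %.4g, v = %.4g, t0 = %.4g s (z = 0.5, s = 1, pi_cont = %.3g)\n",
    x$a, x$v, x$t0, x$pi_cont))
  invisible(x)
}

as_ddm_params <- function(params) {
  if (inherits(params, "ddm_params")) return(params)
  stop("'params' must be a 'ddm_params' object", call. = FALSE)
}

#' Wiener first-passage-time density
#'
#' Defective density of the decision time (response time minus non-decision
#' time) at one of the two absorbing boundaries. Evaluation uses the
#' alternating-series representations of the first-passage density with
#' automatic small-time/large-time selection; the truncation tolerance
#' bounds the absolute error.
#'
#' The density is defective: integrated over `t` it equals the absorption
#' probability at the chosen boundary, and the two boundaries together
#' integrate to one.
#'
#' @param t decision times in seconds; all must be > 0. The caller handles
#'   subtraction of `t0` from observed response times.
#' @param params a [ddm_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @param err absolute truncation tolerance of the series evaluation.
#' @return Numeric vector of densities (per second).
#' @examples
#' p <- ddm_params(a = 1.5, v = 1.2, t0 = 0)
#' wfpt_density(c(0.2, 0.5, 1), p, "upper")
#' @export
wfpt_density <- function(t, params, boundary = c("upper", "lower"),
                         err = 1e-11) {
  params <- as_ddm_params(params)
  boundary <- match.arg(boundary)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("'t' must contain positive decision times", call. = FALSE)
  cpp_wfpt_density(t, params$a, params$v, params$z_rel,
                   boundary == "upper", err)
}

#' Closed-form absorption probability
#'
#' Probability that the diffusion is absorbed at the named boundary
#' (the gambler's-ruin probability). For an unbiased start,
#' `P(upper) = 1 / (1 + exp(-a v))` with diffusion coefficient 1.
#'
#' @inheritParams wfpt_density
#' @return Probability in `[0, 1]`.
#' @export
choice_probability <- function(params, boundary = c("upper", "lower")) {
  params <- as_ddm_params(params)
  boundary <- match.arg(boundary)
  p_up <- cpp_prob_upper(params$a, params$v, params$z_rel)
  if (boundary == "upper") p_up else 1 - p_up
}

#' Closed-form mean decision time
#'
#' Expected first-passage time (excluding non-decision time) for an
#' unbiased start point. For zero drift this is `z (a - z)` with
#' `z = a / 2`; otherwise `(a / (2 v)) tanh(a v / 2)` (diffusion
#' coefficient 1).
#'
#' @inheritParams wfpt_density
#' @return Mean decision time in seconds.
#' @export
mean_decision_time <- function(params) {
  params <- as_ddm_params(params)
  a <- params$a; v <- params$v
  if (abs(v) < 1e-12) return(a^2 / 4)
  (a / (2 * v)) * tanh(a * v / 2)
}

#' Simulate diffusion trials
#'
#' Draws response times and boundaries from the contamination-mixture
#' diffusion process. With probability `pi_cont` a trial is a contaminant:
#' its RT is uniform over `cont_window` and its response is at chance.
#' Otherwise the diffusion runs to absorption and the RT is `t0` plus the
#' decision time.
#'
#' Two simulation methods are available: `"icdf"` draws decision times by
#' numerical inversion of the first-passage-time distribution (fast and
#' the default), while `"euler"` integrates sample paths of the process
#' with time step `dt` (slower; independent of the series density, useful
#' for cross-validation).
#'
#' @inheritParams wfpt_density
#' @param n number of trials.
#' @param seed optional integer seed for reproducibility.
#' @param method `"icdf"` or `"euler"`.
#' @param cont_window numeric length-2 vector, the contaminant RT window in
#'   seconds.
#' @param dt Euler time step in seconds (only used by `method = "euler"`).
#' @return A data.frame with columns `rt` (seconds), `boundary`
#'   (`"upper"`/`"lower"`), and `contaminant` (logical).
#' @examples
#' simulate_trials(5, ddm_params(2, 1, 0.3), seed = 1)
#' @export
simulate_trials <- function(n, params, seed = NULL,
                            method = c("icdf", "euler"),
                            cont_window = c(0.25, 5), dt = 1e-4) {
  params <- as_ddm_params(params)
  method <- match.arg(method)
  stopifnot(length(cont_window) == 2L, cont_window[2] > cont_window[1])
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_sim_wiener(as.integer(n), params$a, params$v, params$t0,
                        params$z_rel, params$pi_cont,
                        cont_window[1], cont_window[2],
                        if (method == "icdf") 0L else 1L, dt)
  data.frame(rt = out$rt,
             boundary = ifelse(out$upper == 1L, "upper", "lower"),
             contaminant = out$contaminant == 1L)
}

#' Contamination-mixture log-likelihood
#'
#' Sum over trials of `log[(1 - pi) f(rt - t0, boundary) + pi u(rt) / 2]`,
#' where `f` is the Wiener first-passage density and `u` the uniform
#' contaminant density over `cont_window`. Trials with `rt <= t0` receive
#' only the contaminant term, so the log-likelihood stays finite whenever
#' `pi_cont > 0`; with `pi_cont = 0` such trials yield `-Inf` by contract.
#'
#' @param rt observed response times in seconds (all > 0).
#' @param boundary character vector (`"upper"`/`"lower"`) or 0/1 vector
#'   (1 = upper) of the same length as `rt`.
#' @param params a [ddm_params()] object.
#' @param cont_window contaminant window; defaults to the observed RT range.
#' @param err series truncation tolerance.
#' @return The log-likelihood (a single number, possibly `-Inf`).
#' @export
mixture_loglik <- function(rt, boundary, params, cont_window = range(rt),
                           err = 1e-11) {
  params <- as_ddm_params(params)
  if (length(rt) == 0L) stop("no trials supplied", call. = FALSE)
  if (any(!is.finite(rt)) || any(rt <= 0))
    stop("'rt' must contain positive response times", call. = FALSE)
  up <- boundary_to_int(boundary, length(rt))
  cpp_mixture_loglik(rt, up, params$a, params$v, params$t0, params$z_rel,
                     params$pi_cont, cont_window[1], cont_window[2], err)
}

boundary_to_int <- function(boundary, n) {
  if (is.character(boundary) || is.factor(boundary)) {
    boundary <- as.character(boundary)
    if (!all(boundary %in% c("upper", "lower")))
      stop("'boundary' must be \"upper\" or \"lower\"", call. = FALSE)
    up <- as.integer(boundary == "upper")
  } else {
    up <- as.integer(boundary)
    if (!all(up %in% c(0L, 1L)))
      stop("numeric 'boundary' must be 0/1", call. = FALSE)
  }
  if (length(up) != n)
    stop("'boundary' and 'rt' lengths differ", call. = FALSE)
  up
}
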