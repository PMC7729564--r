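#' Kinetic mortality models
#'
#' Seven nonlinear models describe the percentage of dead cells in a well as a
#' function of time (days) after nitrogen removal. The parameterizations follow
#' the conventions of common statistical curve-fitting software:
#'
#' \describe{
#'   \item{exp2p}{`f(t) = a * exp(b * t)` — exponential growth/decay from a
#'     baseline `a` (percent at day 0) at rate `b` (per day).}
#'   \item{exp3p}{`f(t) = a + b * exp(c * t)` — exponential with offset.}
#'   \item{logistic3p}{`f(t) = a / (1 + exp(-b * (t - c)))` — sigmoid rising
#'     to asymptote `a`, inflection at day `c`.}
#'   \item{logistic5p}{`f(t) = d + (a - d) / (1 + exp(-b * (t - c)))^e` —
#'     generalized (Richards-type) logistic with lower asymptote `d` and
#'     asymmetry exponent `e > 0`.}
#'   \item{gompertz3p}{`f(t) = a * exp(-exp(-b * (t - c)))` — asymmetric
#'     sigmoid with `f(c) = a / exp(1)`.}
#'   \item{mech_growth}{`f(t) = a * (1 - b * exp(-c * t))` — mechanistic
#'     (monomolecular) growth saturating at `a`.}
#'   \item{probit4p}{`f(t) = d + (a - d) * pnorm(b * (t - c))`. A linear time
#'     argument is used because day 0 is an observed time point (a log-time
#'     argument is undefined there).}
#' }
#'
#' @format A named list; each element has fields `arity` (parameter count),
#'   `param_names`, `fn(params, t)`, `lower` and `upper` (box bounds used in
#'   fitting), in the canonical model order used for deterministic tie-breaks.
#' @name mortality_models
NULL

MODEL_IDS <- c("exp2p", "exp3p", "logistic3p", "logistic5p",
               "gompertz3p", "mech_growth", "probit4p")

# Deterministic tie-break order for model selection: more constrained
# families precede families that contain them (mech_growth curves are a
# sign-restricted subset of exp3p, so equal-arity ties on saturating data
# resolve to the mechanistic parameterization).
MODEL_TIE_ORDER <- c("exp2p", "logistic3p", "gompertz3p", "mech_growth",
                     "exp3p", "probit4p", "logistic5p")

# Bounds rationale: asymptote/level parameters live on the mortality scale
# [0, 105] (5 points of slack over 100%), rate parameters within [-5, 5] per
# day, inflection times within [-100, 1000] days, offsets within [-105, 105].
.models <- list(
  exp2p = list(
    arity = 2L, param_names = c("a", "b"),
    fn = function(p, t) p[1] * exp(p[2] * t),
    lower = c(1e-6, -5), upper = c(105, 5)
  ),
  exp3p = list(
    arity = 3L, param_names = c("a", "b", "c"),
    fn = function(p, t) p[1] + p[2] * exp(p[3] * t),
    lower = c(-105, -105, -5), upper = c(105, 105, 5)
  ),
  logistic3p = list(
    arity = 3L, param_names = c("a", "b", "c"),
    fn = function(p, t) p[1] / (1 + exp(-p[2] * (t - p[3]))),
    lower = c(1e-6, -5, -100), upper = c(105, 5, 1000)
  ),
  logistic5p = list(
    arity = 5L, param_names = c("a", "b", "c", "d", "e"),
    fn = function(p, t) p[4] + (p[1] - p[4]) / (1 + exp(-p[2] * (t - p[3])))^p[5],
    lower = c(1e-6, -5, -100, 0, 0.05), upper = c(105, 5, 1000, 105, 20)
  ),
  gompertz3p = list(
    arity = 3L, param_names = c("a", "b", "c"),
    fn = function(p, t) p[1] * exp(-exp(-p[2] * (t - p[3]))),
    lower = c(1e-6, -5, -100), upper = c(105, 5, 1000)
  ),
  # b and c restricted to the saturating regime (b in [0, 1] keeps f(0) >= 0,
  # c >= 0 keeps the curve bounded); without the restriction the family is an
  # exact reparameterization of exp3p and the two are indistinguishable
  mech_growth = list(
    arity = 3L, param_names = c("a", "b", "c"),
    fn = function(p, t) p[1] * (1 - p[2] * exp(-p[3] * t)),
    lower = c(1e-6, 0, 0), upper = c(105, 1, 5)
  ),
  probit4p = list(
    arity = 4L, param_names = c("a", "b", "c", "d"),
    fn = function(p, t) p[4] + (p[1] - p[4]) * stats::pnorm(p[2] * (t - p[3])),
    lower = c(1e-6, -5, -100, 0), upper = c(105, 5, 1000, 105)
  )
)

.get_model <- function(model_id) {
  m <- .models[[model_id]]
  if (is.null(m)) {
    stop("unknown model_id '", model_id, "'; must be one of: ",
         paste(MODEL_IDS, collapse = ", "), call. = FALSE)
  }
  m
}

#' Number of parameters of a kinetic model
#'
#' @param model_id One of `"exp2p"`, `"exp3p"`, `"logistic3p"`,
#'   `"logistic5p"`, `"gompertz3p"`, `"mech_growth"`, `"probit4p"`.
#' @return Integer parameter count (2, 3, 3, 5, 3, 3, 4 respectively).
#' @export
model_arity <- function(model_id) .get_model(model_id)$arity

#' Evaluate a kinetic mortality model
#'
#' @inheritParams model_arity
#' @param params Numeric vector of model parameters, in the order documented
#'   in [mortality_models].
#' @param t Days (vector allowed), `t >= 0`.
#' @return Predicted mortality percentage at each `t` (not clamped).
#' @examples
#' evaluate_model("exp2p", c(a = 12.5, b = log(2)), 0:2)  # 12.5 25 50
#' @export
evaluate_model <- function(model_id, params, t) {
  m <- .get_model(model_id)
  if (length(params) != m$arity) {
    stop(model_id, " takes ", m$arity, " parameters, got ", length(params),
         call. = FALSE)
  }
  as.numeric(m$fn(as.numeric(params), t))
}

#' First time a mortality curve reaches a level
#'
#' Finds the smallest `t` in `[0, horizon]` at which the model prediction
#' reaches `level` percent, by coarse bracketing followed by bisection to
#' 1e-6 day. For `exp2p` with `b > 0` the closed form
#' `t = log(level / a) / b` is used directly when it falls inside the horizon.
#'
#' @inheritParams evaluate_model
#' @param level Mortality percentage in (0, 100), e.g. 50 for T1/2.
#' @param horizon Extrapolation horizon in days (default 1000).
#' @return A list with `time` (days; equals `horizon` when censored),
#'   `censored` (logical) and `horizon`.
#' @examples
#' threshold_time("exp2p", c(12.5, log(2)), 50)$time  # 2
#' @export
threshold_time <- function(model_id, params, level, horizon = 1000) {
  stopifnot(level > 0, level < 100, horizon > 0)
  f <- function(t) evaluate_model(model_id, params, t)

  if (model_id == "exp2p" && params[2] > 0 && params[1] > 0) {
    t_cf <- log(level / params[1]) / params[2]
    t_cf <- max(t_cf, 0)
    if (t_cf <= horizon) {
      return(list(time = t_cf, censored = FALSE, horizon = horizon))
    }
    return(list(time = horizon, censored = TRUE, horizon = horizon))
  }

  if (f(0) >= level) return(list(time = 0, censored = FALSE, horizon = horizon))

  # coarse grid to find the first upcrossing (curves need not be monotone)
  grid <- unique(c(seq(0, min(horizon, 100), length.out = 512),
                   seq(min(horizon, 100), horizon, length.out = 512)))
  vals <- f(grid)
  vals[!is.finite(vals)] <- -Inf
  idx <- which(vals >= level)
  if (length(idx) == 0) {
    return(list(time = horizon, censored = TRUE, horizon = horizon))
  }
  hi <- grid[idx[1]]
  lo <- if (idx[1] == 1) 0 else grid[idx[1] - 1]
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) >= level) hi <- mid else lo <- mid
  }
  list(time = hi, censored = FALSE, horizon = horizon)
}
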