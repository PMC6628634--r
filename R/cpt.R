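# The CPT model primitives: value function, probability weighting, gamble
# utility, logistic choice rule, and the expected-value benchmark. All are
# vectorized over their first argument(s).

#' CPT value function
#'
#' Power value function with loss aversion:
#' `v(x) = x^alpha` for gains and `v(x) = -lam * (-x)^alpha` for losses.
#' The same curvature `alpha` applies in both domains.
#'
#' @param x numeric vector of outcomes (points).
#' @param params a [cpt_params()] object (or coercible list).
#' @return Numeric vector of subjective values; `sign(v(x)) == sign(x)` and
#'   `v(0) == 0`.
#' @examples
#' cpt_value(c(-10, 0, 10), cpt_params(alpha = 0.88, lam = 2.25))
#' @export
cpt_value <- function(x, params) {
  params <- as_cpt_params(params)
  if (any(!is.finite(x))) stop("outcomes must be finite", call. = FALSE)
  a <- params[["alpha"]]; l <- params[["lam"]]
  ifelse(x >= 0, x^a, -l * (-x)^a)
}

#' CPT probability weighting function
#'
#' Two-parameter weighting function, linear in log-odds:
#' `w(p) = delta * p^gamma / (delta * p^gamma + (1 - p)^gamma)`.
#' `gamma` controls curvature (inverse-S for `gamma < 1`), `delta` elevation.
#' Evaluated through logs so small `p^gamma` terms do not underflow.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @inheritParams cpt_value
#' @return Decision weights in `[0, 1]`, with `w(0) = 0` and `w(1) = 1`.
#' @examples
#' cpt_weight(c(0.05, 0.5, 0.95), cpt_params(gamma = 0.6, delta = 0.8))
#' @export
cpt_weight <- function(p, params) {
  params <- as_cpt_params(params)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  g <- params[["gamma"]]; d <- params[["delta"]]
  w <- numeric(length(p))
  mid <- p > 0 & p < 1
  if (any(mid)) {
    pm <- p[mid]
    # log-space evaluation of delta * p^g / (delta * p^g + (1-p)^g)
    la <- log(d) + g * log(pm)
    lb <- g * log1p(-pm)
    w[mid] <- 1 / (1 + exp(lb - la))
  }
  w[p == 1] <- 1
  w
}

#' CPT utility of a two-outcome gamble
#'
#' For single-domain gambles (all-gain or all-loss) the utility uses
#' complementary decision weights, `w(p) v(x) + (1 - w(p)) v(y)`; for
#' mixed-outcome gambles the gain and loss are weighted separately,
#' `w(p) v(x) + w(1 - p) v(y)`. By package convention, `x` is the outcome
#' carried with probability `p`: the more extreme outcome in single-domain
#' gambles, the gain in mixed gambles.
#'
#' At identity parameters (`alpha = lam = gamma = delta = 1`) both branches
#' reduce to the gamble's expected value.
#'
#' @param x,y outcome vectors (points); `x` is obtained with probability `p`,
#'   `y` with `1 - p`.
#' @param p probability vector for the `x` outcome.
#' @param trial_type character vector in `c("GAIN_ONLY", "LOSS_ONLY",
#'   "MIXED")`; recycled against the outcomes.
#' @inheritParams cpt_value
#' @return Numeric vector of CPT utilities.
#' @examples
#' cpt_utility(100, 0, 0.5, "GAIN_ONLY", cpt_params())   # = EV = 50
#' cpt_utility(100, -50, 0.5, "MIXED", cpt_params(lam = 2))
#' @export
cpt_utility <- function(x, y, p, trial_type, params) {
  params <- as_cpt_params(params)
  n <- max(length(x), length(y), length(p), length(trial_type))
  x <- rep_len(x, n); y <- rep_len(y, n); p <- rep_len(p, n)
  trial_type <- rep_len(trial_type, n)
  bad <- !trial_type %in% c("GAIN_ONLY", "LOSS_ONLY", "MIXED")
  if (any(bad))
    stop("unknown trial_type: ", paste(unique(trial_type[bad]), collapse = ", "),
         call. = FALSE)
  sign_ok <- ifelse(trial_type == "GAIN_ONLY", x >= 0 & y >= 0,
             ifelse(trial_type == "LOSS_ONLY", x <= 0 & y <= 0,
                    x > 0 & y < 0))
  if (any(!sign_ok))
    stop("gamble outcome signs inconsistent with trial_type", call. = FALSE)
  wp <- cpt_weight(p, params)
  vx <- cpt_value(x, params)
  vy <- cpt_value(y, params)
  mixed <- trial_type == "MIXED"
  u <- wp * vx + (1 - wp) * vy
  if (any(mixed)) {
    wq <- cpt_weight(1 - p[mixed], params)
    u[mixed] <- wp[mixed] * vx[mixed] + wq * vy[mixed]
  }
  u
}

#' Logistic choice probability
#'
#' Probability of choosing gamble A over gamble B given their CPT utilities:
#' `P(A) = 1 / (1 + exp(k * (f_B - f_A)))` with sensitivity `k` (fixed at 1 in
#' the standard model). Probabilities are clipped to
#' `[clip, 1 - clip]` so that log-likelihoods stay finite even when the
#' logistic saturates (with `k = 1` on raw point utilities it routinely does).
#'
#' @param f_a,f_b numeric vectors of utilities for gambles A and B.
#' @param params a [cpt_params()] object; only `k` is used.
#' @param clip clipping bound for numerical safety.
#' @return Probabilities of choosing A, in `(0, 1)`.
#' @examples
#' choice_probability(1, 0, cpt_params())  # 1 / (1 + exp(-1))
#' @export
choice_probability <- function(f_a, f_b, params = cpt_params(), clip = 1e-12) {
  params <- as_cpt_params(params)
  if (any(!is.finite(f_a)) || any(!is.finite(f_b)))
    stop("utilities must be finite", call. = FALSE)
  pr <- stats::plogis(params[["k"]] * (f_a - f_b))
  pmin(pmax(pr, clip), 1 - clip)
}

#' Expected value of a gamble
#'
#' The risk-neutral benchmark `EV = p * x + (1 - p) * y`.
#'
#' @inheritParams cpt_utility
#' @return Numeric vector of expected values (points).
#' @examples
#' gamble_ev(200, 0, 0.95)  # 190
#' @export
gamble_ev <- function(x, y, p) p * x + (1 - p) * y

# Utilities of both gambles on every row of a task table, as a two-column
# matrix (A, B). Internal workhorse for simulation and likelihoods.
task_utilities <- function(task, params) {
  cbind(
    a = cpt_utility(task$ax, task$ay, task$ap, task$trial_type, params),
    b = cpt_utility(task$bx, task$by, task$bp, task$trial_type, params)
  )
}
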