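#' CPT parameter set
#'
#' Container for the four free cumulative prospect theory parameters plus the
#' fixed choice sensitivity. `alpha` is the exponent of the power value
#' function ("value discrimination"), `lam` the loss-aversion coefficient,
#' `gamma` the curvature and `delta` the elevation of the two-parameter
#' probability weighting function. The choice sensitivity `k` is fixed to 1 in
#' the standard configuration so that no parameter outside the theory enters
#' the model; it can be overridden for sensitivity analysis only.
#'
#' @param alpha value-function curvature, > 0.
#' @param lam loss-aversion coefficient, > 0; `lam > 1` means losses loom
#'   larger than equivalent gains.
#' @param gamma weighting-function curvature, > 0; inverse-S when `gamma < 1`.
#' @param delta weighting-function elevation, > 0.
#' @param k logistic choice sensitivity; fixed at 1.
#' @return An object of class `cpt_params`: a named numeric vector with
#'   elements `alpha`, `lam`, `gamma`, `delta`, `k`.
#' @examples
#' cpt_params()                      # identity parameters (risk-neutral EV agent)
#' cpt_params(alpha = 0.88, lam = 2.25, gamma = 0.61, delta = 1)
#' @export
cpt_params <- function(alpha = 1, lam = 1, gamma = 1, delta = 1, k = 1) {
  p <- c(alpha = as.numeric(alpha), lam = as.numeric(lam),
         gamma = as.numeric(gamma), delta = as.numeric(delta),
         k = as.numeric(k))
  if (any(!is.finite(p))) stop("CPT parameters must be finite", call. = FALSE)
  if (any(p[c("alpha", "lam", "gamma", "delta")] <= 0))
    stop("alpha, lam, gamma and delta must be strictly positive", call. = FALSE)
  structure(p, class = "cpt_params")
}

as_cpt_params <- function(x) {
  if (inherits(x, "cpt_params")) return(x)
  x <- unlist(x)
  cpt_params(alpha = x[["alpha"]], lam = x[["lam"]], gamma = x[["gamma"]],
             delta = x[["delta"]],
             k = if ("k" %in% names(x)) x[["k"]] else 1)
}

#' @export
print.cpt_params <- function(x, digits = 4, ...) {
  cat("CPT parameters (k fixed at ", format(x[["k"]]), "):\n", sep = "")
  print(round(unclass(x)[c("alpha", "lam", "gamma", "delta")], digits))
  invisible(x)
}

#' Serialize / deserialize CPT parameters as JSON
#'
#' Parameters travel as a flat JSON object `{"alpha": ..., "lam": ...,
#' "gamma": ..., "delta": ..., "k": ...}`.
#'
#' @param params a [cpt_params()] object.
#' @param path file path; for `read_cpt_params`, a path written by
#'   `write_cpt_params`.
#' @return `write_cpt_params` returns `path` invisibly; `read_cpt_params`
#'   returns a `cpt_params` object.
#' @export
write_cpt_params <- function(params, path) {
  params <- as_cpt_params(params)
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cpt_params
#' @export
read_cpt_params <- function(path) {
  as_cpt_params(jsonlite::read_json(path, simplifyVector = TRUE))
}
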