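#' Fit a logistic cochlear dose-response curve to anchor points
#'
#' Calibrates a logistic curve `risk(d) = plogis(intercept + slope * d)`
#' relating mean cochlear dose (Gy) to the incidence of Grade 3-4 hearing
#' loss, by unweighted least squares on the logit scale.  With exactly two
#' distinct-dose anchors the fit interpolates both exactly.  The curves
#' assume a fixed cisplatin co-exposure context (about 300 mg cumulative);
#' cisplatin dose is not a covariate.
#'
#' @param anchors Two-column matrix or data frame: dose in Gy, incidence
#'   probability in (0, 1).  At least two distinct doses are required;
#'   incidences of exactly 0 or 1 are rejected (infinite logit).
#' @return An object of class `logistic_curve` with fields `intercept`
#'   (logit units) and `slope` (logit units per Gy).
#' @examples
#' crv <- fit_logistic(cbind(c(46.4, 50.0), c(0.3900, 0.4711)))
#' predict_risk(dose_response(list(crv)), 46.4)   # 0.39
#' @export
fit_logistic <- function(anchors) {
  anchors <- as.data.frame(anchors)
  if (ncol(anchors) < 2L) stop("anchors need columns (dose, incidence)")
  d <- anchors[[1]]; p <- anchors[[2]]
  if (length(unique(d)) < 2L) stop("need at least 2 anchors with distinct doses")
  if (any(p <= 0) || any(p >= 1))
    stop("anchor incidences must lie strictly in (0, 1)")
  co <- stats::coef(stats::lm(stats::qlogis(p) ~ d))
  structure(list(intercept = unname(co[1]), slope = unname(co[2])),
            class = "logistic_curve")
}

#' Combine logistic curves into a dose-response model
#'
#' The model's predicted risk is the pointwise average of its member
#' curves, mirroring an evidence synthesis that averages dose-effect
#' relations from two source studies.  Averaging is done on the
#' probability scale by default; averaging the logits first is available
#' as an option since the synthesis rule is ambiguous in narrative
#' descriptions.
#'
#' @param curves List of `logistic_curve` objects (at least one).
#' @param scale `"probability"` (default) or `"logit"`.
#' @return An object of class `dose_response`.
#' @export
dose_response <- function(curves, scale = c("probability", "logit")) {
  scale <- match.arg(scale)
  if (!length(curves)) stop("need at least one curve")
  for (crv in curves)
    if (!inherits(crv, "logistic_curve")) stop("curves must be logistic_curve objects")
  structure(list(curves = curves, scale = scale), class = "dose_response")
}

#' Predict hearing-loss risk at a cochlear dose
#'
#' @param m A `dose_response` model.
#' @param dose Mean cochlear dose in Gy (vectorised, `>= 0`).
#' @return Predicted Grade 3-4 hearing-loss probability in (0, 1).
#' @export
predict_risk <- function(m, dose) {
  if (!inherits(m, "dose_response")) stop("m must be a dose_response model")
  if (any(dose < 0)) stop("dose must be >= 0")
  logits <- vapply(m$curves,
                   function(crv) crv$intercept + crv$slope * dose,
                   numeric(length(dose)))
  logits <- matrix(logits, nrow = length(dose))
  if (m$scale == "probability") {
    rowMeans(stats::plogis(logits))
  } else {
    stats::plogis(rowMeans(logits))
  }
}

#' @export
predict.dose_response <- function(object, dose, ...) predict_risk(object, dose)

#' Dose-response model calibrated to the base-case anchors
#'
#' Builds a two-curve model, one curve through the X-ray anchor points
#' (dose, risk) of the two risk groups and one through the proton anchors.
#' The base-case analysis feeds the anchor risks into the Markov model
#' directly; this calibrated model is a scenario tool for re-running the
#' analysis at alternative cochlear doses (see [risks_at_doses()]).
#'
#' @param params A `cea_params` object supplying the anchors.
#' @param scale Averaging scale passed to [dose_response()].
#' @return A `dose_response` model with two member curves.
#' @export
calibrated_dose_response <- function(params = default_params(),
                                     scale = "probability") {
  xrt <- cbind(c(params$avg_risk$dose_xrt_gy, params$high_risk$dose_xrt_gy),
               c(params$avg_risk$hl_risk_xrt, params$high_risk$hl_risk_xrt))
  pt <- cbind(c(params$avg_risk$dose_pt_gy, params$high_risk$dose_pt_gy),
              c(params$avg_risk$hl_risk_pt, params$high_risk$hl_risk_pt))
  dose_response(list(fit_logistic(xrt), fit_logistic(pt)), scale = scale)
}

#' Replace hearing-loss risks with dose-response predictions
#'
#' Scenario helper: returns a copy of `params` whose four hearing-loss
#' risks are the model's predictions at the stated cochlear doses, so the
#' full cost-effectiveness analysis can be re-run under alternative dose
#' assumptions.
#'
#' @param params A `cea_params` object (doses taken from its
#'   `dose_*_gy` fields unless overridden).
#' @param model A `dose_response` model.
#' @return A modified `cea_params` object (not re-validated against the
#'   shipped triangular ranges, which describe the base-case risks).
#' @export
risks_at_doses <- function(params, model) {
  params$avg_risk$hl_risk_xrt  <- predict_risk(model, params$avg_risk$dose_xrt_gy)
  params$avg_risk$hl_risk_pt   <- predict_risk(model, params$avg_risk$dose_pt_gy)
  params$high_risk$hl_risk_xrt <- predict_risk(model, params$high_risk$dose_xrt_gy)
  params$high_risk$hl_risk_pt  <- predict_risk(model, params$high_risk$dose_pt_gy)
  params$ranges <- params$ranges[!grepl("^hl_risk", names(params$ranges))]
  params
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Cochlear dose-response model (%d logistic curve%s, %s-scale mean)\n",
              length(x$curves), if (length(x$curves) > 1) "s" else "", x$scale))
  for (crv in x$curves)
    cat(sprintf("  logit(risk) = %.4f + %.4f * dose[Gy]\n",
                crv$intercept, crv$slope))
  invisible(x)
}
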