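#' Four-parameter logistic curve
#'
#' `bottom + (top - bottom) / (1 + (ec50 / x)^hill)`: increasing in `x`
#' for `top > bottom` and `hill > 0`, with `y = (top + bottom) / 2` at
#' `x = ec50`.
#'
#' @param x strictly positive dose(s).
#' @param bottom,top asymptotes at dose 0 and infinite dose.
#' @param ec50 curve midpoint.
#' @param hill Hill slope.
#' @return response value(s).
#' @export
four_pl <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit by the Levenberg-Marquardt algorithm
#' ([minpack.lm::nlsLM()]). The model is fitted on the asymptote pair
#' (`A` at dose 0, `B` at infinite dose) so both activation (rising) and
#' growth-inhibition (falling) data use the same parameterisation; the
#' reported `bottom`/`top` are the ordered asymptotes and `direction`
#' records the orientation. Initial values come from the dose-aggregated
#' means (asymptotes from the extreme doses, EC50 by log-linear
#' interpolation of the half-span crossing, Hill slope 1); the EC50 is
#' bounded to `[min(dose)/10, max(dose)*10]` and the Hill slope to
#' `[0.2, 10]`.
#'
#' The fit is censored - never silently numeric - when the response span
#' is less than 20 percent of `control_range`, or when the fitted EC50
#' falls outside the tested dose range (`above_top_dose` /
#' `below_bottom_dose`). Non-convergence is reported via `converged`.
#'
#' @param doses strictly positive concentrations (at least 4 distinct).
#' @param responses numeric responses, same length as `doses`.
#' @param control_range full assay window used for the minimum-span rule;
#'   default 100 for responses on a percent-of-control scale.
#' @return object of class `four_pl_fit`: list with `bottom`, `top`,
#'   `ec50`, `hill`, `direction` (`"increasing"`/`"decreasing"`),
#'   `converged`, `censoring` (`"none"`, `"above_top_dose"`,
#'   `"below_bottom_dose"`, `"low_span"`), `residual_sd`, `n`.
#' @export
fit_4pl <- function(doses, responses, control_range = 100) {
  stopifnot(length(doses) == length(responses))
  if (any(doses <= 0)) stop("doses must be strictly positive")
  ud <- sort(unique(doses))
  if (length(ud) < 4)
    stop("a 4PL fit needs at least 4 distinct doses")

  dmean <- tapply(responses, doses, mean)
  dd <- as.numeric(names(dmean))
  o <- order(dd); dd <- dd[o]; dmean <- as.numeric(dmean)[o]

  A0 <- dmean[1]                 # response toward dose 0
  B0 <- dmean[length(dmean)]     # response toward infinite dose
  span <- abs(B0 - A0)
  base <- list(n = length(doses), direction = if (B0 >= A0) "increasing"
                                              else "decreasing")
  if (span < 0.2 * control_range || span == 0) {
    return(structure(c(list(bottom = min(A0, B0), top = max(A0, B0),
                            ec50 = NA_real_, hill = NA_real_,
                            converged = FALSE, censoring = "low_span",
                            residual_sd = NA_real_), base),
                     class = "four_pl_fit"))
  }

  half <- (A0 + B0) / 2
  ec0 <- exp(mean(log(range(dd))))
  cross <- which(diff(sign(dmean - half)) != 0)
  if (length(cross)) {
    i <- cross[1]
    f <- (half - dmean[i]) / (dmean[i + 1] - dmean[i])
    ec0 <- exp(log(dd[i]) + f * (log(dd[i + 1]) - log(dd[i])))
  }
  lo <- c(A = -Inf, B = -Inf, ec50 = min(dd) / 10, hill = 0.2)
  hi <- c(A = Inf, B = Inf, ec50 = max(dd) * 10, hill = 10)
  dat <- data.frame(x = doses, y = responses)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A + (B - A) / (1 + (ec50 / x)^hill),
                      data = dat,
                      start = list(A = A0, B = B0, ec50 = ec0, hill = 1),
                      lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(c(list(bottom = min(A0, B0), top = max(A0, B0),
                            ec50 = NA_real_, hill = NA_real_,
                            converged = FALSE, censoring = "none",
                            residual_sd = NA_real_), base),
                     class = "four_pl_fit"))
  }
  cf <- coef(fit)
  censoring <- "none"
  if (cf[["ec50"]] > max(dd)) censoring <- "above_top_dose"
  if (cf[["ec50"]] < min(dd)) censoring <- "below_bottom_dose"
  structure(c(list(bottom = min(cf[["A"]], cf[["B"]]),
                   top = max(cf[["A"]], cf[["B"]]),
                   ec50 = unname(cf[["ec50"]]), hill = unname(cf[["hill"]]),
                   converged = fit$convInfo$isConv %||% TRUE,
                   censoring = censoring,
                   residual_sd = sd(resid(fit))),
              base),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit (%s): bottom %.3g, top %.3g, EC50 %.3g, hill %.3g [%s%s]\n",
    x$direction, x$bottom, x$top, x$ec50, x$hill,
    if (x$converged) "converged" else "NOT converged",
    if (x$censoring != "none") paste0(", censored: ", x$censoring) else ""))
  invisible(x)
}

#' Normalise raw translocation values to percent activation
#'
#' Min/max control scaling of raw NUC/CYT values:
#' `100 * (x - mu_min) / (mu_max - mu_min)`, where the control means come
#' from the plate's [control_summary()]. The vehicle-control mean maps to
#' 0 percent and the maximal-activation mean to 100 percent.
#'
#' @param x raw translocation values.
#' @param cs a [control_summary()].
#' @return percent activation values.
#' @export
normalize_activation <- function(x, cs) {
  stopifnot(inherits(cs, "control_summary"))
  if (cs$mu_max == cs$mu_min)
    stop("degenerate controls: mu_max equals mu_min")
  100 * (x - cs$mu_min) / (cs$mu_max - cs$mu_min)
}

#' Percent growth from luminescence counts
#'
#' Normalises per-well luminescence (RLU) of the cytotoxicity assay by the
#' mean of the vehicle-control wells: `100 * rlu / mean(control)`.
#'
#' @param rlu luminescence counts of the treated wells.
#' @param negative_control_rlu luminescence counts of the vehicle controls.
#' @return percent growth values.
#' @export
percent_growth <- function(rlu, negative_control_rlu) {
  if (length(negative_control_rlu) == 0)
    stop("negative control RLU values are required")
  m <- mean(negative_control_rlu)
  if (!is.finite(m) || m <= 0)
    stop("negative-control mean must be positive")
  100 * rlu / m
}

#' Fit a cytotoxicity curve and extract the IC50
#'
#' Fits the percent-growth curve with the same 4PL machinery as the
#' activation assay (the curve falls with dose) and reports the midpoint
#' as the IC50. An IC50 beyond the top tested dose is reported as censored
#' at that dose (a "greater than" bound).
#'
#' @param doses strictly positive concentrations.
#' @param pct_growth percent-growth responses (see [percent_growth()]).
#' @return list of class `cytotox_result`: `ic50`, `censored` (logical),
#'   `limit` (top tested dose), `fit` (the underlying `four_pl_fit`).
#' @export
fit_cytotox <- function(doses, pct_growth) {
  fit <- fit_4pl(doses, pct_growth)
  top_dose <- max(doses)
  censored <- !fit$converged || fit$censoring != "none"
  ic50 <- if (censored) top_dose else fit$ec50
  structure(list(ic50 = ic50, censored = censored, limit = top_dose,
                 fit = fit),
            class = "cytotox_result")
}

#' Classify a selectivity index
#'
#' Three classes: `good` (SI > 5), `some` (2 <= SI <= 5), `none`
#' (SI < 2). For a censored SI the lower bound is classified.
#'
#' @param si numeric selectivity index (or its lower bound).
#' @return character vector of classes.
#' @export
classify_si <- function(si) {
  ifelse(si > 5, "good", ifelse(si >= 2, "some", "none"))
}

#' Selectivity index of a compound
#'
#' `SI = IC50 / EC50`: cytotoxic potency in the counterscreen divided by
#' activating potency in the translocation assay. Reported rounded to two
#' significant figures. A censored IC50 (`> limit`) yields a lower-bound
#' SI flagged `si_censored`; a censored EC50 makes the compound
#' unclassifiable.
#'
#' @param ec50 activation EC50 (numeric), or a `four_pl_fit`.
#' @param ic50 cytotoxicity IC50 (numeric), or a `cytotox_result`.
#' @param ec50_censored,ic50_censored censoring flags used when `ec50` /
#'   `ic50` are plain numbers.
#' @param compound_id optional id carried through.
#' @return one-row data frame with `compound_id`, `ec50`, `ic50`, `si`
#'   (2 significant figures), `si_censored`, `class` (`good`/`some`/
#'   `none`, or NA when unclassifiable).
#' @export
selectivity <- function(ec50, ic50, ec50_censored = FALSE,
                        ic50_censored = FALSE,
                        compound_id = NA_character_) {
  if (inherits(ec50, "four_pl_fit")) {
    ec50_censored <- !ec50$converged || ec50$censoring != "none"
    ec50 <- ec50$ec50
  }
  if (inherits(ic50, "cytotox_result")) {
    ic50_censored <- ic50$censored
    ic50 <- ic50$ic50
  }
  if (isTRUE(ec50_censored) || is.na(ec50)) {
    return(data.frame(compound_id = compound_id, ec50 = NA_real_,
                      ic50 = ic50, si = NA_real_, si_censored = NA,
                      class = NA_character_))
  }
  si <- signif2(ic50 / ec50)
  data.frame(compound_id = compound_id, ec50 = ec50, ic50 = ic50,
             si = si, si_censored = isTRUE(ic50_censored),
             class = classify_si(si))
}
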