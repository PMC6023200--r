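#' Summarise control wells of a plate
#'
#' Mean and sample standard deviation of the translocation values of the
#' maximal-activation (positive, "max") and vehicle (negative, "min")
#' control wells.
#'
#' @param positive,negative numeric vectors of control-well translocation
#'   values; at least two each so the SDs are defined.
#' @return object of class `control_summary` with `mu_max`, `sd_max`,
#'   `n_max`, `mu_min`, `sd_min`, `n_min`.
#' @export
control_summary <- function(positive, negative) {
  if (length(positive) < 2 || length(negative) < 2)
    stop("need at least 2 control wells per side to define SDs")
  structure(list(mu_max = mean(positive), sd_max = sd(positive),
                 n_max = length(positive),
                 mu_min = mean(negative), sd_min = sd(negative),
                 n_min = length(negative)),
            class = "control_summary")
}

#' Z-prime factor
#'
#' The screening-window quality metric
#' `Z' = 1 - 3 * (SDmax + SDmin) / |mu_max - mu_min|`.
#' Values above 0.5 indicate an excellent assay window.
#'
#' @param cs a [control_summary()].
#' @return numeric Z-prime (at most 1).
#' @export
zprime <- function(cs) {
  stopifnot(inherits(cs, "control_summary"))
  if (cs$mu_max == cs$mu_min)
    stop("undefined separation: control means are equal")
  1 - 3 * (cs$sd_max + cs$sd_min) / abs(cs$mu_max - cs$mu_min)
}

#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, length at least 2, nonzero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * sd(values) / m
}

#' Quality-control a plate of well measurements
#'
#' Computes the control summary, Z-prime, and CVs for the positive
#' controls, negative controls and (when present) the compound test wells,
#' then applies the validation gates: every computed CV must be below
#' `cv_limit` (default 20 percent) and Z-prime must exceed `zprime_limit`
#' (default 0.5). Wells flagged invalid (low cell count) are excluded from
#' all statistics and reported.
#'
#' @param wells data frame of well measurements (columns `well`,
#'   `translocation_value`, `valid`), as produced by [aggregate_well()].
#' @param layout plate layout mapping wells to roles.
#' @param cv_limit,zprime_limit the validation gates.
#' @return object of class `plate_qc`: list with `summary`
#'   (a [control_summary()]), `zprime`, `cv_max`, `cv_min`, `cv_test`
#'   (NA when fewer than 2 valid compound wells), `pass`,
#'   `n_invalid_wells`, `invalid_wells`.
#' @export
qc_plate <- function(wells, layout, cv_limit = 20, zprime_limit = 0.5) {
  roles <- layout$role[match(wells$well, layout$well)]
  if (anyNA(roles))
    stop("wells not present in layout: ",
         paste(wells$well[is.na(roles)], collapse = ", "))
  ok <- wells$valid
  pos <- wells$translocation_value[ok & roles == "positive_control"]
  neg <- wells$translocation_value[ok & roles == "negative_control"]
  if (length(pos) < 2)
    stop("no valid positive_control wells (need at least 2)")
  if (length(neg) < 2)
    stop("no valid negative_control wells (need at least 2)")
  cs <- control_summary(pos, neg)
  z <- zprime(cs)
  test <- wells$translocation_value[ok & roles == "compound"]
  cvs <- c(cv_max = cv_percent(pos), cv_min = cv_percent(neg),
           cv_test = if (length(test) >= 2) cv_percent(test) else NA_real_)
  pass <- all(cvs < cv_limit, na.rm = TRUE) && z > zprime_limit
  structure(list(summary = cs, zprime = z,
                 cv_max = unname(cvs["cv_max"]),
                 cv_min = unname(cvs["cv_min"]),
                 cv_test = unname(cvs["cv_test"]),
                 pass = pass,
                 n_invalid_wells = sum(!ok),
                 invalid_wells = wells$well[!ok]),
            class = "plate_qc")
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("Plate QC: Z' = %.3f | CV max/min/test = %s/%s/%s%% | %s\n",
              x$zprime,
              formatC(x$cv_max, digits = 2, format = "f"),
              formatC(x$cv_min, digits = 2, format = "f"),
              if (is.na(x$cv_test)) "NA"
              else formatC(x$cv_test, digits = 2, format = "f"),
              if (x$pass) "PASS" else "FAIL"))
  if (x$n_invalid_wells > 0)
    cat("  invalid wells excluded:", x$n_invalid_wells, "\n")
  invisible(x)
}

#' Kruskal-Wallis comparison of condition groups
#'
#' Rank-based comparison of the medians of two or more groups (e.g.
#' stimulation conditions during assay development), with tie correction
#' and the chi-squared approximation for the p-value.
#'
#' @param groups list of two or more nonempty numeric vectors.
#' @return list with `H` (tie-corrected statistic), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis needs at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("all groups must be nonempty")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop("need a total of at least 3 observations")
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(values)) == 1)  # fully tied: no evidence of any shift
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Optional rank-based follow-up to [kruskal_wallis()]: pairwise z
#' statistics on mean ranks with tie correction, with multiplicity
#' adjustment (Bonferroni by default).
#'
#' @param groups named (or unnamed) list of numeric vectors.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return data frame with `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, p_adjust = "bonferroni") {
  if (!is.list(groups) || length(groups) < 2)
    stop("dunn_posthoc needs at least 2 groups")
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  n <- vapply(groups, length, integer(1))
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, rep(seq_len(k), n), mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[p[1]] + 1 / n[p[2]]))
    (mean_rank[p[1]] - mean_rank[p[2]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
             z = as.numeric(z), p_value = p,
             p_adjusted = stats::p.adjust(p, method = p_adjust))
}
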