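#' Library-level counts from a published translocation screening campaign
#'
#' Per-library compound and hit counts of a published single-point
#' high-content NF-kB translocation screen of three commercial small-
#' molecule libraries (hits called at NUC/CYT >= 1.3). Bundled as example
#' input for [tabulate_hit_rates()].
#'
#' @return data frame with `library`, `n_compounds`, `n_hits`.
#' @export
screen_library_counts <- function() {
  data.frame(
    library = c("MyriaScreen II", "TimTec", "ChemBridge"),
    n_compounds = c(10000L, 800L, 28191L),
    n_hits = c(86L, 4L, 60L))
}

#' Potencies of confirmed hits from a published screening campaign
#'
#' Mean activation EC50 (micromolar, endothelial translocation assay) and
#' cytotoxicity IC50 (micromolar, HepG2 counterscreen) of the confirmed
#' hits of the same published campaign as [screen_library_counts()],
#' together with the selectivity index column as printed. Censored IC50s
#' (reported only as greater than the top tested dose) carry the bound in
#' `ic50` with `ic50_censored = TRUE`; the corresponding printed SI is a
#' lower bound (`si_censored`). Bundled as example input for
#' [selectivity()].
#'
#' @return data frame with `compound_id`, `ec50`, `ic50`, `ic50_censored`,
#'   `si_printed`, `si_censored`.
#' @export
confirmed_hit_potencies <- function() {
  data.frame(
    compound_id = c("IDR-0112566", "IDR-0112703", "IDR-0112706",
                    "IDR-0113345", "IDR-0122120", "IDR-0131600",
                    "IDR-0133275", "IDR-0137368", "IDR-0137875",
                    "IDR-0137892", "IDR-0139144", "IDR-0208481",
                    "IDR-0515158", "IDR-0516961", "IDR-0516964",
                    "IDR-0517069", "IDR-0518296", "IDR-0520796",
                    "IDR-0605183", "IDR-0605186", "IDR-0605187",
                    "IDR-0605188"),
    ec50 = c(3.8, 6.3, 13, 8.6, 6.6, 17, 18, 17, 15, 9.8, 12, 13,
             2.6, 25, 19, 10, 2.4, 5.0, 5.0, 15, 5.9, 4.7),
    ic50 = c(28, 13, 27, 54, 40, 32, 100, 19, 16, 7.3, 18, 41,
             86, 46, 78, 100, 17, 6.6, 31, 50, 51, 17),
    ic50_censored = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                      FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                      FALSE, TRUE, FALSE, FALSE),
    si_printed = c(7.4, 2.1, 2.1, 6.3, 6.1, 1.9, 5.5, 1.1, 1.1,
                   0.7, 1.5, 3.2, 33, 1.8, 4.1, 10, 7.1, 1.3,
                   6.2, 3.3, 8.6, 3.6),
    si_censored = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                    FALSE, TRUE, FALSE, FALSE))
}
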