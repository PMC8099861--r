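#' Fit a qPCR standard curve
#'
#' Ordinary least squares of quantification cycle (Cq) on log10 dilution.
#' Amplification efficiency is `E = 10^(-1/slope)`; a perfectly doubling
#' reaction (E = 2) has slope -1/log10(2) = -3.3219 Cq per tenfold dilution.
#'
#' @param log10_dilution numeric, log10 of the relative template amount.
#' @param cq observed quantification cycles.
#' @return A `standard_curve`: list with `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n`.
#' @export
fit_standard_curve <- function(log10_dilution, cq) {
  stopifnot(length(log10_dilution) == length(cq))
  if (length(cq) < 3L) stop("fit_standard_curve: need >= 3 dilution points")
  fit <- stats::lm(cq ~ log10_dilution)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("fit_standard_curve: slope must be negative ",
         "(Cq decreases with template amount)")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = length(cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: slope %.4f, intercept %.3f, E = %.4f, r2 = %.5f (n = %d)\n",
              x$slope, x$intercept, x$efficiency, x$r_squared, x$n))
  invisible(x)
}

# Relative template amount implied by one Cq under a fitted curve.
curve_concentration <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Efficiency-corrected relative quantification
#'
#' Target expression relative to a housekeeping reference: each Cq is
#' converted to a relative template amount via its gene's own standard
#' curve, and the ratio of the two amounts is returned.
#'
#' @param target_cq,reference_cq observed Cq values (recycled to a common
#'   length).
#' @param target_curve,reference_curve fitted [fit_standard_curve()]
#'   objects for the two genes.
#' @return Numeric ratio(s), target / reference.
#' @export
relative_quantification <- function(target_cq, reference_cq, target_curve,
                                    reference_curve) {
  curve_concentration(target_curve, target_cq) /
    curve_concentration(reference_curve, reference_cq)
}

#' Simulate a qPCR dilution series
#'
#' Generates Cq values from the log-linear standard-curve model
#' `Cq = intercept - log10(dilution) / log10(E)` with additive Gaussian
#' noise; reproducible from `seed`.
#'
#' @param efficiency true amplification efficiency E, in (1, 2.2].
#' @param dilutions relative template amounts (e.g. `10^(0:-4)`).
#' @param noise_sd Cq noise SD (cycles).
#' @param intercept Cq at dilution 1.
#' @param seed integer RNG seed.
#' @return data.frame with `dilution`, `log10_dilution`, `cq`, `true_cq`.
#' @export
simulate_qpcr <- function(efficiency = 2, dilutions = 10^(0:-4),
                          noise_sd = 0, intercept = 15, seed = 1) {
  stopifnot(efficiency > 1, efficiency <= 2.2)
  set.seed(seed)
  ld <- log10(dilutions)
  true_cq <- intercept - ld / log10(efficiency)
  data.frame(dilution = dilutions, log10_dilution = ld,
             cq = true_cq + stats::rnorm(length(ld), 0, noise_sd),
             true_cq = true_cq)
}
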