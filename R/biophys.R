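# Theoretical peptide masses and Boltzmann sigmoidal melting-curve fitting
# for differential scanning fluorimetry (DSF).

#' Theoretical mass of a peptide
#'
#' Sum of residue masses (standard IUPAC table) plus one water, for the free
#' (unmodified, non-cyclic) peptide.
#'
#' @param sequence one-letter sequence (20 standard residues).
#' @param kind `"average"` or `"monoisotopic"`.
#' @return mass in Da.
#' @export
peptide_mass <- function(sequence, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  if (nchar(sequence) < 1) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  tab <- if (kind == "average") AA_MASS_AVG else AA_MASS_MONO
  m <- tab[aa]
  if (anyNA(m))
    stop("non-standard residue letter(s): ",
         paste(unique(aa[is.na(m)]), collapse = ", "))
  water <- if (kind == "average") MASS_WATER_AVG else MASS_WATER_MONO
  sum(m) + water
}

#' Simulate a DSF melt curve from the Boltzmann model
#'
#' F(T) = F_min + (F_max - F_min) / (1 + exp((Tm - T) / k)), sampled on a
#' regular temperature grid with optional Gaussian noise. Reproducible given
#' `seed`.
#'
#' @param f_min,f_max baseline and plateau fluorescence (a.u.).
#' @param tm melting temperature (deg C); must lie inside the scanned range.
#' @param k slope parameter (deg C).
#' @param t_start,t_end,step temperature grid (default 25 to 95 by 0.5).
#' @param noise_sd Gaussian noise standard deviation (a.u., default 0).
#' @param seed integer seed (used when `noise_sd > 0`).
#' @return data.frame with `temperature`, `fluorescence`.
#' @export
simulate_melt_curve <- function(f_min, f_max, tm, k, t_start = 25,
                                t_end = 95, step = 0.5, noise_sd = 0,
                                seed = 1L) {
  if (tm <= t_start || tm >= t_end)
    stop("Tm (", tm, ") outside scanned range [", t_start, ", ", t_end, "]")
  temp <- seq(t_start, t_end, by = step)
  f <- f_min + (f_max - f_min) / (1 + exp((tm - temp) / k))
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    f <- f + stats::rnorm(length(f), sd = noise_sd)
  }
  data.frame(temperature = temp, fluorescence = f)
}

#' Fit a Boltzmann sigmoid to a melt curve
#'
#' Least-squares fit of F(T) = F_min + (F_max - F_min) / (1 + exp((Tm - T)/k))
#' via Levenberg-Marquardt. The automatic initial guess takes F_min/F_max
#' from the curve extremes, Tm at the maximum of the first derivative and
#' k = 2 deg C. Tm is reported from the fitted parameter.
#'
#' @param curve data.frame with `temperature` (strictly increasing) and
#'   `fluorescence`; at least 10 points.
#' @param initial_guess optional named list (`f_min`, `f_max`, `tm`, `k`)
#'   overriding the automatic guess.
#' @return list of class `boltzmann_fit`: `f_min`, `f_max`, `tm`, `k`,
#'   `rss`, `converged`.
#' @export
fit_boltzmann <- function(curve, initial_guess = NULL) {
  stopifnot(all(c("temperature", "fluorescence") %in% names(curve)))
  if (nrow(curve) < 10) stop("need at least 10 points to fit")
  if (any(diff(curve$temperature) <= 0))
    stop("temperatures must be strictly increasing")
  temp <- curve$temperature; f <- curve$fluorescence
  amp <- diff(range(f))
  if (amp < 1e-8) stop("flat curve: no transition to fit")
  if (is.null(initial_guess)) {
    dfdt <- diff(f) / diff(temp)
    initial_guess <- list(f_min = min(f), f_max = max(f),
                          tm = temp[which.max(abs(dfdt))], k = 2)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fluorescence ~ f_min + (f_max - f_min) / (1 + exp((tm - temperature) / k)),
      data = curve,
      start = initial_guess,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("Boltzmann fit did not converge: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  out <- structure(list(f_min = unname(cf["f_min"]),
                        f_max = unname(cf["f_max"]),
                        tm = unname(cf["tm"]), k = unname(cf["k"]),
                        rss = sum(stats::resid(fit)^2), converged = TRUE),
                   class = "boltzmann_fit")
  if (out$f_min >= out$f_max)
    stop("degenerate fit: F_min >= F_max (no unfolding transition)")
  if (out$tm <= min(temp) || out$tm >= max(temp))
    stop("fitted Tm (", round(out$tm, 2), ") outside the scanned range")
  out
}
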