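# Repair-misrepair-fixation (RMF) mapping from DSB yields to
# linear-quadratic survival, plus RBE/OER endpoints.

#' RMF model parameters
#'
#' Parameters of the repair-misrepair-fixation model linking DSB induction to
#' the linear-quadratic survival coefficients: `theta` is the fraction of
#' DSBs undergoing lethal first-order misrepair or fixation, `kappa` the
#' fraction undergoing pairwise interaction, and `j` the least number of
#' lesions per DSB that makes it unrejoinable. Defaults follow the oxygen
#' condition: `theta = 5.79e-3`, `kappa = 5.59e-5`, `j = 13` at 21% and 2%
#' O2; `theta = 4.25e-3`, `kappa = 4.5e-5`, `j = 10` at 0.1% O2.
#'
#' @param o2_percent Oxygen condition (selects the defaults above).
#' @param theta,kappa,j Override the condition defaults.
#' @param diameter_um Cell-nucleus target diameter (8 um, typical V79 cell).
#' @param genome_gbp Genome size in Gbp per cell, converting per-Gbp yields
#'   to per-cell yields. Default [calibrate_genome_size()]: chosen once so
#'   the reference-radiation alpha lands on the measured alpha-LET trend.
#' @param reference_let LET of the reference radiation (Co-60, 0.24 keV/um).
#' @return An object of class `rmf_params`.
#' @export
rmf_params <- function(o2_percent = 21, theta = NULL, kappa = NULL, j = NULL,
                       diameter_um = 8, genome_gbp = NULL,
                       reference_let = 0.24) {
  severe <- o2_percent <= 0.5
  if (is.null(theta)) theta <- if (severe) 4.25e-3 else 5.79e-3
  if (is.null(kappa)) kappa <- if (severe) 4.5e-5 else 5.59e-5
  if (is.null(j)) j <- if (severe) 10L else 13L
  if (theta < 0 || theta > 1 || kappa < 0 || kappa > 1) {
    stop("theta and kappa must lie in [0, 1]")
  }
  if (j < 2) stop("j must be >= 2")
  if (diameter_um <= 0) stop("diameter_um must be > 0")
  if (is.null(genome_gbp)) genome_gbp <- calibrate_genome_size()
  if (genome_gbp <= 0) stop("genome_gbp must be > 0")
  structure(list(theta = theta, kappa = kappa, j = as.integer(j),
                 diameter_um = diameter_um, genome_gbp = genome_gbp,
                 o2_percent = o2_percent, reference_let = reference_let),
            class = "rmf_params")
}

#' Calibrate the genome size from the reference alpha
#'
#' The genome size G (Gbp per cell) is not an observable of the damage
#' tables; it is fixed once so that the RMF alpha computed for the reference
#' radiation (Co-60, DSB yield `sigma_gbp_ref` per Gy per Gbp, LET
#' `let_ref`) equals `alpha_target`, the measured aerobic alpha-LET trend
#' evaluated at the reference LET. Solving the RMF alpha expression for the
#' per-cell DSB yield gives Sigma, and G = Sigma / sigma_gbp_ref. With the
#' defaults G is about 5.4 Gbp, a realistic hamster-cell genome.
#'
#' @param alpha_target Target alpha for the reference radiation (Gy^-1).
#' @param sigma_gbp_ref Reference DSB yield per Gy per Gbp.
#' @param f_r Rejoinable fraction assumed for the reference radiation.
#' @param let_ref Reference LET (keV/um).
#' @param diameter_um Target diameter (um).
#' @param theta,kappa Aerobic RMF fractions.
#' @return Genome size in Gbp per cell.
#' @export
calibrate_genome_size <- function(alpha_target = 0.0466 * 0.24 + 0.2412,
                                  sigma_gbp_ref = 8.1, f_r = 1,
                                  let_ref = 0.24, diameter_um = 8,
                                  theta = 5.79e-3, kappa = 5.59e-5) {
  zf <- frequency_mean_specific_energy(let_ref, diameter_um)
  a <- kappa * zf * f_r
  b <- 1 - f_r * (1 - theta)
  sigma <- if (a > 0) {
    (-b + sqrt(b^2 + 4 * a * alpha_target)) / (2 * a)
  } else {
    alpha_target / b
  }
  sigma / sigma_gbp_ref
}

#' DSBs per cell per Gy
#'
#' Converts a per-Gbp DSB yield to a per-cell yield via the genome size.
#'
#' @param spectrum A `damage_spectrum` (its `total_dsb` is used), or a bare
#'   per-Gbp yield.
#' @param params An [rmf_params()] carrying `genome_gbp`.
#' @return Sigma, DSBs per cell per Gy.
#' @export
dsb_per_cell <- function(spectrum, params) {
  sigma_gbp <- if (inherits(spectrum, "damage_spectrum")) {
    spectrum$total_dsb
  } else {
    as.numeric(spectrum)
  }
  if (sigma_gbp < 0) stop("total_dsb must be >= 0")
  sigma_gbp * params$genome_gbp
}

#' Rejoinable fraction of DSBs
#'
#' Fraction of initial DSBs composed of fewer than `j` lesions: the sum of
#' the multiplicity histogram over i = 2..j-1 divided by its total.
#'
#' @param multiplicity Histogram of DSBs by lesion count: a data frame with
#'   columns `i` (>= 2) and `expected_dsbs`, or a numeric vector named by i.
#' @param j Least lesion count making a DSB unrejoinable (>= 2).
#' @return `f_R` in \[0, 1\] (`j = 2` gives 0: the empty sum).
#' @examples
#' h <- data.frame(i = c(2, 20), expected_dsbs = c(90, 10))
#' rejoinable_fraction(h, j = 13)  # 0.9
#' @export
rejoinable_fraction <- function(multiplicity, j) {
  if (j < 2) stop("j must be >= 2")
  if (is.data.frame(multiplicity)) {
    i <- multiplicity$i
    m <- multiplicity$expected_dsbs
  } else {
    i <- as.numeric(names(multiplicity))
    m <- as.numeric(multiplicity)
  }
  if (any(i < 2)) stop("multiplicity support must start at i = 2")
  if (any(m < 0)) stop("multiplicity masses must be >= 0")
  total <- sum(m)
  if (total <= 0) stop("total DSB mass is zero; f_R is undefined")
  sum(m[i <= j - 1]) / total
}

#' Linear-quadratic parameter container
#'
#' @param alpha Linear coefficient, Gy^-1 (>= 0).
#' @param beta Quadratic coefficient, Gy^-2 (>= 0).
#' @param quality_label,o2_percent Optional provenance labels.
#' @return An object of class `lq_params`.
#' @export
lq_params <- function(alpha, beta, quality_label = NA_character_,
                      o2_percent = NA_real_) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  structure(list(alpha = alpha, beta = beta, quality_label = quality_label,
                 o2_percent = o2_percent),
            class = "lq_params")
}

#' RMF linear coefficient alpha
#'
#' `alpha = [1 - f_R (1 - theta)] Sigma + kappa zF f_R Sigma^2`: unrejoinable
#' and lethally misrepaired DSBs contribute linearly; intra-track pairwise
#' interaction (one energy-deposition event, hence the specific energy per
#' event `z_f`) contributes the quadratic-in-Sigma term. At `f_R = 1` this
#' reduces to `theta Sigma` plus the intra-track term.
#'
#' @param sigma DSBs per cell per Gy.
#' @param f_r Rejoinable fraction in \[0, 1\].
#' @param params An [rmf_params()].
#' @param z_f Frequency-mean specific energy per event, Gy.
#' @return alpha in Gy^-1.
#' @export
lq_alpha <- function(sigma, f_r, params, z_f) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (f_r < 0 || f_r > 1) stop("f_r must lie in [0, 1]")
  (1 - f_r * (1 - params$theta)) * sigma +
    params$kappa * z_f * f_r * sigma^2
}

#' RMF quadratic coefficient beta
#'
#' `beta = (kappa / 2) (f_R Sigma)^2`: inter-track pairwise interaction of
#' rejoinable DSBs.
#'
#' @inheritParams lq_alpha
#' @return beta in Gy^-2.
#' @export
lq_beta <- function(sigma, f_r, params) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (f_r < 0 || f_r > 1) stop("f_r must lie in [0, 1]")
  (params$kappa / 2) * (f_r * sigma)^2
}

#' Linear-quadratic survival fraction
#'
#' `S = exp(-(alpha D + beta D^2))`.
#'
#' @param lq An [lq_params()].
#' @param dose Dose in Gy (>= 0).
#' @return Survival fraction in (0, 1\].
#' @export
survival_fraction <- function(lq, dose) {
  if (any(dose < 0)) stop("dose must be >= 0")
  exp(-(lq$alpha * dose + lq$beta * dose^2))
}

#' Dose achieving a survival level
#'
#' The unique non-negative dose with `alpha D + beta D^2 = -log(S)`,
#' computed via the cancellation-free form `D = 2c / (alpha + sqrt(alpha^2 +
#' 4 beta c))` with `c = -log(S)`; round-trips with [survival_fraction()] to
#' better than 1e-10 relative.
#'
#' @param lq An [lq_params()] with `alpha > 0` or `beta > 0`.
#' @param s Survival level in (0, 1).
#' @return Dose in Gy.
#' @export
dose_for_survival <- function(lq, s) {
  if (any(s <= 0) || any(s >= 1)) stop("s must lie in (0, 1)")
  if (lq$alpha == 0 && lq$beta == 0) {
    stop("alpha = beta = 0: no finite dose reaches S < 1")
  }
  cc <- -log(s)
  2 * cc / (lq$alpha + sqrt(lq$alpha^2 + 4 * lq$beta * cc))
}

#' RBE for DSB induction
#'
#' Ratio of the test to the reference DSB yield (both per Gy per Gbp, or
#' both per cell per Gy); DSB induction is linear in dose, so this equals
#' the equal-effect dose ratio. The conventional reference is Co-60.
#'
#' @param sigma_test,sigma_ref DSB yields for test and reference radiation.
#' @return Dimensionless RBE.
#' @export
rbe_dsb <- function(sigma_test, sigma_ref) {
  if (sigma_ref <= 0) stop("reference DSB yield must be > 0")
  sigma_test / sigma_ref
}

#' RBE for cell survival
#'
#' Equal-effect dose ratio `D_ref / D_test` at survival level `s`, with
#' doses from the LQ quadratic for each radiation quality.
#'
#' @param lq_test,lq_ref [lq_params()] for the test and reference quality.
#' @param s Survival level in (0, 1); 10% is conventional.
#' @return Dimensionless RBE.
#' @export
rbe_survival <- function(lq_test, lq_ref, s = 0.1) {
  dose_for_survival(lq_ref, s) / dose_for_survival(lq_test, s)
}

#' OER for DSB induction
#'
#' Aerobic over hypoxic DSB yield at the same dose (21% over 0.1% O2 in the
#' severe-hypoxia convention).
#'
#' @param sigma_aerobic,sigma_hypoxic DSB yields per Gy per Gbp.
#' @return Dimensionless OER (>= 0).
#' @export
oer_dsb <- function(sigma_aerobic, sigma_hypoxic) {
  if (sigma_hypoxic <= 0) stop("hypoxic DSB yield must be > 0")
  if (sigma_aerobic < 0) stop("aerobic DSB yield must be >= 0")
  sigma_aerobic / sigma_hypoxic
}

#' OER for cell survival
#'
#' Hypoxic over aerobic dose at equal survival: `OER = D_h / D_a` at level
#' `s`. At least 1 whenever the hypoxic alpha and beta do not exceed the
#' aerobic ones.
#'
#' @param lq_aerobic,lq_hypoxic [lq_params()] under 21% and severe hypoxia.
#' @param s Survival level in (0, 1).
#' @return Dimensionless OER.
#' @export
oer_survival <- function(lq_aerobic, lq_hypoxic, s = 0.1) {
  dose_for_survival(lq_hypoxic, s) / dose_for_survival(lq_aerobic, s)
}

#' Fractionation parameters for the alpha-LET closed form
#'
#' Describes a family of radiation qualities whose alpha rises linearly with
#' LET (`alpha = alpha_ref + lambda * LET`) while beta stays at the
#' reference value.
#'
#' @param alpha_ref Reference alpha, Gy^-1 (> 0).
#' @param beta_ref Reference beta, Gy^-2 (>= 0).
#' @param lambda Slope of alpha against LET, Gy^-1 per (keV/um).
#' @return An object of class `fractionation_params`.
#' @export
fractionation_params <- function(alpha_ref = 0.2412, beta_ref = 0.0485,
                                 lambda = 0.0466) {
  if (alpha_ref <= 0) stop("alpha_ref must be > 0")
  if (beta_ref < 0) stop("beta_ref must be >= 0")
  structure(list(alpha_ref = alpha_ref, beta_ref = beta_ref,
                 lambda = lambda),
            class = "fractionation_params")
}

#' RBE at a given fraction dose from the alpha-LET line
#'
#' Closed-form equal-effect RBE for a test quality with
#' `alpha = alpha_ref + lambda * LET` and `beta = beta_ref` against the
#' reference `(alpha_ref, beta_ref)`, evaluated at fraction dose `dose` of
#' the test radiation:
#' `RBE = [sqrt(alpha_ref^2 + 4 beta_ref D (alpha_ref + lambda LET +
#' beta_ref D)) - alpha_ref] / (2 beta_ref D)`.
#' Continuous at D -> 0 with limit `(alpha_ref + lambda LET) / alpha_ref`;
#' strictly decreasing in D for positive LET, so larger fraction doses
#' reduce the RBE.
#'
#' @param fp A [fractionation_params()].
#' @param let LET of the test quality, keV/um.
#' @param dose Fraction dose of the test radiation, Gy.
#' @return Dimensionless RBE.
#' @export
rbe_fraction_dose <- function(fp, let, dose) {
  a <- fp$alpha_ref; b <- fp$beta_ref; at <- a + fp$lambda * let
  limit <- at / a
  out <- numeric(length(dose))
  small <- dose <= 0 | b == 0
  out[small] <- limit
  d <- dose[!small]
  if (length(d)) {
    out[!small] <- (sqrt(a^2 + 4 * b * d * (at + b * d)) - a) / (2 * b * d)
  }
  out
}

#' Ordinary least squares fit of alpha against LET
#'
#' @param let LET values, keV/um (at least two distinct).
#' @param alpha Corresponding LQ alpha values, Gy^-1.
#' @return List with `slope` (lambda), `intercept` (alpha_ref),
#'   `r_squared`, and the underlying `lm` fit.
#' @export
alpha_let_fit <- function(let, alpha) {
  if (length(let) != length(alpha)) stop("let and alpha lengths differ")
  if (length(unique(let)) < 2) {
    stop("need at least two distinct LET values to fit a line")
  }
  fit <- stats::lm(alpha ~ let)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, fit = fit)
}

#' Low-energy bias of the clustered-damage yields
#'
#' Fast clustered-damage simulation overestimates DSB yields for very low
#' electron energies relative to track-structure simulation. The maximum
#' deviation attributable to the low-energy part of the spectrum is
#' `(y_mcds_low - y_ts_low) * low_energy_fraction` (per Gbp per Gy), and the
#' relative overestimate is that deviation divided by the reference yield,
#' in percent.
#'
#' @param y_mcds_low Low-energy DSB yield from the clustered-damage
#'   simulation, per Gbp per Gy.
#' @param y_ts_low Matching track-structure DSB yield.
#' @param low_energy_fraction Fraction of electrons in the low-energy band.
#' @param y_reference DSB yield of the full spectrum (> 0).
#' @return List with `absolute` (per Gbp per Gy) and `relative_percent`.
#' @examples
#' estimate_mcds_bias(24.9, 9.8, 0.09, 10.8)
#' @export
estimate_mcds_bias <- function(y_mcds_low, y_ts_low, low_energy_fraction,
                               y_reference) {
  if (any(c(y_mcds_low, y_ts_low, low_energy_fraction) < 0)) {
    stop("inputs must be >= 0")
  }
  if (y_reference <= 0) stop("reference yield must be > 0")
  absolute <- (y_mcds_low - y_ts_low) * low_energy_fraction
  list(absolute = absolute,
       relative_percent = 100 * absolute / y_reference)
}
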