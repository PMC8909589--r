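# Synthetic-data generators: every input the pipeline needs, with known
# ground truth, so no external transport or damage-simulation output is
# required.

#' Recipe for a synthetic secondary-electron spectrum
#'
#' @param kind `"monoenergetic"`, `"exponential_tail"` (energies sampled
#'   from an exponential with the given mean, emulating the soft secondary
#'   spectrum of titanium K-shell irradiation, mean 2.8 keV) or
#'   `"bremsstrahlung_like"` (Kramers-form tube spectrum
#'   `Phi(E) ~ (E_max - E)/E`, truncated below 0.5 keV).
#' @param peak_or_mean_energy Line energy / sample mean / tube cutoff, keV.
#' @param n_points Number of spectrum points (samples or grid nodes).
#' @param seed RNG seed for the sampled kinds.
#' @return An object of class `spectrum_recipe`.
#' @export
spectrum_recipe <- function(kind = c("monoenergetic", "exponential_tail",
                                     "bremsstrahlung_like"),
                            peak_or_mean_energy = 2.8, n_points = 200,
                            seed = 1L) {
  kind <- match.arg(kind)
  if (peak_or_mean_energy <= 0) stop("energy must be positive")
  if (n_points < 1) stop("n_points must be >= 1")
  structure(list(kind = kind, peak_or_mean_energy = peak_or_mean_energy,
                 n_points = as.integer(n_points), seed = as.integer(seed)),
            class = "spectrum_recipe")
}

#' Generate a synthetic fluence spectrum
#'
#' Deterministic given the recipe seed. LET values come from the synthetic
#' stopping-power curve [electron_let()]. The monoenergetic kind yields a
#' single point; the bremsstrahlung-like kind has zero fluence at (and no
#' support above) the tube cutoff energy.
#'
#' @param recipe A [spectrum_recipe()].
#' @return A [fluence_spectrum()] with the recipe attached as attribute
#'   `"recipe"`.
#' @export
make_fluence_spectrum <- function(recipe) {
  stopifnot(inherits(recipe, "spectrum_recipe"))
  e0 <- recipe$peak_or_mean_energy
  sp <- switch(recipe$kind,
    monoenergetic = fluence_spectrum(e0, 1, electron_let(e0)),
    exponential_tail = {
      set.seed(recipe$seed)
      e <- sort(unique(stats::rexp(recipe$n_points, rate = 1 / e0)))
      fluence_spectrum(e, rep(1, length(e)), electron_let(e))
    },
    bremsstrahlung_like = {
      if (e0 <= 0.5) stop("tube cutoff must exceed the 0.5 keV truncation")
      e <- seq(0.5, e0, length.out = max(recipe$n_points, 2L))
      phi <- (e0 - e) / e
      fluence_spectrum(e, phi, electron_let(e))
    })
  attr(sp, "recipe") <- recipe
  sp
}

#' Recipe for a DSB lesion-multiplicity histogram
#'
#' Histogram over the number of lesions per DSB: a point mass at i = 2
#' (simple DSBs) plus a geometric tail over i = 3..`max_i` controlling the
#' share of complex, potentially unrejoinable DSBs.
#'
#' @param base_mass_at_2 Fraction of DSBs with exactly two lesions.
#' @param tail_decay Geometric ratio of the tail (larger = heavier tail).
#' @param max_i Largest multiplicity carried (>= 2).
#' @param total_sigma Total DSBs per cell per Gy the histogram sums to.
#' @return An object of class `multiplicity_recipe`.
#' @export
multiplicity_recipe <- function(base_mass_at_2 = 0.6, tail_decay = 0.3,
                                max_i = 30, total_sigma = 1) {
  if (base_mass_at_2 < 0 || base_mass_at_2 > 1) {
    stop("base_mass_at_2 must lie in [0, 1]")
  }
  if (tail_decay < 0 || tail_decay >= 1) stop("tail_decay must lie in [0, 1)")
  if (max_i < 2) stop("max_i must be >= 2")
  if (total_sigma <= 0) stop("total_sigma must be > 0")
  structure(list(base_mass_at_2 = base_mass_at_2, tail_decay = tail_decay,
                 max_i = as.integer(max_i), total_sigma = total_sigma),
            class = "multiplicity_recipe")
}

#' Generate a DSB multiplicity histogram
#'
#' @param recipe A [multiplicity_recipe()].
#' @return A data frame `(i, expected_dsbs)` with support \[2, max_i\]
#'   summing to `total_sigma`, recipe attached as attribute `"recipe"`.
#'   With `base_mass_at_2 = 1` all mass sits at i = 2 and the rejoinable
#'   fraction is 1 for any j >= 3. The closed form of the rejoinable
#'   fraction for j >= 3 is
#'   `p2 + (1 - p2) (1 - q^(j-3)) / (1 - q^(max_i - 2))`.
#' @export
make_multiplicity_histogram <- function(recipe) {
  stopifnot(inherits(recipe, "multiplicity_recipe"))
  p2 <- recipe$base_mass_at_2
  q <- recipe$tail_decay
  mi <- recipe$max_i
  i <- 2:mi
  mass <- numeric(length(i))
  mass[1] <- p2
  if (mi > 2 && p2 < 1) {
    tail <- q^(seq_len(mi - 2) - 1)          # i = 3..max_i
    mass[-1] <- (1 - p2) * tail / sum(tail)
  } else if (mi > 2) {
    mass[-1] <- 0
  }
  out <- data.frame(i = i, expected_dsbs = mass * recipe$total_sigma)
  out <- out[out$expected_dsbs > 0 | out$i == 2, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "recipe") <- recipe
  out
}

#' Generate a noisy linear-quadratic survival dataset
#'
#' Observed survival is the LQ curve times multiplicative lognormal noise
#' (survival is positive with roughly proportional errors).
#'
#' @param lq An [lq_params()] giving the ground truth.
#' @param doses Dose points in Gy (>= 0).
#' @param noise_sd Standard deviation of `log(S_obs / S_true)`; 0 gives the
#'   exact curve.
#' @param seed RNG seed.
#' @param replicates Independent observations per dose point.
#' @return A data frame `(dose, s_observed)` with the generating parameters
#'   attached as attribute `"truth"`.
#' @export
make_survival_dataset <- function(lq, doses, noise_sd = 0.05, seed = 1L,
                                  replicates = 1L) {
  if (any(doses < 0)) stop("doses must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  d <- rep(doses, each = replicates)
  s_true <- survival_fraction(lq, d)
  s_obs <- s_true * exp(stats::rnorm(length(d), 0, noise_sd))
  out <- data.frame(dose = d, s_observed = s_obs)
  attr(out, "truth") <- list(alpha = lq$alpha, beta = lq$beta,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Fit linear-quadratic parameters to survival data
#'
#' Ordinary least squares on `-log(S) = alpha D + beta D^2` (no intercept).
#' Dose-zero points contribute nothing to the fit beyond their noise and are
#' retained.
#'
#' @param dose Doses in Gy.
#' @param s_observed Observed survival fractions (> 0).
#' @return An [lq_params()] with the fit attached as attribute `"fit"`;
#'   negative estimates are truncated at zero.
#' @export
fit_lq <- function(dose, s_observed) {
  if (any(s_observed <= 0)) stop("survival fractions must be > 0")
  y <- -log(s_observed)
  fit <- stats::lm(y ~ 0 + dose + I(dose^2))
  a <- max(0, unname(coef(fit)[1]))
  b <- max(0, unname(coef(fit)[2]))
  out <- lq_params(a, b)
  attr(out, "fit") <- fit
  out
}
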