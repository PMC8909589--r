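# Packaged reference yield tables: hand-entered fixture CSVs under
# inst/extdata, cells kept as printed ("value ± sem") and parsed on read.

.grenz_env <- new.env(parent = emptyenv())

ext_path <- function(file) {
  system.file("extdata", file, package = "grenzrmf", mustWork = TRUE)
}

#' Parse "value ± sem" cells
#'
#' @param x Character vector of cells such as `"168.6 ± 0.1"` or `"123.5"`.
#' @return A data frame with numeric `value` and `sem` (NA when no
#'   uncertainty is printed).
#' @export
parse_pm <- function(x) {
  parts <- strsplit(trimws(as.character(x)), " ", fixed = TRUE)
  value <- vapply(parts, function(p) {
    if (length(p) == 0L || !nzchar(p[1])) NA_real_ else as.numeric(p[1])
  }, numeric(1))
  sem <- vapply(parts, function(p) {
    if (length(p) >= 3L) as.numeric(p[3]) else NA_real_
  }, numeric(1))
  data.frame(value = value, sem = sem)
}

read_yield_csv <- function(file) {
  raw <- utils::read.csv(ext_path(file), stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = TRUE)
  for (col in c("total_ssb", "total_dsb")) {
    pm <- parse_pm(raw[[col]])
    raw[[col]] <- pm$value
    raw[[paste0(col, "_sem")]] <- pm$sem
  }
  raw
}

#' Packaged photon-quality damage yields
#'
#' Per-quality damage spectra (class percentages plus total SSB/DSB yields in
#' per Gy per Gbp) for the Grenz-ray qualities and the Co-60 reference at
#' 21%, 2% and 0.1% O2, exactly as packaged.
#'
#' @return A data frame with one row per (quality, O2, source).
#' @export
photon_yield_table <- function() {
  if (is.null(.grenz_env$photon)) {
    .grenz_env$photon <- read_yield_csv("photon_yields.csv")
  }
  .grenz_env$photon
}

#' Packaged monoenergetic-electron damage yields
#'
#' Damage spectra for 100 eV to 4.5 keV electrons from the clustered-damage
#' simulation (`source = "mcds"`) and from published track-structure
#' simulations (`source = "track_structure"`), with the LET of each energy.
#'
#' @return A data frame with one row per (energy, source).
#' @export
electron_yield_table <- function() {
  if (is.null(.grenz_env$electron)) {
    .grenz_env$electron <- read_yield_csv("electron_yields.csv")
  }
  .grenz_env$electron
}

#' Radiation-quality metadata
#'
#' Quality names, mean photon energies (kV), LET values (keV/um), measured
#' DSB yields/RBE where available and the packaged simulated DSB yields with
#' their one-decimal RBE relative to Co-60.
#'
#' @return A data frame with one row per radiation quality.
#' @export
grenz_qualities <- function() {
  if (is.null(.grenz_env$qualities)) {
    raw <- utils::read.csv(ext_path("qualities.csv"), stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
    for (col in c("mcds_dsb", "rbe_dsb")) {
      pm <- parse_pm(raw[[col]])
      raw[[col]] <- pm$value
      raw[[paste0(col, "_sem")]] <- pm$sem
    }
    .grenz_env$qualities <- raw
  }
  .grenz_env$qualities
}

pct_columns <- c(BD = "bd_pct", SSB = "ssb_pct", `SSB+` = "ssb_plus_pct",
                 `2SSB` = "two_ssb_pct", DSB = "dsb_pct",
                 `DSB+` = "dsb_plus_pct", `DSB++` = "dsb_pp_pct")

row_to_spectrum <- function(row, n_samples = 10000) {
  pct <- setNames(as.numeric(row[1, pct_columns]), DAMAGE_CLASSES)
  ssb_share <- sum(pct[SSB_CLASSES]) / 100
  dsb_share <- sum(pct[DSB_CLASSES]) / 100
  if (is.na(row$total_ssb) || ssb_share <= 0 || dsb_share <= 0) {
    stop("row has no absolute yields; only percentages are printed")
  }
  # The printed totals are authoritative. Some photon rows print DSB
  # percentages that are not consistent with the printed DSB totals, so
  # each class family is scaled to its own printed total: SSB classes (and
  # BD, which scales with the simple-damage family) against total_ssb, DSB
  # classes against total_dsb.
  yields <- pct
  yields[c("BD", SSB_CLASSES)] <-
    pct[c("BD", SSB_CLASSES)] / (100 * ssb_share) * row$total_ssb
  yields[DSB_CLASSES] <-
    pct[DSB_CLASSES] / (100 * dsb_share) * row$total_dsb
  sem <- setNames(rep(NA_real_, 7L), DAMAGE_CLASSES)
  sp <- new_damage_spectrum(yields, sem, NULL, n_samples,
                            total_ssb_sem = row$total_ssb_sem,
                            total_dsb_sem = row$total_dsb_sem,
                            source = "packaged table")
  sp$percentages <- pct
  sp
}

#' Damage spectrum for a packaged radiation quality
#'
#' @param quality Quality name: one of `"15 kV"`, `"10 kV"`, `"10 kVp"`,
#'   `"4.55 kV"`, `"Co-60"`.
#' @param o2_percent Oxygen condition: 21, 2 or 0.1.
#' @return A `damage_spectrum` built from the packaged row (printed totals
#'   kept exactly; class yields reconstructed from the printed percentages).
#' @examples
#' get_spectrum("Co-60", 21)$total_dsb   # 8.1
#' @export
get_spectrum <- function(quality, o2_percent = 21) {
  tab <- photon_yield_table()
  tab <- tab[tab$source == "mcds", ]
  hit <- tab$quality == quality & tab$o2_percent == o2_percent
  if (!any(hit)) {
    keys <- unique(paste0(tab$quality, " @ ", tab$o2_percent, "% O2"))
    stop(sprintf("no packaged spectrum for '%s' at %s%% O2; available: %s",
                 quality, format(o2_percent), paste(keys, collapse = "; ")))
  }
  row_to_spectrum(tab[hit, , drop = FALSE])
}

#' Damage spectrum for a packaged electron energy
#'
#' @param energy_ev Electron energy in eV: 100, 300, 500, 1000, 1500 or 4500.
#' @param source `"mcds"` (clustered-damage simulation) or
#'   `"track_structure"` (published track-structure results).
#' @return A `damage_spectrum` for that energy.
#' @examples
#' get_electron_yields(1000, "mcds")$total_ssb   # 168.6
#' @export
get_electron_yields <- function(energy_ev, source = c("mcds",
                                                      "track_structure")) {
  source <- match.arg(source)
  tab <- electron_yield_table()
  hit <- tab$energy_ev == energy_ev & tab$source == source
  if (!any(hit)) {
    stop(sprintf("no packaged yields for %s eV (%s); available energies: %s",
                 format(energy_ev), source,
                 paste(unique(tab$energy_ev), collapse = ", ")))
  }
  row_to_spectrum(tab[hit, , drop = FALSE])
}

#' Synthetic electron stopping power
#'
#' Unrestricted LET of electrons in water as a function of energy,
#' log-log-interpolated through the packaged electron-energy LET points
#' (0.1-4.5 keV) and power-law extended beyond them. A documented synthetic
#' stand-in for tabulated stopping powers, sufficient for weighting fluence
#' spectra.
#'
#' @param energy_kev Electron energies in keV (> 0).
#' @return LET values in keV/um.
#' @export
electron_let <- function(energy_kev) {
  if (any(energy_kev <= 0)) stop("energy must be positive")
  tab <- electron_yield_table()
  pts <- unique(tab[, c("energy_ev", "let_kev_um")])
  e <- sort(unique(pts$energy_ev)) / 1000
  l <- pts$let_kev_um[match(e * 1000, pts$energy_ev)]
  lx <- log(e); ly <- log(l)
  n <- length(lx)
  x <- log(energy_kev)
  y <- stats::approx(lx, ly, xout = pmin(pmax(x, lx[1]), lx[n]), rule = 2)$y
  # power-law tails from the terminal slopes
  lo <- x < lx[1]
  hi <- x > lx[n]
  if (any(lo)) {
    s <- (ly[2] - ly[1]) / (lx[2] - lx[1])
    y[lo] <- ly[1] + s * (x[lo] - lx[1])
  }
  if (any(hi)) {
    s <- (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1])
    y[hi] <- ly[n] + s * (x[hi] - lx[n])
  }
  exp(y)
}
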