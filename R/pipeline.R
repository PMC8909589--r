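# End-to-end orchestration: packaged yield tables -> RMF -> LQ parameters ->
# RBE / OER endpoints, plus file-writing front ends with run manifests.

default_multiplicity <- function(o2_percent) {
  # Thin geometric tail matching the multiplicity histograms the simulator
  # produces at table-calibrated damage densities (nearly all DSBs carry
  # fewer than 10 lesions); hypoxic damage is simpler still, so the same
  # recipe is conservative there.
  make_multiplicity_histogram(multiplicity_recipe(
    base_mass_at_2 = 0.6, tail_decay = 0.3, max_i = 30, total_sigma = 1))
}

#' Full RBE/OER table for the packaged radiation qualities
#'
#' For every packaged quality and oxygen condition, converts the tabulated
#' DSB yield to a per-cell yield, derives the rejoinable fraction from a
#' multiplicity histogram with the condition's `j`, maps through the RMF
#' expressions to LQ alpha/beta, and reports equal-effect doses, RBE for
#' DSB induction and for survival (against the reference quality at the
#' same oxygen condition) and OER for DSB induction and survival (against
#' the same quality at 21% O2).
#'
#' @param o2_levels Oxygen conditions to include (subset of 21, 2, 0.1).
#' @param reference Reference quality name (default Co-60).
#' @param survival_level Survival level for equal-effect doses.
#' @param genome_gbp Genome size; default [calibrate_genome_size()].
#' @param multiplicity Optional function `(o2_percent) -> histogram` to
#'   supply DSB multiplicity histograms (e.g. from
#'   [simulate_damage_spectrum()]); default thin-tailed synthetic
#'   histograms.
#' @return A data frame with one row per (quality, O2): LET, per-Gbp and
#'   per-cell DSB yields, `f_r`, `alpha`, `beta`, `dose_at_s`, `rbe_dsb`,
#'   `rbe_survival`, `oer_dsb`, `oer_survival`, plus one-decimal rounded
#'   ratio columns for table comparison.
#' @export
rbe_oer_table <- function(o2_levels = c(21, 2, 0.1), reference = "Co-60",
                          survival_level = 0.1, genome_gbp = NULL,
                          multiplicity = default_multiplicity) {
  quals <- grenz_qualities()
  if (!reference %in% quals$quality) {
    stop(sprintf("unknown reference '%s'; available: %s", reference,
                 paste(quals$quality, collapse = ", ")))
  }
  if (is.null(genome_gbp)) genome_gbp <- calibrate_genome_size()
  rows <- list()
  for (o2 in o2_levels) {
    params <- rmf_params(o2_percent = o2, genome_gbp = genome_gbp)
    hist_o2 <- multiplicity(o2)
    f_r <- rejoinable_fraction(hist_o2, params$j)
    for (q in quals$quality) {
      sp <- get_spectrum(q, o2)
      let <- quals$let_kev_um[quals$quality == q]
      zf <- frequency_mean_specific_energy(let, params$diameter_um)
      sigma <- dsb_per_cell(sp, params)
      alpha <- lq_alpha(sigma, f_r, params, zf)
      beta <- lq_beta(sigma, f_r, params)
      rows[[length(rows) + 1L]] <- data.frame(
        quality = q, o2_percent = o2, let_kev_um = let,
        sigma_gbp = sp$total_dsb, sigma_cell = sigma, f_r = f_r,
        alpha = alpha, beta = beta,
        dose_at_s = dose_for_survival(lq_params(alpha, beta), survival_level))
    }
  }
  out <- do.call(rbind, rows)

  ref_rows <- out[out$quality == reference, ]
  aer_rows <- out[out$o2_percent == 21, ]
  ref_sigma <- setNames(ref_rows$sigma_gbp, ref_rows$o2_percent)
  ref_dose <- setNames(ref_rows$dose_at_s, ref_rows$o2_percent)
  aer_sigma <- setNames(aer_rows$sigma_gbp, aer_rows$quality)
  aer_dose <- setNames(aer_rows$dose_at_s, aer_rows$quality)

  o2key <- as.character(out$o2_percent)
  out$rbe_dsb <- out$sigma_gbp / ref_sigma[o2key]
  out$rbe_survival <- ref_dose[o2key] / out$dose_at_s
  out$oer_dsb <- aer_sigma[out$quality] / out$sigma_gbp
  out$oer_survival <- out$dose_at_s / aer_dose[out$quality]
  for (col in c("rbe_dsb", "rbe_survival", "oer_dsb", "oer_survival")) {
    out[[paste0(col, "_rounded")]] <- round(out[[col]], 1)
  }
  attr(out, "settings") <- list(reference = reference,
                                survival_level = survival_level,
                                genome_gbp = genome_gbp)
  rownames(out) <- NULL
  out
}

#' Equal-effect RBE sweep over fraction dose
#'
#' Evaluates the closed-form fraction-dose RBE over a dose grid for one or
#' more LET values.
#'
#' @param fp A [fractionation_params()].
#' @param let LET values, keV/um.
#' @param doses Fraction doses, Gy.
#' @return Data frame `(let_kev_um, dose_gy, rbe)`.
#' @export
rbe_fraction_sweep <- function(fp = fractionation_params(), let = 6.6,
                               doses = seq(0.5, 7, by = 0.5)) {
  grid <- expand.grid(let_kev_um = let, dose_gy = doses)
  grid$rbe <- mapply(function(l, d) rbe_fraction_dose(fp, l, d),
                     grid$let_kev_um, grid$dose_gy)
  grid
}

write_run_manifest <- function(out_dir, command, files, seed = NA,
                               config = NULL) {
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    seed = seed,
    outputs = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  path
}

#' Write a damage spectrum to CSV and JSON
#'
#' Emits `<prefix>_spectrum.csv` (class, yield, sem, percent),
#' `<prefix>_multiplicity.csv` (i, expected_dsbs) and `<prefix>.json`
#' mirroring both plus the generating configuration and seed.
#'
#' @param spectrum A `damage_spectrum`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the files written.
#' @export
write_damage_spectrum <- function(spectrum, out_dir, prefix = "damage") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec_csv <- file.path(out_dir, paste0(prefix, "_spectrum.csv"))
  mult_csv <- file.path(out_dir, paste0(prefix, "_multiplicity.csv"))
  json_path <- file.path(out_dir, paste0(prefix, ".json"))
  df <- data.frame(class = names(spectrum$yields),
                   yield_per_gy_per_gbp = unname(spectrum$yields),
                   sem = unname(spectrum$sem),
                   percent = unname(spectrum$percentages))
  utils::write.csv(df, spec_csv, row.names = FALSE)
  mult <- spectrum$dsb_multiplicity
  if (is.null(mult)) mult <- data.frame(i = integer(),
                                        expected_dsbs = numeric())
  utils::write.csv(mult, mult_csv, row.names = FALSE)
  cfg <- spectrum$config
  if (!is.null(cfg)) cfg <- unclass(cfg)
  if (!is.null(cfg$oxygen)) cfg$oxygen <- unclass(cfg$oxygen)
  jsonlite::write_json(list(spectrum = df, multiplicity = mult,
                            total_ssb = spectrum$total_ssb,
                            total_dsb = spectrum$total_dsb,
                            n_samples = spectrum$n_samples,
                            all_zero = spectrum$all_zero,
                            config = cfg),
                       json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  c(spec_csv, mult_csv, json_path)
}

#' Reproduce the RBE/OER result tables on disk
#'
#' Runs [rbe_oer_table()] and writes `rbe_oer.csv` (full precision plus
#' one-decimal rounded columns) and a run manifest with file checksums.
#'
#' @param out_dir Output directory.
#' @param ... Passed to [rbe_oer_table()].
#' @return Invisibly, the result data frame (attribute `"files"` lists the
#'   written paths).
#' @export
run_tables <- function(out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- rbe_oer_table(...)
  csv <- file.path(out_dir, "rbe_oer.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  manifest <- write_run_manifest(out_dir, "tables", csv)
  attr(tab, "files") <- c(csv, manifest)
  invisible(tab)
}

#' Simulate a damage spectrum and write it to disk
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the simulated `damage_spectrum` (attribute `"files"`).
#' @export
run_simulate <- function(config, out_dir, prefix = "damage") {
  sp <- simulate_damage_spectrum(config)
  files <- write_damage_spectrum(sp, out_dir, prefix)
  manifest <- write_run_manifest(out_dir, "simulate", files,
                                 seed = config$seed,
                                 config = unclass(config))
  attr(sp, "files") <- c(files, manifest)
  invisible(sp)
}

#' Survival-endpoint report
#'
#' Writes the per-quality LQ/RBE/OER survival table (`survival.csv`) and a
#' fraction-dose RBE sweep (`fraction_sweep.csv`) with a manifest.
#'
#' @param out_dir Output directory.
#' @param fp [fractionation_params()] for the sweep.
#' @param sweep_let LET values for the sweep.
#' @param doses Fraction-dose grid for the sweep.
#' @param ... Passed to [rbe_oer_table()].
#' @return Invisibly, a list with `table` and `sweep` data frames
#'   (attribute `"files"`).
#' @export
run_survival <- function(out_dir, fp = fractionation_params(),
                         sweep_let = c(1, 6.6),
                         doses = seq(0.5, 7, by = 0.5), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- rbe_oer_table(...)
  sweep <- rbe_fraction_sweep(fp, sweep_let, doses)
  surv_csv <- file.path(out_dir, "survival.csv")
  sweep_csv <- file.path(out_dir, "fraction_sweep.csv")
  utils::write.csv(tab, surv_csv, row.names = FALSE)
  utils::write.csv(sweep, sweep_csv, row.names = FALSE)
  manifest <- write_run_manifest(out_dir, "survival",
                                 c(surv_csv, sweep_csv))
  out <- list(table = tab, sweep = sweep)
  attr(out, "files") <- c(surv_csv, sweep_csv, manifest)
  invisible(out)
}
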