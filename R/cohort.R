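# Cohort-level convenience layer: generate a study-sized set of phantom
# specimens, run the full pipeline (correspondence -> measurements ->
# pairing) on each, and pool for the agreement analysis.

#' Generate one complete phantom specimen
#'
#' Runs [generate_specimen()] and [apply_histology_transform()] and
#' gathers volume, slide stack, analytic ground truth and US mucosal-edge
#' landmarks in one object.
#'
#' @param config a [phantom_config()].
#' @return list of class `phantom_specimen` with `config`, `geometry`,
#'   `volume`, `stack`, `truth`, `landmarks`.
#' @export
phantom_specimen <- function(config) {
  gen <- generate_specimen(config)
  ht <- apply_histology_transform(gen$geometry)
  structure(list(config = config, geometry = gen$geometry,
                 volume = gen$volume, stack = ht$stack, truth = ht$truth,
                 landmarks = us_landmarks(gen$geometry)),
            class = "phantom_specimen")
}

# deterministic sub-seed per specimen, kept below 2^31
cohort_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)

#' Generate a phantom cohort
#'
#' Draws `n` specimens with seeded between-specimen variability in size
#' and tumor geometry, emulating the study's 10-patient cohort. Tumor
#' half-axes are shrunk (deterministically) if a draw would violate the
#' strict-containment invariant.
#'
#' @param n number of specimens.
#' @param seed master seed; each specimen uses a derived sub-seed.
#' @param shrinkage linear shrinkage fraction applied to every specimen.
#' @param stretch_factors per-specimen stretch factor (length 1 or n);
#'   set one entry to 1.3 to emulate the stretched-and-pinned outlier.
#' @param deformation_amp smooth-warp amplitude mm.
#' @param n_fiducials fiducial count per specimen.
#' @return list of [phantom_specimen()] objects named `P1`..`Pn`.
#' @export
generate_cohort <- function(n = 10, seed = 1, shrinkage = 0.2,
                            stretch_factors = 1, deformation_amp = 0,
                            n_fiducials = 3) {
  stretch_factors <- rep_len(stretch_factors, n)
  lapply(seq_len(n), function(k) {
    sk <- cohort_seed(seed, k)
    pars <- with_seed(sk, {
      list(half = c(stats::runif(1, 9.5, 12.5), stats::runif(1, 8, 11),
                    stats::runif(1, 15, 22)),
           taxes = c(stats::runif(1, 4.5, 6.5), stats::runif(1, 3.5, 5.5),
                     stats::runif(1, 7, 11)),
           tcen = c(stats::runif(1, -1.5, 1.5), stats::runif(1, 1, 3),
                    stats::runif(1, -3, 3)))
    })
    cfg <- NULL
    taxes <- pars$taxes
    for (try in 1:30) {
      cfg <- tryCatch(
        phantom_config(seed = sk, half_axes = pars$half,
                       tumor_center = pars$tcen, tumor_axes = taxes,
                       shrinkage = shrinkage,
                       stretch_factor = stretch_factors[k],
                       deformation_amp = deformation_amp,
                       n_fiducials = n_fiducials,
                       specimen = sprintf("P%d", k)),
        error = function(e) NULL)
      if (!is.null(cfg)) break
      taxes <- taxes * 0.93
    }
    if (is.null(cfg)) stopf("specimen %d: could not fit tumor inside specimen", k)
    phantom_specimen(cfg)
  })
}

#' Run the full pipeline on one phantom specimen
#'
#' Slice correspondence, blinded measurements in both modalities, and
#' pairing.
#'
#' @param ph a [phantom_specimen()].
#' @param window correspondence search half-window, mm.
#' @param modality US modality label.
#' @return list with `correspondence`, `us`, `histo` (records), `pairs`.
#' @export
analyze_specimen <- function(ph, window = 4, modality = "US-manual") {
  corr <- match_slides(ph$volume, ph$stack, window = window)
  meas <- measure_specimen(ph$volume, ph$stack, corr, ph$landmarks, modality)
  pairs <- pair_records(meas$us, meas$histo)
  list(correspondence = corr, us = meas$us, histo = meas$histo,
       pairs = pairs, discordant = meas$discordant)
}

#' Run the full pipeline on a cohort and pool the pairs
#'
#' @param cohort a [generate_cohort()] result.
#' @param window correspondence search half-window, mm.
#' @return pooled `paired_measurements` across all specimens.
#' @export
analyze_cohort <- function(cohort, window = 4) {
  pool_pairs(lapply(cohort, function(ph) analyze_specimen(ph, window)$pairs))
}

#' Estimate linear tissue shrinkage from paired measurements
#'
#' Under the uniform-shrinkage model `histology = (1 - s) * US`, the
#' through-origin least-squares slope of histology on US estimates
#' (1 - s): `s_hat = 1 - sum(histo * us) / sum(us^2)`. Only the per-slice
#' measures (TT and the three region margins) are used: the
#' anterior/posterior margins are quantized at the 4 mm slice pitch on
#' the histology side (the "rough step size" limitation), which gives
#' them enormous leverage without carrying scale information.
#'
#' @param pairs a `paired_measurements` object.
#' @return estimated shrinkage fraction `s_hat`.
#' @export
estimate_shrinkage <- function(pairs) {
  p <- pairs[!pairs$region %in% c("anterior", "posterior") & pairs$us > 0, ]
  if (nrow(p) < 2) stopf("too few per-slice pairs to estimate shrinkage")
  1 - sum(p$histo * p$us) / sum(p$us^2)
}

#' Write a phantom dataset to disk
#'
#' Volume as NRRD, slides as PNG + JSON sidecar, US landmarks and ground
#' truth as JSON/CSV — the on-disk layout the readers consume.
#'
#' @param ph a [phantom_specimen()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_phantom_dataset <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_volume(ph$volume, file.path(dir, "volume.nrrd"))
  write_slide_stack(ph$stack, file.path(dir, "slides"))
  utils::write.csv(ph$landmarks, file.path(dir, "us_landmarks.csv"),
                   row.names = FALSE)
  write_measurements(true_measurements(ph$truth, "US"),
                     file.path(dir, "truth_us.csv"))
  write_measurements(true_measurements(ph$truth, "histology"),
                     file.path(dir, "truth_histology.csv"))
  jsonlite::write_json(ph$truth$correspondence, file.path(dir, "truth_correspondence.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(dir)
}
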