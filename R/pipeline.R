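#' Production-scale default settings of the analysis pipeline
#'
#' The standard configuration for protease activation analysis on long MD
#' datasets: 80 ns MSM lag at a 10 ps frame stride (8000 frames), 400
#' k-means microstates on the 4 leading TICs, 2 metastable states, 0.90
#' PCCA++ membership cutoff and a 3.8 Angstrom Na+ coordination cutoff.
#' Desk-scale analyses (e.g. on the synthetic double well) override these.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(lag_ns = 80, frame_stride_ps = 10, lag_frames = 8000,
       n_clusters = 400, n_tics = 4, n_meta = 2,
       membership_cutoff = 0.90, na_cutoff_A = 3.8,
       kmeans_seed = 1234)
}

#' Bookkeeping of the seeding and featurization protocol
#'
#' Frame and trajectory counts implied by a TMD-seeded sampling protocol:
#' `n_tmd` targeted trajectories of `tmd_length_ns` sampled every
#' `tmd_stride_ps` are clustered into `n_seeds` seeds; each seed spawns
#' `sims_per_seed` unbiased simulations of `cmd_length_ns` (of which
#' `sims_without_na` per seed are sodium-free), sampled every
#' `cmd_stride_ps` for the featurization.
#'
#' @param n_tmd,tmd_length_ns,tmd_stride_ps targeted-run parameters.
#' @param n_seeds,sims_per_seed,sims_without_na seeding parameters.
#' @param cmd_length_ns,cmd_stride_ps unbiased-run parameters.
#' @return named list of derived counts: `tmd_frames`, `n_cmd`,
#'   `n_cmd_without_na`, `n_cmd_with_na`, `total_time_us`,
#'   `frames_without_na`, `frames_with_na`.
#' @export
protocol_bookkeeping <- function(n_tmd = 10, tmd_length_ns = 140,
                                 tmd_stride_ps = 100, n_seeds = 100,
                                 sims_per_seed = 3, sims_without_na = 2,
                                 cmd_length_ns = 200, cmd_stride_ps = 10) {
  frames_per_tmd <- tmd_length_ns * 1000 / tmd_stride_ps
  n_cmd <- n_seeds * sims_per_seed
  n_wo <- n_seeds * sims_without_na
  n_w <- n_cmd - n_wo
  frames_per_cmd <- cmd_length_ns * 1000 / cmd_stride_ps
  list(tmd_frames = n_tmd * frames_per_tmd,
       n_cmd = n_cmd, n_cmd_without_na = n_wo, n_cmd_with_na = n_w,
       total_time_us = n_cmd * cmd_length_ns / 1000,
       frames_without_na = n_wo * frames_per_cmd,
       frames_with_na = n_w * frames_per_cmd)
}

#' Full featurization -> TICA -> k-means -> MSM -> PCCA++ pipeline
#'
#' Runs the complete analysis on per-trajectory feature matrices: reversible
#' TICA at `tica_lag`, k-means discretization of the leading TICs, reversible
#' MSM estimation at `lag`, PCCA++ lumping, coarse stationary probabilities
#' and metastable mean first passage times, with optional trajectory-
#' bootstrap uncertainties.
#'
#' @param features list of feature matrices (one per trajectory, shared
#'   columns).
#' @param lag MSM lag in frames.
#' @param tica_lag TICA lag in frames (default: `lag`).
#' @param n_tics retained TICA components (default 4).
#' @param n_clusters k-means microstates (default 400).
#' @param n_meta metastable states (default 2).
#' @param cutoff PCCA++ membership cutoff for frame weights (default 0.90).
#' @param seed k-means seed.
#' @param dt_frame physical time per frame.
#' @param n_boot bootstrap resamples (0 to skip).
#' @return list with `tica`, `projections`, `kmeans`, `dtrajs`, `msm`,
#'   `pcca`, `populations`, `mfpt`, `weights`, and `bootstrap` (or `NULL`);
#'   class `msm_pipeline`.
#' @export
run_msm_pipeline <- function(features, lag, tica_lag = lag, n_tics = 4,
                             n_clusters = 400, n_meta = 2, cutoff = 0.90,
                             seed = 1234, dt_frame = 1, n_boot = 0) {
  if (is.matrix(features)) features <- list(features)
  tica <- fit_tica(features, lag = tica_lag, n_components = n_tics)
  proj <- lapply(features, function(X) project(tica, X))
  km <- kmeans_fit(do.call(rbind, proj), k = n_clusters, seed = seed)
  dtrajs <- assign_clusters(km, proj)
  C <- count_transitions(dtrajs, lag)
  msm <- estimate_reversible(C, dt_frame = dt_frame, lag = lag)
  pcca <- pcca_plus(msm, n_meta)
  w <- frame_weights(dtrajs, msm, pcca, cutoff = cutoff)
  boot <- if (n_boot > 0)
    bootstrap_ensemble(dtrajs, lag, n_meta = n_meta, n_resamples = n_boot,
                       seed = seed, dt_frame = dt_frame)
  else NULL
  structure(list(tica = tica, projections = proj, kmeans = km,
                 dtrajs = dtrajs, msm = msm, pcca = pcca,
                 populations = pcca$coarse_pi,
                 mfpt = mfpt_coarse(msm, pcca),
                 weights = w, bootstrap = boot),
            class = "msm_pipeline")
}

#' @export
print.msm_pipeline <- function(x, ...) {
  cat(sprintf("MSM pipeline: %d microstates (of %d), lag %g time units\n",
              length(x$msm$pi), x$kmeans$k, lag_time(x$msm)))
  cat("  coarse populations:", paste(signif(x$populations, 3),
                                     collapse = ", "), "\n")
  cat("  mfpts:", paste(sprintf("%s = %.3g", names(x$mfpt), x$mfpt),
                        collapse = ", "), "\n")
  invisible(x)
}
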