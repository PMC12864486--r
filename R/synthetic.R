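## Synthetic multi-timepoint EEG cohort generator.
##
## Emulates the group-by-time structure the analysis assumes: progressive
## spectral slowing (rising delta/theta, falling alpha/beta/gamma), falling
## signal complexity (mixing weight rho toward a deterministic quasi-periodic
## component) and falling alpha-band phase synchrony (coupling weight kappa
## of a shared, per-channel phase-shifted alpha source) in the PMCI group,
## with group differences negligible at timepoints 1-2 and pronounced at 3-4.

# Baseline per-band RMS amplitudes (muV) of the stochastic components.
BASE_BAND_AMP <- c(delta = 0.9, theta = 0.7, alpha = 1.6, beta = 0.8,
                   gamma = 0.3)

# Mild anterior/posterior topographic gradients: alpha strongest occipitally,
# slow rhythms slightly frontal.
channel_band_gain <- function() {
  ch <- eeg_channels()
  # scalp position rank front (0) -> back (1)
  pos <- c(Fp1 = 0, Fp2 = 0, F3 = .25, F4 = .25, F7 = .25, F8 = .25,
           C3 = .5, C4 = .5, T3 = .5, T4 = .5,
           P3 = .75, P4 = .75, T5 = .75, T6 = .75, O1 = 1, O2 = 1)[ch]
  gain <- cbind(delta = 1.15 - 0.25 * pos,
                theta = 1.10 - 0.20 * pos,
                alpha = 0.80 + 0.45 * pos,
                beta = rep(1, 16),
                gamma = rep(1, 16))
  rownames(gain) <- ch
  gain
}

#' Group-by-time effect schedule for the synthetic cohort
#'
#' Encodes, per group and timepoint, the band-amplitude multipliers, the
#' alpha-coupling coefficient `kappa` (share of a common phase-shifted alpha
#' source; raises inter-channel PLI) and the regularity weight `rho` (share
#' of a deterministic quasi-periodic component; lowers entropy), plus the
#' between-subject log-normal amplitude SD and the pink-noise floor.
#'
#' @param band_mult numeric array `[group, timepoint, band]` of positive
#'   amplitude multipliers; groups `c("SMCI","PMCI")`, bands as [eeg_bands()].
#' @param kappa,rho numeric matrices `[group, timepoint]` with values in
#'   `[0, 1]`.
#' @param subject_sd SD (log scale) of per-subject, per-band amplitude
#'   multipliers.
#' @param noise_floor RMS amplitude (muV) of the 1/f noise floor.
#' @return Object of class `effect_schedule`.
#' @export
effect_schedule <- function(band_mult, kappa, rho, subject_sd = 0.1,
                            noise_floor = 0.3) {
  if (any(band_mult <= 0)) stop_invalid_config("band multipliers must be > 0")
  if (any(kappa < 0 | kappa > 1)) stop_invalid_config("kappa must be in [0, 1]")
  if (any(rho < 0 | rho > 1)) stop_invalid_config("rho must be in [0, 1]")
  if (subject_sd < 0 || noise_floor < 0) {
    stop_invalid_config("subject_sd and noise_floor must be >= 0")
  }
  structure(list(band_mult = band_mult, kappa = kappa, rho = rho,
                 subject_sd = subject_sd, noise_floor = noise_floor),
            class = "effect_schedule")
}

schedule_dims <- function(n_time = 4) {
  list(groups = c("SMCI", "PMCI"), timepoints = seq_len(n_time),
       bands = eeg_bands()$band)
}

#' Default effect schedule
#'
#' The study conditions the generator emulates: both groups drift toward
#' slower, less complex, less synchronised EEG; groups are identical at
#' timepoints 1-2 and diverge at 3-4, with the PMCI group showing a
#' pronounced rise in delta/theta amplitude (+35%/+55% at timepoints 3/4), a
#' fall in alpha/beta/gamma (-25%/-35%), falling alpha coupling
#' (0.55 -> 0.25) and rising regularity (0.25 -> 0.55).
#'
#' @return An [effect_schedule()].
#' @export
default_effect_schedule <- function() {
  dims <- schedule_dims()
  bm <- array(1, c(2, 4, 5),
              dimnames = list(dims$groups, dims$timepoints, dims$bands))
  slow <- c("delta", "theta")
  fast <- c("alpha", "beta", "gamma")
  bm["SMCI", , slow] <- c(1.00, 1.02, 1.05, 1.08)
  bm["SMCI", , fast] <- c(1.00, 0.99, 0.97, 0.95)
  bm["PMCI", , slow] <- c(1.00, 1.02, 1.35, 1.55)
  bm["PMCI", , fast] <- c(1.00, 0.99, 0.75, 0.65)
  kappa <- rbind(SMCI = c(0.55, 0.54, 0.52, 0.50),
                 PMCI = c(0.55, 0.54, 0.35, 0.25))
  rho <- rbind(SMCI = c(0.25, 0.26, 0.28, 0.30),
               PMCI = c(0.25, 0.26, 0.45, 0.55))
  effect_schedule(bm, kappa, rho)
}

#' Null effect schedule
#'
#' Both groups share identical, time-constant parameters: under this schedule
#' no feature carries group information, so the downstream pipeline must
#' perform at chance (a calibration and leakage check).
#'
#' @param kappa,rho constant coupling and regularity weights.
#' @inheritParams effect_schedule
#' @return An [effect_schedule()].
#' @export
null_effect_schedule <- function(kappa = 0.5, rho = 0.25, subject_sd = 0.1,
                                 noise_floor = 0.3) {
  dims <- schedule_dims()
  bm <- array(1, c(2, 4, 5),
              dimnames = list(dims$groups, dims$timepoints, dims$bands))
  effect_schedule(bm,
                  matrix(kappa, 2, 4, dimnames = list(dims$groups, NULL)),
                  matrix(rho, 2, 4, dimnames = list(dims$groups, NULL)),
                  subject_sd, noise_floor)
}

## Unit-variance band-limited noise of length n.
band_noise <- function(n, fs, lo, hi) {
  x <- bandpass_vector(rnorm(n), fs, lo, hi)
  x / sd(x)
}

## Unit-variance 1/f (pink-ish) noise.
pink_noise <- function(n) {
  X <- fft(rnorm(n))
  f <- c(1, seq_len(n - 1))            # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)              # symmetric spectral shaping
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE) / n)
  x <- x - mean(x)
  x / sd(x)
}

## Unit-variance quasi-periodic component: two incommensurate tones;
## deterministic given its phases.
quasi_periodic <- function(n, fs, phases, freqs = c(5.2, 7.9),
                           amps = c(1, 0.8)) {
  t <- seq(0, by = 1 / fs, length.out = n)
  x <- amps[1L] * sin(2 * pi * freqs[1L] * t + phases[1L]) +
    amps[2L] * sin(2 * pi * freqs[2L] * t + phases[2L])
  x / sqrt(sum(amps^2) / 2)
}

#' Generate one synthetic EEG epoch
#'
#' Builds a 16-channel recording as the sum of per-band filtered-noise
#' components with group/timepoint amplitude multipliers and topographic
#' gains, a `rho`-weighted deterministic quasi-periodic component replacing
#' part of the slow stochastic activity (variance-preserving mix), a
#' `kappa`-weighted shared alpha source injected into all channels with fixed
#' per-channel phase offsets, and a pink-noise floor.
#'
#' @param group `"SMCI"` or `"PMCI"`.
#' @param timepoint integer 1-4.
#' @param schedule an [effect_schedule()].
#' @param subject_effects named per-band amplitude multipliers for the
#'   subject (default: none).
#' @param fs sampling rate (Hz), >= 100.
#' @param duration epoch length in seconds, >= 4.
#' @param seed RNG seed (required for reproducibility).
#' @param subject_id,... identifiers stored on the epoch.
#' @return An [eeg_epoch()].
#' @export
generate_epoch <- function(group, timepoint, schedule = default_effect_schedule(),
                           subject_effects = NULL, fs = 250, duration = 30,
                           seed = 1L, subject_id = NA_character_) {
  group <- match.arg(group, c("SMCI", "PMCI"))
  timepoint <- as.integer(timepoint)
  if (fs < 100) stop_invalid_config("fs must be >= 100 Hz")
  if (duration < 4) stop_invalid_config("duration must be >= 4 s")
  bands <- eeg_bands()
  if (is.null(subject_effects)) {
    subject_effects <- setNames(rep(1, 5), bands$band)
  }
  n <- round(duration * fs)
  gain <- channel_band_gain()
  amp <- BASE_BAND_AMP * schedule$band_mult[group, timepoint, bands$band] *
    subject_effects[bands$band]
  kappa <- schedule$kappa[group, timepoint]
  rho <- schedule$rho[group, timepoint]

  with_seed(seed, {
    # shared alpha source, phase-shifted per channel via its analytic signal
    s <- band_noise(n, fs, 8, 13)
    s_an <- hilbert_analytic(s)
    theta_off <- (seq_len(16) - 1L) * 2 * pi / 17
    data <- matrix(0, 16, n)
    for (c_ in seq_len(16)) {
      slow <- amp["delta"] * gain[c_, "delta"] * band_noise(n, fs, 0.5, 4) +
        amp["theta"] * gain[c_, "theta"] * band_noise(n, fs, 4, 8)
      sigma_slow <- sqrt((amp["delta"] * gain[c_, "delta"])^2 +
                           (amp["theta"] * gain[c_, "theta"])^2)
      det <- quasi_periodic(n, fs, runif(2, 0, 2 * pi))
      slow_mixed <- sqrt(1 - rho) * slow + sqrt(rho) * sigma_slow * det

      shared <- Re(s_an * exp(1i * theta_off[c_]))
      shared <- shared / sd(shared)
      alpha <- amp["alpha"] * gain[c_, "alpha"] *
        (sqrt(kappa) * shared + sqrt(1 - kappa) * band_noise(n, fs, 8, 13))

      fastn <- amp["beta"] * gain[c_, "beta"] * band_noise(n, fs, 13, 30) +
        amp["gamma"] * gain[c_, "gamma"] * band_noise(n, fs, 30, 45)
      sigma_fast <- sqrt((amp["beta"] * gain[c_, "beta"])^2 +
                           (amp["gamma"] * gain[c_, "gamma"])^2)
      det_fast <- quasi_periodic(n, fs, runif(2, 0, 2 * pi),
                                 freqs = c(16.3, 33.7), amps = c(1, 0.6))
      fast_mixed <- sqrt(1 - rho) * fastn + sqrt(rho) * sigma_fast * det_fast

      # the broadband floor is purely stochastic, so it carries the same
      # regularity weight as the stochastic band components
      data[c_, ] <- slow_mixed + alpha + fast_mixed +
        sqrt(1 - rho) * schedule$noise_floor * pink_noise(n)
    }
    eeg_epoch(data, fs, subject_id = subject_id, timepoint = timepoint)
  })
}

#' Generate a synthetic longitudinal cohort
#'
#' @param n_smci,n_pmci group sizes (defaults 38 stable, 27 progressive).
#' @param timepoints which measurement occasions to generate (1-4).
#' @param schedule an [effect_schedule()].
#' @param fs sampling rate (Hz).
#' @param duration epoch length (s).
#' @param seed base RNG seed; the cohort is a deterministic function of the
#'   full configuration and this seed.
#' @return A [cohort_dataset()].
#' @export
generate_cohort <- function(n_smci = 38, n_pmci = 27, timepoints = 1:4,
                            schedule = default_effect_schedule(),
                            fs = 250, duration = 30, seed = 1L) {
  if (n_smci < 1 || n_pmci < 1) stop_invalid_config("group sizes must be >= 1")
  if (duration < 4) stop_invalid_config("duration must be >= 4 s")
  if (fs < 100) stop_invalid_config("fs must be >= 100 Hz")
  if (is.null(seed)) stop_invalid_config("a seed is required")
  groups <- c(rep("SMCI", n_smci), rep("PMCI", n_pmci))
  ids <- c(sprintf("SMCI%03d", seq_len(n_smci)),
           sprintf("PMCI%03d", seq_len(n_pmci)))
  n_sub <- length(ids)
  seeds <- derive_seeds(seed, n_sub * (length(timepoints) + 1L))
  bands <- eeg_bands()$band
  subjects <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    sfx <- with_seed(seeds[i], {
      setNames(exp(rnorm(5, 0, schedule$subject_sd)), bands)
    })
    epochs <- list()
    for (k in seq_along(timepoints)) {
      tp <- timepoints[k]
      ep_seed <- seeds[n_sub + (i - 1L) * length(timepoints) + k]
      epochs[[as.character(tp)]] <- generate_epoch(
        groups[i], tp, schedule, sfx, fs, duration, ep_seed, subject_id = ids[i])
    }
    subjects[[i]] <- subject_record(ids[i], groups[i], epochs,
                                    metadata = list(subject_sd = schedule$subject_sd))
  }
  cohort_dataset(subjects, generation_config = list(
    n_smci = n_smci, n_pmci = n_pmci, timepoints = timepoints,
    schedule = schedule, fs = fs, duration = duration, seed = seed))
}

#' Write a cohort to disk as plain-text arrays
#'
#' One CSV per subject-by-timepoint recording (samples x channels, header =
#' channel names), a cohort manifest CSV (`subject_id`, `group`, `timepoint`,
#' `filename`, `fs`) and a JSON sidecar with the generation configuration.
#'
#' @param cohort a [cohort_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in cohort$subjects) {
    for (tp in names(s$epochs)) {
      ep <- s$epochs[[tp]]
      fn <- sprintf("%s_t%s.csv", s$subject_id, tp)
      write.csv(as.data.frame(t(ep$data)), file.path(dir, fn),
                row.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, group = s$group,
        timepoint = as.integer(tp), filename = fn, fs = ep$fs,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- cohort$generation_config
  if (!is.null(cfg)) {
    cfg$schedule <- unclass(cfg$schedule)
    jsonlite::write_json(cfg, file.path(dir, "cohort.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv` and the recording CSVs.
#' @return A [cohort_dataset()].
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  subjects <- lapply(split(manifest, manifest$subject_id), function(mf) {
    epochs <- list()
    for (r in seq_len(nrow(mf))) {
      m <- read.csv(file.path(dir, mf$filename[r]), check.names = FALSE)
      epochs[[as.character(mf$timepoint[r])]] <- eeg_epoch(
        t(as.matrix(m)), mf$fs[r], subject_id = mf$subject_id[r],
        timepoint = mf$timepoint[r], channels = colnames(m))
    }
    subject_record(mf$subject_id[1L], mf$group[1L], epochs)
  })
  # preserve manifest order
  ord <- unique(manifest$subject_id)
  cohort_dataset(unname(subjects[ord]))
}
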