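# Synthetic annotated single-lead ECG. Beats are rendered as sums of
# Gaussian bumps (P wave, biphasic QRS pair, T wave) placed at cumulative
# RR times; this is not a physiological model, but it makes beat classes
# morphologically separable and the written annotations are exact ground
# truth for the rendered signal.

# unified rhythm code -> raw symbol written by the beat-level generator
.synth_rhythm_raw <- c(SINUS = "N", AFIB = "AFIB", AFL = "AFL",
                       STACH = "ST", SBRAD = "SBR", SVTA = "SVTA")

#' Construct a beat morphology template
#'
#' @param code Unified beat code the template renders (e.g. `"N"`, `"PVC"`).
#' @param qrs_width_s QRS width in seconds (> 0).
#' @param qrs_amp QRS amplitude in mV (non-zero; negative = inverted
#'   polarity).
#' @param p_wave Logical: render a P wave before the QRS.
#' @param t_amp T-wave amplitude in mV.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(code, qrs_width_s, qrs_amp, p_wave = TRUE,
                          t_amp = 0.3) {
  if (qrs_width_s <= 0) stop("qrs_width_s must be positive")
  if (qrs_amp == 0) stop("qrs_amp must be non-zero")
  structure(list(code = code, qrs_width_s = qrs_width_s, qrs_amp = qrs_amp,
                 p_wave = p_wave, t_amp = t_amp),
            class = "beat_template")
}

#' Default beat templates
#'
#' Keyed by the raw beat symbol the generator writes: `N` (narrow upright
#' QRS with P wave), `V` (premature ventricular: wide, inverted, no P
#' wave), `A` (premature atrial: narrow QRS, reduced amplitude, no
#' preceding P wave).
#'
#' @return Named list of [beat_template()] objects.
#' @export
default_beat_templates <- function() {
  list(
    N = beat_template("N", qrs_width_s = 0.08, qrs_amp = 1.0,
                      p_wave = TRUE, t_amp = 0.30),
    V = beat_template("PVC", qrs_width_s = 0.16, qrs_amp = -1.4,
                      p_wave = FALSE, t_amp = 0.50),
    A = beat_template("PAC", qrs_width_s = 0.08, qrs_amp = 0.85,
                      p_wave = FALSE, t_amp = 0.25)
  )
}

# additive rendering of one beat into `samples` centred at sample `r`
.render_beat <- function(samples, r, tpl, fs) {
  sigma_q <- tpl$qrs_width_s / 2.5
  if (round(tpl$qrs_width_s * fs) < 3) {
    stop("sampling frequency ", fs, " Hz too low to render a ",
         tpl$qrs_width_s, " s QRS (needs >= 3 samples)")
  }
  span <- round(0.45 * fs)
  idx <- (r - span):(r + span)
  keep <- idx >= 1 & idx <= length(samples)
  t <- (idx[keep] - r) / fs
  y <- tpl$qrs_amp * exp(-t^2 / (2 * sigma_q^2)) -
    0.35 * tpl$qrs_amp * exp(-(t - tpl$qrs_width_s)^2 / (2 * sigma_q^2))
  if (tpl$p_wave) y <- y + 0.15 * exp(-(t + 0.17)^2 / (2 * 0.025^2))
  y <- y + tpl$t_amp * exp(-(t - 0.28)^2 / (2 * 0.05^2))
  samples[idx[keep]] <- samples[idx[keep]] + y
  samples
}

#' Construct a rhythm plan
#'
#' A rhythm plan is an ordered list of rhythm episodes with their RR
#' interval models. Regular rhythms draw RR intervals as
#' `mean + Normal(0, jitter)`; irregular rhythms (atrial fibrillation)
#' draw log-normal RR intervals with the given coefficient of variation.
#'
#' @param episodes data.frame with columns `code` (unified rhythm code),
#'   `duration_s`, `rr_mean_s`, `rr_jitter_s` (regular model),
#'   `rr_cv` (irregular model) and `irregular` (logical).
#' @return An object of class `rhythm_plan`.
#' @export
rhythm_plan <- function(episodes) {
  required <- c("code", "duration_s", "rr_mean_s", "rr_jitter_s", "rr_cv",
                "irregular")
  if (!all(required %in% names(episodes))) {
    stop("rhythm plan requires columns: ", paste(required, collapse = ", "))
  }
  if (!nrow(episodes)) stop("rhythm plan must contain at least one episode")
  if (any(episodes$duration_s <= 0)) stop("episode durations must be positive")
  if (any(!episodes$code %in% names(.synth_rhythm_raw))) {
    stop("unsupported rhythm code(s): ",
         paste(setdiff(episodes$code, names(.synth_rhythm_raw)), collapse = ", "))
  }
  structure(list(episodes = episodes), class = "rhythm_plan")
}

#' Default RR model for one rhythm episode
#'
#' Encodes the clinical heart-rate conventions behind the rhythm classes:
#' sinus rhythm 0.8 s mean RR, sinus tachycardia < 0.6 s, sinus
#' bradycardia > 1.0 s, atrial fibrillation irregular (RR coefficient of
#' variation 0.25), atrial flutter fast and regular, supraventricular
#' tachycardia fastest.
#'
#' @param code Unified rhythm code.
#' @param duration_s Episode duration in seconds.
#' @return One-row data.frame suitable for [rhythm_plan()].
#' @export
rhythm_episode_spec <- function(code, duration_s) {
  defs <- list(
    SINUS = list(rr = 0.80, jitter = 0.020, cv = 0,    irregular = FALSE),
    STACH = list(rr = 0.45, jitter = 0.015, cv = 0,    irregular = FALSE),
    SBRAD = list(rr = 1.30, jitter = 0.030, cv = 0,    irregular = FALSE),
    AFIB  = list(rr = 0.70, jitter = 0,     cv = 0.25, irregular = TRUE),
    AFL   = list(rr = 0.55, jitter = 0.010, cv = 0,    irregular = FALSE),
    SVTA  = list(rr = 0.40, jitter = 0.010, cv = 0,    irregular = FALSE)
  )
  if (!code %in% names(defs)) stop("unsupported rhythm code: ", code)
  d <- defs[[code]]
  data.frame(code = code, duration_s = duration_s, rr_mean_s = d$rr,
             rr_jitter_s = d$jitter, rr_cv = d$cv, irregular = d$irregular,
             stringsAsFactors = FALSE)
}

#' Generate one annotated synthetic ECG record
#'
#' Beats are placed at cumulative RR times within each planned episode.
#' Every beat is normal except for independent PVC/PAC substitutions; a
#' PAC additionally shortens its preceding RR interval by 20% (premature
#' timing). The signal is the sum of the placed beat templates plus
#' additive Gaussian noise. Annotations returned are exact ground truth
#' for the rendered signal. Randomness comes from the R RNG; call
#' `set.seed()` beforehand for reproducibility.
#'
#' @param plan A [rhythm_plan()].
#' @param templates Named list of beat templates (`N`, `V`, `A`).
#' @param pvc_rate,pac_rate Per-beat substitution probabilities in `[0, 1]`.
#' @param fs Sampling frequency in Hz.
#' @param noise_sd Gaussian noise standard deviation (mV).
#' @param record_id,patient_id Identifiers for the returned record.
#' @return List with `record` (an `ecg_record`), `beats` (data.frame
#'   `sample`, `symbol` with raw symbols `N`/`V`/`A`) and `episodes`
#'   (data.frame `start`, `end`, `symbol` with raw rhythm symbols,
#'   half-open spans).
#' @export
generate_record <- function(plan, templates = default_beat_templates(),
                            pvc_rate = 0, pac_rate = 0, fs = 250,
                            noise_sd = 0.02, record_id = "synth",
                            patient_id = record_id) {
  stopifnot(inherits(plan, "rhythm_plan"))
  if (pvc_rate < 0 || pvc_rate > 1 || pac_rate < 0 || pac_rate > 1 ||
      pvc_rate + pac_rate > 1) {
    stop("pvc_rate and pac_rate must lie in [0,1] with sum <= 1")
  }
  eps <- plan$episodes
  total_s <- sum(eps$duration_s)
  n <- round(total_s * fs)
  samples <- numeric(n)
  beat_t <- numeric(0)
  beat_sym <- character(0)
  ep_start_s <- cumsum(c(0, eps$duration_s[-nrow(eps)]))
  for (e in seq_len(nrow(eps))) {
    t <- ep_start_s[e] + 0.3 # settle-in before the first beat
    end_s <- ep_start_s[e] + eps$duration_s[e]
    while (TRUE) {
      if (eps$irregular[e]) {
        sdlog <- sqrt(log(1 + eps$rr_cv[e]^2))
        rr <- stats::rlnorm(1, log(eps$rr_mean_s[e]) - sdlog^2 / 2, sdlog)
      } else {
        rr <- eps$rr_mean_s[e] + stats::rnorm(1, 0, eps$rr_jitter_s[e])
      }
      rr <- max(rr, 0.2)
      u <- stats::runif(1)
      sym <- if (u < pvc_rate) "V" else if (u < pvc_rate + pac_rate) "A" else "N"
      if (sym == "A") rr <- rr * 0.8 # premature atrial timing
      t <- t + rr
      if (t >= end_s - 0.05) break
      beat_t <- c(beat_t, t)
      beat_sym <- c(beat_sym, sym)
    }
  }
  beat_r <- as.integer(round(beat_t * fs)) + 1L
  keep <- beat_r >= 1 & beat_r <= n
  beat_r <- beat_r[keep]; beat_sym <- beat_sym[keep]
  for (i in seq_along(beat_r)) {
    samples <- .render_beat(samples, beat_r[i], templates[[beat_sym[i]]], fs)
  }
  if (noise_sd > 0) samples <- samples + stats::rnorm(n, 0, noise_sd)
  ep_start <- as.integer(round(ep_start_s * fs)) + 1L
  episodes <- data.frame(
    start = ep_start,
    end = c(ep_start[-1], as.integer(n) + 1L),
    symbol = unname(.synth_rhythm_raw[eps$code]),
    stringsAsFactors = FALSE)
  list(record = ecg_record(record_id, patient_id, samples, fs, "MLII"),
       beats = data.frame(sample = beat_r, symbol = beat_sym,
                          stringsAsFactors = FALSE),
       episodes = episodes)
}

#' Configuration for the synthetic dataset generators
#'
#' @param n_patients Number of patients (>= 1).
#' @param records_per_patient Records per patient (>= 1).
#' @param record_duration_s Duration of each record in seconds.
#' @param fs Sampling frequency in Hz (default 250; network frequencies
#'   are obtained downstream by resampling).
#' @param class_mixture Named numeric vector of rhythm-class probabilities
#'   (must sum to 1).
#' @param noise_sd Additive Gaussian noise SD in mV.
#' @param pvc_rate,pac_rate Baseline per-beat ectopic substitution rates.
#' @param seed Integer RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients, records_per_patient = 1,
                             record_duration_s = 60, fs = 250,
                             class_mixture = c(SINUS = 0.7, AFIB = 0.3),
                             noise_sd = 0.02, pvc_rate = 0.08,
                             pac_rate = 0.05, seed = 0) {
  if (n_patients < 1 || records_per_patient < 1) stop("counts must be >= 1")
  if (abs(sum(class_mixture) - 1) > 1e-8) stop("class_mixture must sum to 1")
  if (is.null(names(class_mixture)) ||
      !all(names(class_mixture) %in% names(.synth_rhythm_raw))) {
    stop("class_mixture must be named with rhythm codes: ",
         paste(names(.synth_rhythm_raw), collapse = ", "))
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_patients = n_patients,
                 records_per_patient = records_per_patient,
                 record_duration_s = record_duration_s, fs = fs,
                 class_mixture = class_mixture, noise_sd = noise_sd,
                 pvc_rate = pvc_rate, pac_rate = pac_rate, seed = seed),
            class = "generator_config")
}

# Dirichlet perturbation of the global mixture so that patients differ
# (enables meaningful stratified-split testing); concentration 10 keeps
# patient mixtures centred on the global one.
.patient_mixture <- function(mix, concentration = 10) {
  g <- stats::rgamma(length(mix), shape = mix * concentration + 1e-3)
  p <- g / sum(g)
  names(p) <- names(mix)
  p
}

#' Generate a beat-level annotated synthetic dataset on disk
#'
#' Writes WFDB-style records (`.hea`/`.dat`/`.atr` with beat and rhythm
#' annotations), a `RECORDS` file and `patients.csv`, then reopens the
#' directory through [open_dataset()]. Per-patient rhythm mixtures and
#' ectopic rates are drawn around the configured global values so that
#' patients differ.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory.
#' @return An `ecg_dataset` handle (dataset name `"synth"`).
#' @export
generate_beat_level_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create dataset directory: ", dir)
  set.seed(cfg$seed)
  ids <- character(0); pids <- character(0)
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("p%03d", p)
    mix <- .patient_mixture(cfg$class_mixture)
    pvc <- min(1, cfg$pvc_rate * stats::runif(1, 0.5, 1.5))
    pac <- min(1 - pvc, cfg$pac_rate * stats::runif(1, 0.5, 1.5))
    for (r in seq_len(cfg$records_per_patient)) {
      rid <- sprintf("%sr%02d", pid, r)
      remaining <- cfg$record_duration_s
      ep <- NULL
      while (remaining > 1e-9) {
        d <- min(remaining, stats::runif(1, 8, 20))
        if (remaining - d < 4) d <- remaining # avoid slivers
        code <- sample(names(mix), 1, prob = mix)
        ep <- rbind(ep, rhythm_episode_spec(code, d))
        remaining <- remaining - d
      }
      g <- generate_record(rhythm_plan(ep), pvc_rate = pvc, pac_rate = pac,
                           fs = cfg$fs, noise_sd = cfg$noise_sd,
                           record_id = rid, patient_id = pid)
      wfdb_write_record(dir, rid, g$record$samples, cfg$fs,
                        leads = g$record$lead_name)
      ann <- rbind(
        data.frame(sample = g$beats$sample, symbol = g$beats$symbol,
                   aux = "", stringsAsFactors = FALSE),
        data.frame(sample = g$episodes$start, symbol = "+",
                   aux = paste0("(", g$episodes$symbol),
                   stringsAsFactors = FALSE))
      wfdb_write_annotations(dir, rid, ann)
      ids <- c(ids, rid); pids <- c(pids, pid)
    }
  }
  writeLines(ids, file.path(dir, "RECORDS"))
  utils::write.csv(data.frame(record_id = ids, patient_id = pids),
                   file.path(dir, "patients.csv"), row.names = FALSE,
                   quote = FALSE)
  open_dataset(dir, name = "synth")
}

#' Generate a recording-level annotated synthetic dataset on disk
#'
#' Each record is a short (default 10 s) single-rhythm recording with one
#' recording-level label, written as WFDB-style signal files plus a
#' `labels.csv` table.
#'
#' @param cfg A [generator_config()]; `record_duration_s` defaults make
#'   sense around 10 s for this category.
#' @param dir Output directory.
#' @return An `ecg_dataset` handle (dataset name `"synthrec"`).
#' @export
generate_recording_level_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "generator_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create dataset directory: ", dir)
  set.seed(cfg$seed)
  ids <- character(0); pids <- character(0); labs <- character(0)
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("q%04d", p)
    for (r in seq_len(cfg$records_per_patient)) {
      rid <- sprintf("%sr%02d", pid, r)
      code <- sample(names(cfg$class_mixture), 1, prob = cfg$class_mixture)
      ep <- rhythm_episode_spec(code, cfg$record_duration_s)
      g <- generate_record(rhythm_plan(ep), pvc_rate = cfg$pvc_rate,
                           pac_rate = cfg$pac_rate, fs = cfg$fs,
                           noise_sd = cfg$noise_sd, record_id = rid,
                           patient_id = pid)
      wfdb_write_record(dir, rid, g$record$samples, cfg$fs,
                        leads = g$record$lead_name)
      ids <- c(ids, rid); pids <- c(pids, pid); labs <- c(labs, code)
    }
  }
  utils::write.csv(data.frame(record_id = ids, patient_id = pids,
                              labels = labs),
                   file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  open_dataset(dir, name = "synthrec")
}
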