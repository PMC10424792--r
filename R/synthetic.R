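#' Synthetic overnight sessions with ground truth
#'
#' Seeded generator for belt (BCG, 50 Hz) and oximeter (PPG, 100 Hz)
#' recordings with the statistical structure the pipeline assumes:
#' quasi-periodic IJK heartbeat complexes riding on a respiration baseline and
#' broadband noise, plus movement-induced saturation episodes. Every session
#' carries its ground-truth beat times and artifact spans, so detector output
#' can be scored exactly.
#'
#' @name synthetic_data
NULL

#' Subject profile for the session simulator
#'
#' Defaults describe a resting adult asleep: mean heart rate 55 bpm with a
#' slow mean-reverting wander of 5 bpm, 30 ms beat-to-beat jitter, a
#' respiration baseline at 0.2-0.4 Hz three times the J-peak amplitude,
#' broadband noise at 0.15 of the J amplitude, and about six movement
#' artifacts per hour lasting 100 s on average (together covering roughly
#' 15-20% of an overnight signal).
#'
#' @param subject_id opaque identifier.
#' @param mean_hr_bpm mean heart rate, beats/min, in `[30, 120]`.
#' @param hr_wander_sd_bpm stationary SD of the slow heart-rate drift.
#' @param ibi_jitter_sd_s SD of beat-to-beat interval jitter, seconds.
#' @param resp_rate_hz respiration frequency, Hz, in `[0.1, 0.5]`.
#' @param resp_amp respiration baseline amplitude relative to the J peak.
#' @param noise_sd white-noise SD relative to the J peak.
#' @param artifact_events_per_hour movement-artifact event rate.
#' @param artifact_duration_s mean artifact event length, seconds.
#' @param pat_delay_s PPG pulse arrival delay after the J peak, seconds.
#' @param adc_limits length-2 numeric, sensor saturation codes (min, max).
#' @param seed integer seed; all outputs are pure functions of
#'   (profile, duration, seed).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "s01",
                            mean_hr_bpm = 55,
                            hr_wander_sd_bpm = 5,
                            ibi_jitter_sd_s = 0.03,
                            resp_rate_hz = 0.3,
                            resp_amp = 3,
                            noise_sd = 0.15,
                            artifact_events_per_hour = 6,
                            artifact_duration_s = 100,
                            pat_delay_s = 0.25,
                            adc_limits = c(-10, 10),
                            seed = 1L) {
  stopifnot(mean_hr_bpm >= 30, mean_hr_bpm <= 120,
            resp_rate_hz >= 0.1, resp_rate_hz <= 0.5,
            artifact_events_per_hour >= 0, artifact_duration_s >= 0,
            length(adc_limits) == 2, adc_limits[1] < adc_limits[2])
  structure(list(subject_id = subject_id, mean_hr_bpm = mean_hr_bpm,
                 hr_wander_sd_bpm = hr_wander_sd_bpm,
                 ibi_jitter_sd_s = ibi_jitter_sd_s,
                 resp_rate_hz = resp_rate_hz, resp_amp = resp_amp,
                 noise_sd = noise_sd,
                 artifact_events_per_hour = artifact_events_per_hour,
                 artifact_duration_s = artifact_duration_s,
                 pat_delay_s = pat_delay_s, adc_limits = adc_limits,
                 seed = as.integer(seed)),
            class = "subject_profile")
}

# run a block with a local RNG state so generator calls never perturb the
# caller's stream and identical seeds give identical output
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate ground-truth beat times
#'
#' Inter-beat intervals follow `60 / HR(t)` plus Gaussian jitter, where
#' `HR(t)` is a smooth, bounded, mean-reverting (Ornstein-Uhlenbeck-style)
#' random walk around `mean_hr_bpm` with stationary SD `hr_wander_sd_bpm` and
#' a 60 s relaxation time. Heart rate is clamped to [30, 120] bpm and
#' intervals to at least 0.25 s. With zero wander and jitter the train is
#' exactly periodic.
#'
#' @param profile a [subject_profile].
#' @param duration_s session length in seconds (> 0).
#' @return Numeric vector of strictly increasing beat times in
#'   `[0, duration_s)`, first beat at 0.
#' @export
make_beat_times <- function(profile, duration_s) {
  stopifnot(duration_s > 0)
  with_local_seed(profile$seed, {
    tau <- 60                            # HR wander relaxation time, s
    n_max <- ceiling(duration_s * 4) + 2L  # hard IBI floor is 0.25 s
    beats <- numeric(n_max)
    hr <- profile$mean_hr_bpm
    t <- 0
    k <- 0L
    while (t < duration_s) {
      k <- k + 1L
      beats[k] <- t
      ibi <- 60 / hr
      if (profile$ibi_jitter_sd_s > 0)
        ibi <- ibi + stats::rnorm(1, 0, profile$ibi_jitter_sd_s)
      ibi <- max(ibi, 0.25)
      # AR(1) step with stationary SD = hr_wander_sd_bpm
      if (profile$hr_wander_sd_bpm > 0) {
        phi <- exp(-ibi / tau)
        hr <- profile$mean_hr_bpm + phi * (hr - profile$mean_hr_bpm) +
          sqrt(1 - phi^2) * profile$hr_wander_sd_bpm * stats::rnorm(1)
        hr <- min(max(hr, 30), 120)
      }
      t <- t + ibi
    }
    beats[seq_len(k)]
  })
}

# IJK template: Gaussian-windowed deflections so dominant energy lies in the
# 2-10 Hz band that the pre-elaboration filter passes
IJK_TEMPLATE <- list(offset_s = c(-0.06, 0, 0.06),
                     amp = c(-0.4, 1, -0.5),
                     sigma_s = 0.02)

ijk_wave <- function(t_rel) {
  v <- 0
  for (i in 1:3) {
    v <- v + IJK_TEMPLATE$amp[i] *
      exp(-((t_rel - IJK_TEMPLATE$offset_s[i])^2) / (2 * IJK_TEMPLATE$sigma_s^2))
  }
  v
}

#' Render a BCG belt recording from beat times
#'
#' Each beat contributes an IJK complex (I valley at -60 ms, amplitude -0.4;
#' J peak at 0, amplitude +1; K valley at +60 ms, amplitude -0.5; each a
#' Gaussian-windowed deflection of ~20 ms width). A sinusoidal respiration
#' baseline and white noise are added per the profile.
#'
#' @param beats beat times in seconds (may be empty: pure baseline + noise).
#' @param duration_s session length in seconds.
#' @param profile a [subject_profile].
#' @param fs_hz sampling rate, default 50.
#' @return A belt [recording].
#' @export
render_bcg <- function(beats, duration_s, profile, fs_hz = 50) {
  n <- floor(duration_s * fs_hz)
  tgrid <- (seq_len(n) - 1) / fs_hz
  sig <- profile$resp_amp * sin(2 * pi * profile$resp_rate_hz * tgrid)
  half_w <- ceiling(0.15 * fs_hz)        # template support: +/-150 ms
  offs <- -half_w:half_w
  for (tb in beats) {
    c0 <- round(tb * fs_hz)
    idx <- c0 + offs + 1L
    ok <- idx >= 1L & idx <= n
    sig[idx[ok]] <- sig[idx[ok]] + ijk_wave((idx[ok] - 1L) / fs_hz - tb)
  }
  if (profile$noise_sd > 0) {
    sig <- sig + with_local_seed(profile$seed + 1L,
                                 stats::rnorm(n, 0, profile$noise_sd))
  }
  recording(profile$subject_id, "belt", fs_hz, 0, sig)
}

#' Inject movement-saturation artifacts
#'
#' Artifact events are drawn from a Poisson process with the profile's rate
#' and exponential durations. Within each event the signal is replaced by a
#' large random-walk motion transient clipped to the ADC limits, producing the
#' flat-topped saturation runs the repair stage must detect. Overlapping
#' events are merged.
#'
#' @param rec a belt [recording].
#' @param profile a [subject_profile].
#' @return List with `recording` (samples overwritten inside events) and
#'   `artifact_spans`, a two-column matrix of (start_s, end_s).
#' @export
inject_artifacts <- function(rec, profile) {
  duration_s <- length(rec$samples) / rec$fs_hz
  if (profile$artifact_events_per_hour == 0)
    return(list(recording = rec,
                artifact_spans = matrix(numeric(0), ncol = 2,
                                        dimnames = list(NULL, c("start_s", "end_s")))))
  with_local_seed(profile$seed + 2L, {
    lam <- profile$artifact_events_per_hour * duration_s / 3600
    n_ev <- stats::rpois(1, lam)
    spans <- matrix(numeric(0), ncol = 2)
    if (n_ev > 0) {
      starts <- sort(stats::runif(n_ev, 0, duration_s))
      durs <- stats::rexp(n_ev, 1 / profile$artifact_duration_s)
      ends <- pmin(starts + durs, duration_s)
      spans <- cbind(starts, ends)
      # merge overlaps
      merged <- spans[1, , drop = FALSE]
      for (i in seq_len(n_ev)[-1]) {
        if (spans[i, 1] <= merged[nrow(merged), 2]) {
          merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], spans[i, 2])
        } else merged <- rbind(merged, spans[i, ])
      }
      spans <- merged
    }
    lim <- profile$adc_limits
    samples <- rec$samples
    for (i in seq_len(nrow(spans))) {
      i0 <- floor(spans[i, 1] * rec$fs_hz) + 1L
      i1 <- min(ceiling(spans[i, 2] * rec$fs_hz), length(samples))
      m <- i1 - i0 + 1L
      if (m < 1) next
      rw <- cumsum(stats::rnorm(m))
      rw <- rw - mean(rw)
      peak <- max(abs(rw))
      if (peak == 0) peak <- 1
      half <- (lim[2] - lim[1]) / 2
      mid <- (lim[2] + lim[1]) / 2
      # scale so the walk overshoots both rails: guarantees clipped flat runs
      trans <- mid + rw / peak * 4 * half
      samples[i0:i1] <- pmin(pmax(trans, lim[1]), lim[2])
    }
    dimnames(spans) <- list(NULL, c("start_s", "end_s"))
    list(recording = recording(rec$subject_id, rec$device_kind, rec$fs_hz,
                               rec$t0_ms, samples, rec$quality),
         artifact_spans = spans)
  })
}

#' Render a PPG oximeter recording from beat times
#'
#' One smooth unimodal pulse per beat: a raised-cosine upstroke followed by an
#' exponential decay, peaking at `beat_time + pat_delay_s` (pulse arrival
#' delay), plus mild sensor noise.
#'
#' @param beats beat times in seconds.
#' @param duration_s session length in seconds.
#' @param profile a [subject_profile].
#' @param fs_hz sampling rate, default 100.
#' @param noise_sd PPG noise SD relative to unit pulse amplitude.
#' @return An oximeter [recording].
#' @export
render_ppg <- function(beats, duration_s, profile, fs_hz = 100,
                       noise_sd = 0.02) {
  n <- floor(duration_s * fs_hz)
  sig <- numeric(n)
  rise_s <- 0.12
  decay_s <- 0.18
  offs <- seq(-ceiling(rise_s * fs_hz), ceiling(0.45 * fs_hz))
  pulse <- function(tau) {
    ifelse(tau < 0,
           ifelse(tau > -rise_s, 0.5 * (1 + cos(pi * tau / rise_s)), 0),
           exp(-tau / decay_s))
  }
  for (tb in beats) {
    tpk <- tb + profile$pat_delay_s
    c0 <- round(tpk * fs_hz)
    idx <- c0 + offs + 1L
    ok <- idx >= 1L & idx <= n
    sig[idx[ok]] <- sig[idx[ok]] + pulse((idx[ok] - 1L) / fs_hz - tpk)
  }
  if (noise_sd > 0) {
    sig <- sig + with_local_seed(profile$seed + 3L,
                                 stats::rnorm(n, 0, noise_sd))
  }
  recording(profile$subject_id, "oximeter", fs_hz, 0, sig)
}

#' Generate a full synthetic session for one subject
#'
#' Beats, BCG with artifacts, PPG, and ground truth, all derived from the
#' profile's seed.
#'
#' @param profile a [subject_profile].
#' @param duration_s session length in seconds.
#' @return List with `profile`, `beats`, `belt` ([recording]), `ppg`
#'   ([recording]) and `artifact_spans`.
#' @export
generate_session <- function(profile, duration_s) {
  beats <- make_beat_times(profile, duration_s)
  belt <- render_bcg(beats, duration_s, profile)
  art <- inject_artifacts(belt, profile)
  ppg <- render_ppg(beats, duration_s, profile)
  list(profile = profile, beats = beats, belt = art$recording,
       ppg = ppg, artifact_spans = art$artifact_spans)
}

#' Generate a synthetic cohort
#'
#' Draws one profile per subject (mean HR uniform on 45-75 bpm, respiration
#' rate uniform on 0.2-0.4 Hz, other parameters at their defaults), derives
#' per-subject seeds deterministically from the cohort seed, and simulates
#' each session. When `out_dir` is given, belt and PPG streams are written as
#' packet files (belt 400-sample packets, oximeter 100-sample packets) with
#' ground-truth CSVs alongside.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param duration_s session length per subject, seconds. The field-trial
#'   scale is 24 subjects at about 7 h 12 min (25920 s); tests use shorter
#'   sessions.
#' @param seed cohort seed.
#' @param out_dir optional output directory; created if missing.
#' @param ... overrides passed to every [subject_profile] (e.g.
#'   `artifact_events_per_hour = 0` for a clean cohort).
#' @return List of per-subject sessions as from [generate_session].
#' @export
generate_cohort <- function(n_subjects, duration_s, seed = 1L,
                            out_dir = NULL, ...) {
  stopifnot(n_subjects >= 1)
  draws <- with_local_seed(seed, {
    list(mean_hr = stats::runif(n_subjects, 45, 75),
         resp_rate = stats::runif(n_subjects, 0.2, 0.4),
         sub_seed = sample.int(2^30, n_subjects))
  })
  sessions <- lapply(seq_len(n_subjects), function(i) {
    prof <- subject_profile(subject_id = sprintf("s%02d", i),
                            mean_hr_bpm = draws$mean_hr[i],
                            resp_rate_hz = draws$resp_rate[i],
                            seed = draws$sub_seed[i], ...)
    generate_session(prof, duration_s)
  })
  if (!is.null(out_dir)) write_cohort(sessions, out_dir)
  sessions
}

#' Write a cohort to disk in the packet interchange layout
#'
#' One directory per subject with `belt_0.json`, `ppg_0.json`, a
#' `manifest.json` carrying the subject id, and ground-truth CSVs
#' (`beats.csv`: subject_id, beat_time_s; `artifacts.csv`: subject_id,
#' artifact_start_s, artifact_end_s).
#'
#' @param sessions list of sessions from [generate_session].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(sessions, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sessions) {
    sdir <- file.path(out_dir, s$profile$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    belt_p <- frame_packets(s$belt$samples, s$belt$fs_hz, 400L,
                            s$belt$t0_ms, device_id = paste0("belt-", s$profile$subject_id),
                            device_kind = "belt")
    ppg_p <- frame_packets(s$ppg$samples, s$ppg$fs_hz, 100L,
                           s$ppg$t0_ms, device_id = paste0("po-", s$profile$subject_id),
                           device_kind = "oximeter")
    write_packets(belt_p, file.path(sdir, "belt_0.json"))
    write_packets(ppg_p, file.path(sdir, "ppg_0.json"))
    writeLines(jsonlite::toJSON(list(subject_id = s$profile$subject_id),
                                auto_unbox = TRUE),
               file.path(sdir, "manifest.json"))
    utils::write.csv(data.frame(subject_id = s$profile$subject_id,
                                beat_time_s = s$beats),
                     file.path(sdir, "beats.csv"), row.names = FALSE)
    n_art <- nrow(s$artifact_spans)
    utils::write.csv(data.frame(subject_id = rep(s$profile$subject_id, n_art),
                                artifact_start_s = s$artifact_spans[, 1],
                                artifact_end_s = s$artifact_spans[, 2]),
                     file.path(sdir, "artifacts.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}
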