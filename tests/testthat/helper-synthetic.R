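# shared fixture builders: everything is generated in code at test time

# a clean subject: no artifacts, optionally no noise/wander/jitter
clean_profile <- function(mean_hr = 60, seed = 1, noise_sd = 0,
                          wander = 0, jitter = 0, resp_amp = 0) {
  subject_profile(mean_hr_bpm = mean_hr, hr_wander_sd_bpm = wander,
                  ibi_jitter_sd_s = jitter, noise_sd = noise_sd,
                  resp_amp = resp_amp, artifact_events_per_hour = 0,
                  seed = seed)
}

# band-passed, segmented windows for a rendered session
prep_windows <- function(beats, duration_s, profile) {
  rec <- render_bcg(beats, duration_s, profile)
  segment(bandpass(rec))
}

# fraction of ground-truth beats matched by a detection within tol samples
beat_recall <- function(det_peaks, beat_times, fs = 50, tol = 3) {
  truth <- round(beat_times * fs) + 1
  mean(vapply(truth, function(ti) any(abs(det_peaks - ti) <= tol), logical(1)))
}
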