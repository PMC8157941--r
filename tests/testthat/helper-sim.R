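# Shared fixtures: short noise-free and mildly noisy simulated sessions.

noiseless <- list(ecg = 0, ppg = 0, accel = 0, doppler = 0, ehg = 0, temp = 0)

quiet_session <- function(duration_s = 60, seed = 7, ...) {
  simulate_session(scenario_config(duration_s = duration_s, seed = seed,
                                   noise = noiseless, ...))
}

# sensitivity / positive predictive value of detected vs true event times
match_rates <- function(detected_ms, truth_ms, tol_ms = 50) {
  sens <- mean(vapply(truth_ms, function(t) any(abs(detected_ms - t) <= tol_ms), logical(1)))
  ppv <- mean(vapply(detected_ms, function(t) any(abs(truth_ms - t) <= tol_ms), logical(1)))
  c(sensitivity = sens, ppv = ppv)
}
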