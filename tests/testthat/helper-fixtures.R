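# Small cohorts and beat tables built in code for the unit tests.

small_config <- function(seed = 42, n_patients = 8, duration_h = 4, ...) {
  sim_config(n_patients = n_patients, duration_mean_h = duration_h,
             duration_sd_h = 0, seed = seed, ...)
}

# deterministic beat table: constant IBIs with full quality, resting
flat_beats <- function(n = 100, ibi_ms = 1000, quality = 3L, t0 = 0) {
  data.frame(t_s = t0 + seq_len(n) * ibi_ms / 1000, ibi_ms = ibi_ms,
             quality = as.integer(quality),
             activity = factor("RESTING", levels = ACTIVITY_LEVELS))
}

# wrap a beats table as a minimal patient record
as_patient <- function(beats, duration_s, timeline = NULL, id = "T01") {
  if (is.null(timeline)) {
    timeline <- data.frame(start_s = 0, end_s = duration_s, rhythm = "SINUS")
  }
  structure(list(patient_id = id, recruitment_index = 1L, kind = "sinus",
                 duration_s = duration_s, samples = beats,
                 timeline = timeline, profile = NULL, meta = list()),
            class = "af_patient")
}

# toy labelled gaussian embeddings for head/knn tests
toy_embeddings <- function(n_per_class = 40, d = 8, sep = 4, sd = 1) {
  x <- rbind(matrix(rnorm(n_per_class * d, 0, sd), ncol = d),
             matrix(rnorm(n_per_class * d, sep, sd), ncol = d))
  list(z = x, y = rep(c(FALSE, TRUE), each = n_per_class))
}
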