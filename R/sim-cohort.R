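#' Generate a synthetic patient cohort
#'
#' Draws a full cohort of per-patient IBI streams with ground-truth rhythm
#' timelines, quality scores and activity profiles. Patient rhythm kinds
#' (sinus-only, persistent AF, paroxysmal AF, flutter) are allocated by
#' largest-remainder rounding of `config$rhythm_mix` and shuffled over
#' recruitment order, so both ends of a recruitment-ordered split contain all
#' rhythm classes. The whole cohort is reproducible from `config$seed`.
#'
#' @param config A simulation configuration from [sim_config()].
#'
#' @return An object of class `af_cohort`: a list of `af_patient` records,
#'   each holding `patient_id`, `recruitment_index` (generation order, the
#'   key for recruitment-ordered splits), `kind`, `duration_s`, `samples`
#'   (data.frame `t_s`, `ibi_ms`, `quality`, `activity`), `timeline`
#'   (data.frame `start_s`, `end_s`, `rhythm`) and `meta`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 2, duration_mean_h = 1,
#'                                      duration_sd_h = 0, seed = 7))
#' sapply(cohort, function(p) p$kind)
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "af_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients

  counts <- largest_remainder(config$rhythm_mix, n)
  n_parox <- floor(config$prop_paroxysmal * counts[["af"]] + 0.5)
  kinds <- c(rep("sinus", counts[["sinus"]]),
             rep("af_persistent", counts[["af"]] - n_parox),
             rep("af_paroxysmal", n_parox),
             rep("flutter", counts[["flutter"]]))
  kinds <- kinds[sample.int(n)]

  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    cohort[[i]] <- generate_patient(
      patient_id = sprintf("P%03d", i), recruitment_index = i,
      kind = kinds[i], config = config
    )
  }
  structure(cohort, class = "af_cohort", config = config)
}

# Largest-remainder (Hare) allocation of n units to proportions p.
largest_remainder <- function(p, n) {
  exact <- p * n
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    add <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

generate_patient <- function(patient_id, recruitment_index, kind, config) {
  dur_h <- min(26, max(8, rnorm(1, config$duration_mean_h, config$duration_sd_h)))
  duration_s <- dur_h * 3600

  sinus_rr <- min(1200, max(500, rnorm(1, config$sinus$mean_rr_ms,
                                       config$sinus$mean_rr_sd_ms)))
  af_rr <- min(1100, max(450, rnorm(1, config$af$mean_rr_ms,
                                    config$af$mean_rr_sd_ms)))

  timeline <- generate_rhythm_timeline(duration_s, kind, config$bouts)

  seg_beats <- vector("list", nrow(timeline))
  for (k in seq_len(nrow(timeline))) {
    seg <- timeline[k, ]
    seg_dur <- seg$end_s - seg$start_s
    if (seg_dur < 1) next
    b <- switch(as.character(seg$rhythm),
      SINUS = generate_sinus_ibis(seg_dur, mean_rr_ms = sinus_rr,
                                  rsa_amp_ms = config$sinus$rsa_amp_ms,
                                  rsa_freq_hz = config$sinus$rsa_freq_hz,
                                  jitter_sd_ms = config$sinus$jitter_sd_ms),
      AF = generate_af_ibis(seg_dur, mean_rr_ms = af_rr, cv = config$af$cv),
      FLUTTER = generate_flutter_ibis(
        seg_dur, atrial_cycle_ms = config$flutter$atrial_cycle_ms,
        ratios = config$flutter$ratios,
        switch_rate_per_h = config$flutter$switch_rate_per_h,
        jitter_sd_ms = config$flutter$jitter_sd_ms
      )
    )
    attr(b, "ratio_segments") <- NULL
    b$t_s <- b$t_s + seg$start_s
    seg_beats[[k]] <- b
  }
  beats <- do.call(rbind, seg_beats)
  rownames(beats) <- NULL

  profile <- generate_activity_profile(duration_s, config$activity)
  samples <- apply_quality_model(beats, profile, config$quality)

  structure(list(
    patient_id = patient_id, recruitment_index = recruitment_index,
    kind = kind, duration_s = duration_s, samples = samples,
    timeline = timeline, profile = profile,
    meta = list(frailty = attr(samples, "frailty"),
                sinus_mean_rr_ms = sinus_rr, af_mean_rr_ms = af_rr)
  ), class = "af_patient")
}

#' @export
print.af_cohort <- function(x, ...) {
  kinds <- table(vapply(x, `[[`, "", "kind"))
  cat(sprintf("af_cohort: %d patients (%s)\n", length(x),
              paste(names(kinds), kinds, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Cohort manifest table
#'
#' One row per patient with the identifiers needed for recruitment-ordered
#' splitting and bookkeeping.
#'
#' @param cohort An `af_cohort`.
#' @return A data.frame (`patient_id`, `recruitment_index`, `kind`,
#'   `duration_s`).
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "af_cohort"))
  data.frame(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    recruitment_index = vapply(cohort, `[[`, 0L, "recruitment_index"),
    kind = vapply(cohort, `[[`, "", "kind"),
    duration_s = vapply(cohort, `[[`, 0, "duration_s")
  )
}

#' Serialize / read a cohort as plain-text files
#'
#' `write_cohort()` writes a JSON manifest plus, per patient, an IBI stream
#' CSV (`t_s`, `ibi_ms`, `quality`, `activity`) and a timeline CSV
#' (`start_s`, `end_s`, `rhythm`), all UTF-8 with `.` decimal separator.
#' `read_cohort()` reconstructs the `af_cohort` from such a directory.
#' Output is deterministic: identical cohorts serialize to identical bytes.
#'
#' @param cohort An `af_cohort`.
#' @param dir Target/source directory.
#' @return `write_cohort()` returns the manifest path invisibly;
#'   `read_cohort()` returns an `af_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "af_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  config <- attr(cohort, "config")
  entries <- lapply(cohort, function(p) {
    ibi_file <- sprintf("%s_ibi.csv", p$patient_id)
    tl_file <- sprintf("%s_timeline.csv", p$patient_id)
    data.table::fwrite(p$samples, file.path(dir, ibi_file))
    data.table::fwrite(p$timeline, file.path(dir, tl_file))
    list(patient_id = p$patient_id, recruitment_index = p$recruitment_index,
         kind = p$kind, duration_s = p$duration_s,
         ibi_file = ibi_file, timeline_file = tl_file)
  })
  manifest <- list(seed = config$seed, n_patients = config$n_patients,
                   patients = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cohort <- lapply(manifest$patients, function(e) {
    samples <- as.data.frame(data.table::fread(file.path(dir, e$ibi_file)))
    samples$activity <- factor(samples$activity, levels = ACTIVITY_LEVELS)
    timeline <- as.data.frame(data.table::fread(file.path(dir, e$timeline_file)))
    structure(list(
      patient_id = e$patient_id, recruitment_index = e$recruitment_index,
      kind = e$kind, duration_s = e$duration_s, samples = samples,
      timeline = timeline, profile = NULL, meta = list()
    ), class = "af_patient")
  })
  structure(cohort, class = "af_cohort")
}
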