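# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All phantom randomness flows through this helper so a
# master seed determines every draw.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# child seed for subject `index` under `master_seed`; documented derivation
# so cohorts are reproducible subject by subject
subject_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(index)) %% 2147483647)
}

#' Phantom signal model
#'
#' Describes how regional tracer signal grows with amyloid burden in the
#' phantom. Every region has a baseline uptake (in SUVR-like units), an
#' onset phase at which specific signal starts accumulating, and a slope
#' per phase step. Cortical regions (the five composite-VOI regions plus
#' precuneus) onset at phase 1; the caudate onsets at phase 3, so striatal
#' signal discriminates the advanced phases; the cerebellar grey matter and
#' pons never accumulate specific signal and serve as reference regions.
#' White matter carries high nonspecific retention. On top of the phase
#' signal, a neuritic coupling term adds signal proportional to the
#' subject's maximal regional CERAD plaque density, and two subject-level
#' random effects (a log-normal amplitude multiplier on the specific signal
#' and an additive per-region shift) emulate between-subject biological
#' variability, which is what keeps synthetic cohorts from being perfectly
#' separable. Voxel noise is added before smoothing to mimic spatially
#' correlated PET noise.
#'
#' @param baseline Named numeric vector of per-region baseline uptake; any
#'   region not named keeps the default.
#' @param slope_cortical SUVR per phase step in cortical regions (>= 0).
#' @param slope_caudate SUVR per phase step in the caudate from its onset
#'   (>= 0).
#' @param coupling Extra SUVR per unit of maximal regional CERAD density in
#'   signal regions (>= 0).
#' @param noise_sd Voxelwise Gaussian noise SD (SUVR units), added before
#'   smoothing.
#' @param fwhm Gaussian smoothing FWHM in mm applied to the final volume.
#' @param subject_amplitude_sd SD of the log-normal subject amplitude
#'   multiplier on the specific signal.
#' @param region_effect_sd SD of the additive per-subject, per-region shift
#'   in signal regions (SUVR units).
#' @return An object of class `signal_model`.
#' @export
signal_model <- function(baseline = NULL,
                         slope_cortical = 0.22,
                         slope_caudate = 0.45,
                         coupling = 0.15,
                         noise_sd = 0.25,
                         fwhm = 5,
                         subject_amplitude_sd = 0.35,
                         region_effect_sd = 0.08) {
  regions <- phantom_regions()
  base <- c(frontal = 1.0, parietal = 1.0, anterior_cingulate = 1.0,
            posterior_cingulate = 1.0, lateral_temporal = 1.0,
            precuneus = 1.0, caudate = 1.0, cerebellar_gm = 1.0,
            pons = 2.8, white_matter = 1.6)
  if (!is.null(baseline)) {
    unknown <- setdiff(names(baseline), regions)
    if (length(unknown)) stop("unknown region(s) in baseline: ",
                              paste(unknown, collapse = ", "))
    base[names(baseline)] <- baseline
  }
  if (slope_cortical < 0 || slope_caudate < 0 || coupling < 0) {
    stop("signal slopes and coupling must be non-negative")
  }
  if (noise_sd < 0 || fwhm < 0 || subject_amplitude_sd < 0 || region_effect_sd < 0) {
    stop("noise, smoothing and random-effect parameters must be non-negative")
  }
  cortical <- c(composite_regions(), "precuneus")
  onset <- stats::setNames(rep(Inf, length(regions)), regions)
  onset[cortical] <- 1
  onset["caudate"] <- 3
  slope <- stats::setNames(rep(0, length(regions)), regions)
  slope[cortical] <- slope_cortical
  slope["caudate"] <- slope_caudate
  structure(
    list(baseline = base, onset = onset, slope = slope, coupling = coupling,
         noise_sd = noise_sd, fwhm = fwhm,
         subject_amplitude_sd = subject_amplitude_sd,
         region_effect_sd = region_effect_sd),
    class = "signal_model"
  )
}

#' Per-subject phantom metadata
#'
#' @param id Subject identifier.
#' @param amyloid_phase Integer 0-5 hierarchical amyloid phase.
#' @param cerad_regional_densities Named numeric vector of mean neuritic
#'   plaque density scores on the 0-3 scale for the five composite cortical
#'   regions.
#' @param cohort Cohort tag, `"end_of_life_like"` or `"asymptomatic_like"`.
#' @param seed Integer child seed driving all of this subject's randomness.
#' @param burden Optional continuous amyloid burden on the 0-5 phase scale;
#'   used by the asymptomatic cohort so intermediate signal levels exist.
#'   Defaults to `amyloid_phase`.
#' @return An object of class `subject_record`; the Bielschowsky class
#'   (`bss_class`) is derived as `"abnormal"` iff any regional density
#'   exceeds 1.5.
#' @export
subject_record <- function(id, amyloid_phase, cerad_regional_densities,
                           cohort = c("end_of_life_like", "asymptomatic_like"),
                           seed = 1L, burden = NULL) {
  cohort <- match.arg(cohort)
  if (!(amyloid_phase %in% 0:5)) stop("`amyloid_phase` must be an integer in 0..5")
  d <- as.numeric(cerad_regional_densities)
  if (length(d) == 0) stop("`cerad_regional_densities` must be non-empty")
  if (any(d < 0 | d > 3)) stop("regional densities must lie in [0, 3]")
  structure(
    list(id = as.character(id), amyloid_phase = as.integer(amyloid_phase),
         cerad_regional_densities = cerad_regional_densities,
         bss_class = if (max(d) > 1.5) "abnormal" else "normal",
         cohort = cohort, seed = as.integer(seed),
         burden = if (is.null(burden)) as.numeric(amyloid_phase) else as.numeric(burden)),
    class = "subject_record"
  )
}

# noiseless regional means implied by the model for a given subject:
# baseline + amplitude * (phase signal + neuritic coupling), before the
# per-region random effect and voxel noise
regional_means <- function(record, model, amplitude = 1) {
  b <- record$burden
  dmax <- max(as.numeric(record$cerad_regional_densities))
  signal <- model$slope * pmax(0, b - model$onset + 1)
  has_signal <- is.finite(model$onset)
  signal[has_signal] <- signal[has_signal] + model$coupling * dmax
  model$baseline + amplitude * signal
}

#' Simulate one phantom SUVR-like image
#'
#' Builds the subject's raw volume as regional mean + subject random
#' effects + voxel noise, then smooths with the model's Gaussian FWHM
#' (noise before smoothing). All randomness comes from `record$seed`, so
#' the image is bit-reproducible.
#'
#' @param atlas A [generate_atlas()] phantom atlas.
#' @param record A [subject_record()].
#' @param model A [signal_model()].
#' @return A [voxel_image] whose brain mask is the atlas non-background
#'   mask.
#' @export
simulate_subject <- function(atlas, record, model) {
  stopifnot(inherits(atlas, "phantom_atlas"), inherits(record, "subject_record"),
            inherits(model, "signal_model"))
  with_seed(record$seed, {
    amplitude <- exp(stats::rnorm(1, 0, model$subject_amplitude_sd))
    mu <- regional_means(record, model, amplitude)
    has_signal <- is.finite(model$onset)
    mu[has_signal] <- mu[has_signal] +
      stats::rnorm(sum(has_signal), 0, model$region_effect_sd)
    vals <- array(0, dim(atlas$labels))
    inside <- atlas$labels > 0L
    vals[inside] <- mu[atlas$region_table$name[atlas$labels[inside]]]
    if (model$noise_sd > 0) {
      vals[inside] <- vals[inside] + stats::rnorm(sum(inside), 0, model$noise_sd)
    }
    img <- voxel_image(vals, atlas$spacing, inside)
    smooth_gaussian(img, model$fwhm)
  })
}

#' Cohort compositions
#'
#' `table1_composition()` is the end-of-life-like composition: the
#' cross-classification of Bielschowsky status by amyloid phase with 29
#' BSS-negative and 72 BSS-positive cases, 22 cases at phases 0-2 and 79 at
#' phases 3-5, including the 7 discordant BSS-negative cases at phases 3-5.
#' `asymptomatic_composition()` describes a cognitively intact cohort whose
#' continuous amyloid burden is drawn from a right-skewed mixture: a
#' majority low-burden component and a minority elevated component, so
#' intermediate cases exist.
#'
#' @param n_negative,n_positive Integer vectors of per-phase counts
#'   (phases 0-5) for BSS-negative and BSS-positive cases.
#' @return An object of class `cohort_composition`.
#' @export
table1_composition <- function(n_negative = c(7, 10, 5, 5, 1, 1),
                               n_positive = c(0, 0, 0, 14, 21, 37)) {
  if (length(n_negative) != 6L || length(n_positive) != 6L ||
      any(n_negative < 0) || any(n_positive < 0)) {
    stop("validation error: per-phase counts must be six non-negative integers")
  }
  if (any(n_positive[1:3] > 0)) {
    stop("validation error: BSS-abnormal cases cannot occur at phases 0-2")
  }
  structure(
    list(kind = "end_of_life_like",
         cells = data.frame(phase = rep(0:5, 2),
                            bss = rep(c("normal", "abnormal"), each = 6),
                            n = c(n_negative, n_positive))),
    class = "cohort_composition"
  )
}

#' @rdname table1_composition
#' @param n Number of asymptomatic-like subjects.
#' @param prop_elevated Probability that a subject comes from the elevated-
#'   burden mixture component.
#' @param low_mean Mean of the (exponential) low-burden component on the
#'   0-5 phase scale.
#' @param elevated_mean,elevated_sd Mean and SD of the (Gaussian, clipped to
#'   0-5) elevated-burden component.
#' @export
asymptomatic_composition <- function(n = 180, prop_elevated = 0.3,
                                     low_mean = 0.7, elevated_mean = 3.3,
                                     elevated_sd = 0.9) {
  if (n < 0) stop("validation error: n must be non-negative")
  structure(
    list(kind = "asymptomatic_like", n = as.integer(n),
         prop_elevated = prop_elevated, low_mean = low_mean,
         elevated_mean = elevated_mean, elevated_sd = elevated_sd),
    class = "cohort_composition"
  )
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# draw the five cortical CERAD densities for one subject, consistent with
# the requested Bielschowsky class (class membership is enforced, the
# phase shifts the distribution upward)
draw_densities <- function(phase, bss) {
  regions <- composite_regions()
  if (bss == "normal") {
    d <- clip(stats::rnorm(5, 0.25 + 0.18 * phase, 0.35), 0, 1.5)
  } else {
    d <- clip(stats::rnorm(5, 1.1 + 0.28 * (phase - 1), 0.5), 0, 3)
    if (max(d) <= 1.5) {
      d[which.max(d)] <- stats::runif(1, 1.6, clip(1.3 + 0.35 * phase, 1.7, 3))
    }
  }
  stats::setNames(round(d, 3), regions)
}

#' Generate a synthetic cohort
#'
#' Expands a composition into subject records and simulates one image per
#' subject. The full cohort is a pure function of (atlas, composition,
#' model, master_seed): subject `i` draws everything from the child seed
#' `(master_seed + 7919 * i) mod (2^31 - 1)`.
#'
#' @param atlas A phantom atlas.
#' @param composition A [table1_composition()] or
#'   [asymptomatic_composition()] (or the strings `"table1"` /
#'   `"asymptomatic"` for the defaults).
#' @param model A [signal_model()].
#' @param master_seed Integer master seed.
#' @return An object of class `phantom_cohort`: list with `atlas`, `model`,
#'   `subjects` (list of [subject_record()]), `images` (list of
#'   [voxel_image]), and `master_seed`.
#' @export
generate_cohort <- function(atlas, composition, model = signal_model(),
                            master_seed = 1L) {
  if (is.character(composition)) {
    composition <- switch(match.arg(composition, c("table1", "asymptomatic")),
                          table1 = table1_composition(),
                          asymptomatic = asymptomatic_composition())
  }
  stopifnot(inherits(atlas, "phantom_atlas"),
            inherits(composition, "cohort_composition"),
            inherits(model, "signal_model"))
  subjects <- list()
  if (composition$kind == "end_of_life_like") {
    cells <- composition$cells[composition$cells$n > 0, , drop = FALSE]
    idx <- 0L
    for (k in seq_len(nrow(cells))) {
      for (j in seq_len(cells$n[k])) {
        idx <- idx + 1L
        seed <- subject_seed(master_seed, idx)
        rec <- with_seed(seed, {
          subject_record(
            id = sprintf("eol%03d", idx),
            amyloid_phase = cells$phase[k],
            cerad_regional_densities = draw_densities(cells$phase[k], cells$bss[k]),
            cohort = "end_of_life_like", seed = seed
          )
        })
        stopifnot(rec$bss_class == cells$bss[k])  # enforced by construction
        subjects[[idx]] <- rec
      }
    }
  } else {
    for (idx in seq_len(composition$n)) {
      seed <- subject_seed(master_seed, idx)
      subjects[[idx]] <- with_seed(seed, {
        elevated <- stats::runif(1) < composition$prop_elevated
        burden <- if (elevated) {
          clip(stats::rnorm(1, composition$elevated_mean, composition$elevated_sd), 0, 5)
        } else {
          clip(stats::rexp(1, rate = 1 / composition$low_mean), 0, 5)
        }
        dens <- clip(stats::rnorm(5, pmax(0, 0.55 * (burden - 1.5)), 0.4), 0, 3)
        subject_record(
          id = sprintf("asym%03d", idx),
          amyloid_phase = min(5L, as.integer(floor(burden))),
          cerad_regional_densities = stats::setNames(round(dens, 3), composite_regions()),
          cohort = "asymptomatic_like", seed = seed, burden = burden
        )
      })
    }
  }
  images <- lapply(subjects, function(rec) simulate_subject(atlas, rec, model))
  structure(
    list(atlas = atlas, model = model, subjects = subjects, images = images,
         master_seed = as.integer(master_seed)),
    class = "phantom_cohort"
  )
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$subjects), " subjects (",
      if (length(x$subjects)) x$subjects[[1]]$cohort else "empty",
      "), master seed ", x$master_seed, "\n", sep = "")
  invisible(x)
}

#' Subject table of a cohort
#'
#' @param cohort A `phantom_cohort`.
#' @return A data.frame with columns id, cohort, amyloid_phase, cerad_max,
#'   bss_class, seed (the on-disk CSV schema).
#' @export
subject_table <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(id = s$id, cohort = s$cohort, amyloid_phase = s$amyloid_phase,
               cerad_max = max(as.numeric(s$cerad_regional_densities)),
               bss_class = s$bss_class, seed = s$seed,
               stringsAsFactors = FALSE)
  }))
}

#' Write a cohort to disk
#'
#' Writes the subject table as CSV and each image as NIfTI under `dir`.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- subject_table(cohort)
  utils::write.csv(tab, file.path(dir, "subjects.csv"), row.names = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  for (i in seq_along(cohort$images)) {
    write_voxel_image(cohort$images[[i]],
                      file.path(dir, paste0(tab$id[i], ".nii.gz")))
  }
  invisible(dir)
}
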