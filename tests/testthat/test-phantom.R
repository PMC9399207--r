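test_that("the atlas places every region exactly once, deterministically", {
  atlas <- generate_atlas(c(40, 48, 40), 4)
  expect_setequal(sort(unique(as.vector(atlas$labels))), 0:10)
  expect_true(all(atlas$region_table$n_voxels > 0))
  # label volume is single-valued by construction; counts are consistent
  expect_equal(sum(atlas$region_table$n_voxels), sum(atlas$labels > 0))
  expect_identical(atlas$labels, generate_atlas(c(40, 48, 40), 4)$labels)
  expect_error(generate_atlas(c(8, 8, 8)), "configuration error")
  # smallest supported grid still carries all regions
  tiny <- generate_atlas(c(16, 16, 16), 6)
  expect_setequal(sort(unique(as.vector(tiny$labels))), 0:10)
})

test_that("reference regions are disjoint from the cortical compartment", {
  atlas <- small_atlas()
  refs <- region_mask(atlas, c("cerebellar_gm", "pons"))
  cortex <- region_mask(atlas, c(composite_regions(), "precuneus", "caudate"))
  expect_false(any(refs & cortex))
  for (r in composite_regions()) expect_gt(sum(region_mask(atlas, r)), 0)
  expect_error(region_mask(atlas, "hippocampus"), "unknown region")
})

test_that("subject records derive the Bielschowsky class from densities", {
  rec <- subject_record("s1", 3, c(a = 0.2, b = 1.6, c = 0), seed = 1)
  expect_equal(rec$bss_class, "abnormal")
  rec2 <- subject_record("s2", 2, rep(1.5, 5), seed = 1)
  expect_equal(rec2$bss_class, "normal")  # strict > 1.5
  expect_error(subject_record("s3", 7, c(1, 1)), "0..5")
  expect_error(subject_record("s4", 1, c(1, 3.2)), "\\[0, 3\\]")
})

test_that("noiseless simulation reproduces the regional means exactly", {
  atlas <- small_atlas()
  model <- noiseless_model(fwhm = 0)
  rec0 <- subject_record("p0", 0, rep(0, 5), seed = 3)
  img0 <- simulate_subject(atlas, rec0, model)
  for (r in c("frontal", "caudate", "pons", "white_matter", "cerebellar_gm")) {
    vals <- img0$values[region_mask(atlas, r)]
    expect_equal(vals, rep(model$baseline[[r]], length(vals)))
  }
  # phase 5 strictly exceeds phase 0 in the cortex, references untouched
  rec5 <- subject_record("p5", 5, rep(0, 5), seed = 3)
  img5 <- simulate_subject(atlas, rec5, model)
  cortex <- region_mask(atlas, composite_regions())
  expect_gt(masked_mean(img5, cortex), masked_mean(img0, cortex))
  expect_equal(masked_mean(img5, region_mask(atlas, "cerebellar_gm")), 1.0)
  expect_equal(masked_mean(img5, region_mask(atlas, "pons")),
               model$baseline[["pons"]])
})

test_that("noisy replicate means converge to the smoothed noiseless prediction", {
  atlas <- small_atlas()
  model <- signal_model(noise_sd = 0.1, subject_amplitude_sd = 0,
                        region_effect_sd = 0)
  caudate <- region_mask(atlas, "caudate")
  # closed-form oracle: expectation is linear, so the expected caudate mean
  # is the smoothed noiseless image's caudate mean
  rec <- subject_record("c", 3, rep(1, 5), seed = 1)
  noiseless <- simulate_subject(atlas, rec, noiseless_model())
  predicted <- masked_mean(noiseless, caudate)
  reps <- vapply(1:200, function(s) {
    r <- subject_record("c", 3, rep(1, 5), seed = 1000 + s)
    masked_mean(simulate_subject(atlas, r, model), caudate)
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - predicted), 3 * se + 1e-12)
})

test_that("the end-of-life-like composition reproduces the cross-table exactly", {
  tab <- label_cohort(small_eol_cohort())
  expect_equal(nrow(tab), 101)
  expect_equal(sum(tab$bss_label == "normal"), 29)
  expect_equal(sum(tab$bss_label == "abnormal"), 72)
  expect_equal(sum(tab$phase_label == "low"), 22)
  expect_equal(sum(tab$phase_label == "high"), 79)
  expect_equal(sum(tab$bss_label == "normal" & tab$phase_label == "high"), 7)
  # per-cell conservation against the requested composition
  comp <- table1_composition()
  got <- as.data.frame(table(phase = tab$amyloid_phase, bss = tab$bss_label))
  for (k in seq_len(nrow(comp$cells))) {
    cell <- comp$cells[k, ]
    expect_equal(sum(tab$amyloid_phase == cell$phase &
                       tab$bss_label == cell$bss), cell$n)
  }
})

test_that("compositions validate and empty compositions give empty cohorts", {
  expect_error(table1_composition(n_positive = c(1, 0, 0, 14, 21, 37)),
               "phases 0-2")
  expect_error(table1_composition(n_negative = rep(-1, 6)), "non-negative")
  atlas <- small_atlas()
  empty <- generate_cohort(atlas, table1_composition(rep(0, 6), rep(0, 6)),
                           signal_model(), 1)
  expect_length(empty$subjects, 0)
  empty2 <- generate_cohort(atlas, asymptomatic_composition(n = 0),
                            signal_model(), 1)
  expect_length(empty2$subjects, 0)
})

test_that("cohort generation is bit-deterministic in the master seed", {
  atlas <- small_atlas()
  model <- signal_model()
  comp <- table1_composition(c(2, 1, 1, 1, 0, 0), c(0, 0, 0, 2, 1, 1))
  a <- generate_cohort(atlas, comp, model, master_seed = 123)
  b <- generate_cohort(atlas, comp, model, master_seed = 123)
  expect_identical(lapply(a$images, `[[`, "values"),
                   lapply(b$images, `[[`, "values"))
  expect_identical(subject_table(a), subject_table(b))
  c2 <- generate_cohort(atlas, comp, model, master_seed = 124)
  expect_false(identical(a$images[[1]]$values, c2$images[[1]]$values))
})

test_that("noiseless composite SUVR grows with phase and with plaque density", {
  atlas <- small_atlas()
  model <- noiseless_model()
  suvr_of <- function(rec) {
    img <- simulate_subject(atlas, rec, model)
    composite_suvr(compute_suvr(img, region_mask(atlas, "cerebellar_gm")), atlas)
  }
  by_phase <- vapply(0:5, function(p) {
    suvr_of(subject_record("m", p, rep(0, 5), seed = 1))
  }, numeric(1))
  expect_true(all(diff(by_phase) >= 0))
  # coupling: equal phase, higher max density, strictly higher signal
  lo <- suvr_of(subject_record("d1", 3, rep(0.5, 5), seed = 1))
  hi <- suvr_of(subject_record("d2", 3, c(0.5, 0.5, 0.5, 0.5, 2.5), seed = 1))
  expect_gt(hi, lo)
})

test_that("the asymptomatic-like cohort spans a continuum with a low-burden majority", {
  atlas <- small_atlas()
  coh <- generate_cohort(atlas, asymptomatic_composition(n = 120),
                         signal_model(), master_seed = 31)
  burdens <- vapply(coh$subjects, `[[`, numeric(1), "burden")
  expect_equal(length(burdens), 120)
  expect_gt(mean(burdens < 1.5), 0.5)          # majority low
  expect_gt(sum(burdens > 2.5), 10)            # elevated minority exists
  expect_gt(sum(burdens >= 1 & burdens <= 3), 5)  # intermediates exist
  tab <- subject_table(coh)
  expect_true(all(tab$cohort == "asymptomatic_like"))
})
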