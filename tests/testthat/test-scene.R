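test_that("scene generation is seed-deterministic and structurally correct", {
  spec <- small_spec(n_plants = 4L)
  f1 <- build_scene(spec, seed = 3)
  f2 <- build_scene(spec, seed = 3)
  expect_identical(f1, f2)
  f3 <- build_scene(spec, seed = 4)
  expect_false(identical(f1$footprint, f3$footprint))

  # one connected group per plant
  comps <- max(EBImage::bwlabel(f1$footprint * 1))
  expect_equal(as.numeric(comps), 4)

  # healthy presets are exact before noise
  fp <- f1$footprint
  expect_identical(mean(f1$phi_max[fp]), 0.80)
  expect_identical(mean(f1$phi_op[fp]), 0.40)
  expect_equal(mean(2 * f1$chroma[fp]), 1.6)
  # off-footprint fields are zero
  expect_true(all(f1$phi_max[!fp] == 0))
  expect_true(all(f1$chroma[!fp] == 0))
  # both leaf-age classes are present
  expect_setequal(unique(as.vector(f1$age[fp])), c(1L, 2L))
})

test_that("invalid scene specifications are rejected", {
  expect_error(scene_spec(n_plants = 0), class = "fluoroscan_invalid_spec")
  expect_error(scene_spec(leaves_per_plant = 0),
               class = "fluoroscan_invalid_spec")
  expect_error(scene_spec(image_height = -5))
})

test_that("drought lowers PhiPSII first, leaving Fv/Fm for the severe stage", {
  f <- healthy_field(seed = 2)
  model <- stress_model("drought", severity_trajectory = seq(0, 1, length.out = 9))
  # severity 0.5 (day 5 of the linear ramp)
  mid <- apply_stress(f, model, day = 5)
  fp <- f$footprint
  expect_lt(mean(mid$phi_op[fp]), mean(f$phi_op[fp]))
  expect_lt(abs(mean(mid$phi_max[fp]) - mean(f$phi_max[fp])), 0.02)
  # at full severity all three have declined
  late <- apply_stress(f, model, day = 9)
  expect_lt(mean(late$phi_max[fp]), 0.75)
  expect_lt(mean(2 * late$chroma[fp]), 1.5)
  expect_equal(mean(late$phi_op[fp]), 0.25, tolerance = 1e-10)
})

test_that("nitrogen deficiency raises Fv/Fm heterogeneity via the old-leaf lead", {
  f <- healthy_field(seed = 2)
  model <- stress_model("nitrogen_deficiency",
                        severity_trajectory = seq(0, 1, length.out = 9))
  fp <- f$footprint
  sd0 <- sd(f$phi_max[fp])
  # severity 0.625 (day 6 of the linear ramp)
  d6 <- apply_stress(f, model, day = 6)
  expect_gt(sd(d6$phi_max[fp]), sd0)
  # old leaves are ahead of new leaves
  expect_lt(mean(d6$phi_max[fp & f$age == 1L]),
            mean(d6$phi_max[fp & f$age == 2L]))
})

test_that("disease carves lesions where all indicators collapse together", {
  f <- healthy_field(seed = 2)
  model <- stress_model("disease")
  d4 <- apply_stress(f, model, day = 4)
  fp <- f$footprint
  lesion <- fp & d4$phi_max < f$phi_max
  expect_gt(sum(lesion), 0)
  expect_equal(d4$phi_max[lesion], 0.3 * f$phi_max[lesion])
  expect_equal(d4$phi_op[lesion], 0.3 * f$phi_op[lesion])
  expect_equal(d4$chroma[lesion], 0.3 * f$chroma[lesion])
  # untouched tissue is untouched
  expect_identical(d4$phi_max[fp & !lesion], f$phi_max[fp & !lesion])
})

test_that("no-stress model is the identity and bad days error", {
  f <- healthy_field(seed = 6)
  model <- stress_model("none")
  expect_identical(apply_stress(f, model, 5), f)
  expect_error(apply_stress(f, model, 10), "within")
  expect_error(stress_model("drought", n_days = 3,
                            severity_trajectory = c(0.5, 0.2, 0.9)),
               "non-decreasing")
})

test_that("footprint-mean PhiPSII is non-increasing in severity for every stress type", {
  f <- healthy_field(seed = 8)
  fp <- f$footprint
  for (stress in c("drought", "nitrogen_deficiency", "disease")) {
    model <- stress_model(stress)
    means <- vapply(1:9, function(d) {
      mean(apply_stress(f, model, d)$phi_op[fp])
    }, numeric(1))
    expect_true(all(diff(means) <= 1e-12), label = stress)
  }
})

test_that("generated day series have monotone stress and stable controls", {
  spec <- small_spec()
  ds <- generate_dataset(spec, stress_model("drought"), imaging_model(),
                         seed = 11)
  phi_means <- vapply(seq_along(ds$days), function(i) {
    mean(ds$truth[[i]]$phi_op[ds$truth[[i]]$footprint])
  }, numeric(1))
  expect_true(all(diff(phi_means) <= 1e-12))

  ctrl <- generate_dataset(spec, stress_model("none"), imaging_model(),
                           seed = 11)
  fvfm_means <- vapply(seq_along(ctrl$days), function(i) {
    maps <- compute_indicator_maps(ctrl$stacks[[i]],
                                   truth_mask(ctrl$truth[[i]]))
    summarize_map(maps$fvfm)$mean
  }, numeric(1))
  expect_lt(max(fvfm_means) - min(fvfm_means), 0.01)

  expect_error(generate_dataset(spec, stress_model("none"),
                                imaging_model(), days = integer(0)),
               "non-empty")
})

test_that("written datasets are byte-identical under the same seed", {
  spec <- scene_spec(image_height = 80, image_width = 100, n_plants = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(spec, stress_model("none", n_days = 2), imaging_model(),
                   days = 1:2, seed = 5, out_dir = d1)
  generate_dataset(spec, stress_model("none", n_days = 2), imaging_model(),
                   days = 1:2, seed = 5, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  }
})
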