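# Hand-built tidy trajectory: one row per indicator per day.
make_traj <- function(days, fvfm, phipsii, ratio, fvfm_std = 0.02) {
  dplyr::bind_rows(
    tibble::tibble(day = days, indicator = "fvfm", mean = fvfm,
                   std = fvfm_std),
    tibble::tibble(day = days, indicator = "phipsii", mean = phipsii,
                   std = 0.02),
    tibble::tibble(day = days, indicator = "r550_510", mean = ratio,
                   std = 0.05)
  )
}

test_that("snapshot flags fire exactly at the published bounds", {
  expect_equal(unlist(assess_snapshot(0.80, 0.40, 1.6)),
               c(phipsii_stressed = FALSE, fvfm_affected = FALSE,
                 ratio_abnormal = FALSE))
  expect_equal(unlist(assess_snapshot(0.80, 0.29, 1.6)),
               c(phipsii_stressed = TRUE, fvfm_affected = FALSE,
                 ratio_abnormal = FALSE))
  expect_equal(unlist(assess_snapshot(0.74, 0.40, 1.6)),
               c(phipsii_stressed = FALSE, fvfm_affected = TRUE,
                 ratio_abnormal = FALSE))
  expect_error(assess_snapshot(NA, 0.4, 1.6), "finite")
})

test_that("snapshot flags are monotone in the indicator means", {
  base <- assess_snapshot(0.76, 0.31, 1.55)
  lower <- assess_snapshot(0.70, 0.25, 1.30)
  for (k in names(base)) {
    expect_true(!base[[k]] || lower[[k]], label = k)
  }
})

test_that("patchiness scores empty, full and random impairment correctly", {
  healthy <- compute_fvfm(matrix(600, 20, 20), matrix(3000, 20, 20),
                          matrix(TRUE, 20, 20))
  expect_equal(patchiness_score(healthy, 0.35), 0)

  dead <- compute_fvfm(matrix(2700, 20, 20), matrix(3000, 20, 20),
                       matrix(TRUE, 20, 20))
  expect_equal(patchiness_score(dead, 0.35), 1)

  # spatially independent impairment at density p scores ~ p
  scores <- vapply(1:20, function(seed) {
    set.seed(seed)
    vals <- matrix(0.8, 40, 40)
    hit <- matrix(runif(1600) < 0.1, 40, 40)
    vals[hit] <- 0.2
    map <- compute_fvfm((1 - vals) * 3000, matrix(3000, 40, 40),
                        matrix(TRUE, 40, 40))
    patchiness_score(map, 0.35)
  }, numeric(1))
  expect_lt(abs(mean(scores) - 0.1), 0.03)
})

test_that("the rule table reproduces the published stress signatures", {
  days <- 1:5
  # PhiPSII 0.42 -> 0.30 while Fv/Fm and 550/510 stay normal
  drought <- make_traj(days, fvfm = rep(0.79, 5),
                       phipsii = seq(0.42, 0.295, length.out = 5),
                       ratio = rep(1.6, 5))
  expect_identical(classify_stress(drought)$label, "drought_early")

  # then Fv/Fm and the ratio collapse too
  severe <- make_traj(1:9,
                      fvfm = c(rep(0.8, 6), 0.74, 0.72, 0.71),
                      phipsii = c(seq(0.40, 0.25, length.out = 7), 0.25, 0.25),
                      ratio = c(rep(1.6, 6), 1.45, 1.4, 1.4))
  expect_identical(classify_stress(severe)$label, "drought_severe")

  # gradual three-way decline with rising Fv/Fm heterogeneity, no lesions
  ndef <- make_traj(1:9,
                    fvfm = seq(0.80, 0.52, length.out = 9),
                    phipsii = seq(0.40, 0.20, length.out = 9),
                    ratio = seq(1.60, 1.10, length.out = 9),
                    fvfm_std = seq(0.03, 0.12, length.out = 9))
  d <- classify_stress(ndef, patchiness = rep(0.1, 9))
  expect_identical(d$label, "nitrogen_deficiency")
  expect_true(d$evidence$heterogeneity_rising[nrow(d$evidence)])

  # rapid collapse with clumped lesions
  disease <- make_traj(1:5,
                       fvfm = c(0.80, 0.75, 0.60, 0.45, 0.40),
                       phipsii = c(0.40, 0.36, 0.28, 0.18, 0.12),
                       ratio = c(1.6, 1.5, 1.2, 0.9, 0.8))
  d2 <- classify_stress(disease, patchiness = c(0, 0.3, 0.6, 0.8, 0.9))
  expect_identical(d2$label, "disease")
  expect_true(d2$evidence$rapid_decline[nrow(d2$evidence)] ||
                d2$evidence$patchy_lesions[nrow(d2$evidence)])

  healthy <- make_traj(1:5, fvfm = rep(0.80, 5), phipsii = rep(0.40, 5),
                       ratio = rep(1.6, 5))
  expect_identical(classify_stress(healthy)$label, "healthy")
})

test_that("disease outranks nitrogen deficiency when both rules fire", {
  traj <- make_traj(1:9,
                    fvfm = seq(0.80, 0.50, length.out = 9),
                    phipsii = seq(0.40, 0.18, length.out = 9),
                    ratio = seq(1.60, 1.00, length.out = 9),
                    fvfm_std = seq(0.03, 0.15, length.out = 9))
  d <- classify_stress(traj, patchiness = seq(0.1, 0.9, length.out = 9))
  expect_identical(d$label, "disease")
})

test_that("trailing recovered days never erase a severe diagnosis", {
  stressed <- make_traj(1:9,
                        fvfm = c(rep(0.8, 6), 0.74, 0.72, 0.71),
                        phipsii = c(seq(0.40, 0.25, length.out = 7), 0.25, 0.25),
                        ratio = c(rep(1.6, 6), 1.45, 1.4, 1.4))
  with_recovery <- dplyr::bind_rows(
    stressed,
    make_traj(10:12, fvfm = rep(0.80, 3), phipsii = rep(0.40, 3),
              ratio = rep(1.6, 3))
  )
  expect_identical(classify_stress(with_recovery)$label, "drought_severe")
})

test_that("trajectory validation catches malformed input", {
  short <- make_traj(1:2, fvfm = c(0.8, 0.8), phipsii = c(0.4, 0.4),
                     ratio = c(1.6, 1.6))
  expect_error(classify_stress(short),
               class = "fluoroscan_insufficient_data")
  incomplete <- dplyr::filter(make_traj(1:4, rep(0.8, 4), rep(0.4, 4),
                                        rep(1.6, 4)),
                              !(day == 2 & indicator == "phipsii"))
  expect_error(classify_stress(incomplete), "all three")
})

test_that("diagnosis reports serialise with their evidence and thresholds", {
  traj <- make_traj(1:5, fvfm = rep(0.80, 5), phipsii = rep(0.40, 5),
                    ratio = rep(1.6, 5))
  d <- classify_stress(traj, note = "temperature log reviewed: stable")
  path <- withr::local_tempfile(fileext = ".json")
  write_diagnosis(d, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$label, "healthy")
  expect_identical(back$note, "temperature log reviewed: stable")
  expect_equal(back$thresholds$fvfm_affected, 0.75)
  expect_identical(nrow(back$evidence), 3L)
})
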