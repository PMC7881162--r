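test_that("timepoint selection uses nearest-rank 95th percentile of crossings", {
  # all wells cross at t = 10
  const <- tidyr::expand_grid(well = 1:4, time = 1:12) %>%
    dplyr::mutate(confluence = ifelse(time >= 10, 100, 10 * time))
  expect_equal(select_timepoint(const), 10)

  # 20 wells crossing at t = 1..20: nearest-rank 95th percentile is t = 19
  stagger <- tidyr::expand_grid(well = 1:20, time = 1:20) %>%
    dplyr::mutate(confluence = ifelse(time >= well, 100, 0))
  expect_equal(select_timepoint(stagger), 19)

  # wells that never reach threshold fall back to the last timepoint
  never <- tidyr::expand_grid(well = 1:3, time = 1:8) %>%
    dplyr::mutate(confluence = 50)
  expect_warning(tp <- select_timepoint(never), "never reached")
  expect_equal(tp, 8)

  expect_error(select_timepoint(const[0, ]), "empty")
})

test_that("normalization divides by the DMSO mean and clips to [0, 1]", {
  out <- normalize_response(c(80, 0, 88), dmso_mean = 80)
  expect_equal(out$response, c(1, 0, 1))
  expect_equal(out$clipped, c(FALSE, FALSE, TRUE))
  expect_equal(normalize_response(40, 80)$response, 0.5)
  expect_error(normalize_response(10, 0), "positive")
})

test_that("AAC identities hold and monotonicity is respected", {
  doses <- dose_ladder()
  expect_equal(compute_aac(tibble::tibble(dose = doses, response = 1)), 0)
  expect_equal(compute_aac(tibble::tibble(dose = doses, response = 0)), 1)

  # response declining linearly in log10(dose) from 1 to 0: AAC = 1/2 exactly
  x <- log10(doses)
  lin <- 1 - (x - min(x)) / (max(x) - min(x))
  expect_equal(compute_aac(tibble::tibble(dose = doses, response = lin)), 0.5)

  # pointwise-lower response never lowers AAC
  set.seed(5)
  r <- runif(9)
  lower <- pmax(0, r - runif(9, 0, 0.3))
  expect_gte(compute_aac(tibble::tibble(dose = doses, response = lower)),
             compute_aac(tibble::tibble(dose = doses, response = r)))

  # AAC depends only on log-spacing: common dose rescaling changes nothing
  expect_equal(compute_aac(tibble::tibble(dose = doses * 1e3, response = r)),
               compute_aac(tibble::tibble(dose = doses, response = r)))

  expect_error(compute_aac(tibble::tibble(dose = 1e-8, response = 0.5)),
               "two doses")
})

test_that("Hill fits recover noiseless parameters and flag flat curves", {
  truth <- list(ec50 = 1e-8, hill = 1.5, e_inf = 0.1)
  series <- tibble::tibble(
    dose = dose_ladder(),
    response = truth$e_inf + (1 - truth$e_inf) /
      (1 + (dose / truth$ec50)^truth$hill))
  fit <- fit_hill(series)
  expect_lt(abs(fit$ec50 - truth$ec50) / truth$ec50, 1e-6)
  expect_equal(fit$hill, truth$hill, tolerance = 1e-5)
  expect_equal(fit$e_inf, truth$e_inf, tolerance = 1e-6)

  flat <- fit_hill(tibble::tibble(dose = dose_ladder(), response = 1))
  expect_true(flat$flat)
  expect_true(is.na(flat$ec50))

  expect_error(fit_hill(series[1:3, ]), "four doses")

  td <- tidy(fit)
  expect_equal(td$term, c("ec50", "hill", "e_inf"))
  expect_equal(glance(fit)$converged, TRUE)
})

test_that("sensitivity and responder labels follow their thresholds", {
  sm <- tibble::tibble(
    sample_id = paste0("s", 1:4), compound = "LLY-283",
    aac = c(0.1, 0.2, 0.6, 0.7),
    ec50 = c(249e-9, 251e-9, NA, 100e-9))
  lab <- classify_and_label(sm)
  expect_equal(lab$sensitive, c(TRUE, FALSE, FALSE, TRUE))
  # median split over {.1,.2,.6,.7}: median 0.4
  expect_equal(lab$responder, c("poor", "poor", "good", "good"))

  # all AACs equal: everyone is at the median, so all good
  tied <- classify_and_label(dplyr::mutate(sm, aac = 0.3))
  expect_true(all(tied$responder == "good"))

  # explicit threshold overrides the median rule
  thr <- classify_and_label(sm, aac_threshold = 0.65)
  expect_equal(thr$responder, c("poor", "poor", "poor", "good"))
})

test_that("compound correlation matches the closed form", {
  expect_equal(compound_correlation(1:5, 1:5)$r, 1)
  expect_equal(compound_correlation(1:5, -(1:5))$r, -1)
  # three points {(1,2),(2,4),(3,5)}: r = 3 / sqrt(2 * 14/3)
  got <- compound_correlation(c(1, 2, 3), c(2, 4, 5))
  expect_equal(got$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_error(compound_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("plate summaries combine AAC and Hill fits per sample", {
  plate <- dplyr::bind_rows(
    sim_dose_response(ec50 = 1e-8, noise_sd = 0, sample_id = "A", seed = 1),
    sim_dose_response(ec50 = 1, noise_sd = 0, sample_id = "B", seed = 2))
  sm <- summarise_dose_response(plate)
  expect_equal(nrow(sm), 2)
  expect_lt(abs(sm$ec50[sm$sample_id == "A"] - 1e-8) / 1e-8, 1e-6)
  expect_true(is.na(sm$ec50[sm$sample_id == "B"]))  # flat: undefined EC50
  expect_gt(sm$aac[sm$sample_id == "A"], sm$aac[sm$sample_id == "B"])
})
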