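make_epoch_series <- function(n_epochs, counts = 0L, activity = "jog",
                              child = "c1", epoch_length_s = 15) {
  tibble::tibble(
    child_id = child, activity = activity,
    epoch_index = seq_len(n_epochs), epoch_length_s = epoch_length_s,
    start_offset_s = (seq_len(n_epochs) - 1) * epoch_length_s,
    counts = rep_len(counts, n_epochs)
  )
}

test_that("extract_window selects the steady-state epochs", {
  s <- make_epoch_series(20)
  w <- extract_window(s)
  expect_equal(nrow(w), 8)
  expect_true(all(w$start_offset_s >= 150 & w$start_offset_s < 270))

  lying <- make_epoch_series(120, activity = "lying")
  wl <- extract_window(lying)
  expect_equal(nrow(wl), 8)
  expect_true(all(wl$start_offset_s >= 1350 & wl$start_offset_s < 1470))

  short <- make_epoch_series(16) # 4 minutes only
  expect_error(extract_window(short), "incomplete window.*c1.*jog")
})

test_that("extract_window handles oxygen-uptake series by record time", {
  v <- tibble::tibble(
    child_id = "c1", activity = "slow_walk",
    time_s = seq(5, 300, by = 5), vo2_ml_kg_min = 10
  )
  w <- extract_window(v)
  expect_true(all(w$time_s >= 150 & w$time_s < 270))
  expect_equal(nrow(w), 24)
})

test_that("epochs_to_cpm is the mean of per-minute sums", {
  expect_equal(epochs_to_cpm(make_epoch_series(8, 100L)), 400)
  expect_equal(epochs_to_cpm(make_epoch_series(8, 0L)), 0)

  two_min <- make_epoch_series(8, c(0L, 0L, 0L, 0L, 100L, 100L, 100L, 100L))
  expect_equal(epochs_to_cpm(two_min), 200)
  # invariant under exchanging the two minutes
  swapped <- make_epoch_series(8, c(100L, 100L, 100L, 100L, 0L, 0L, 0L, 0L))
  expect_equal(epochs_to_cpm(swapped), 200)

  expect_error(epochs_to_cpm(make_epoch_series(7)), "whole number")
})

test_that("oxygen-uptake conversion matches the caloric equivalent", {
  expect_equal(vo2_to_ee(5.46), 5.46 * 60 * 4.825 / 1000)
  expect_equal(round(vo2_to_ee(5.46), 2), 1.58)
  expect_equal(vo2_to_ee(0), 0)
  expect_equal(vo2_to_ee(10), 2.895)
  expect_error(vo2_to_ee(-1), "non-negative")
  # round trip
  x <- c(0, 0.3, 5.46, 12.8)
  expect_equal(ee_to_vo2(vo2_to_ee(x)), x, tolerance = 1e-9)
})

test_that("Schofield BMR matches hand-evaluated references", {
  kid <- function(sex) {
    tibble::tibble(child_id = "c1", sex = sex, age_years = 7.5,
                   height_cm = 132.9, weight_kg = 31.3)
  }
  m <- schofield_bmr(kid("male"))
  # 0.082*31.3 + 0.545*1.329 + 1.736 = 5.0269 MJ/day
  expect_equal(m$bmr_kcal_day, 5.02691 * 239.006, tolerance = 1e-4)
  expect_equal(m$bmr_kcal_kg_hr, 5.02691 * 239.006 / (31.3 * 24),
               tolerance = 1e-4)
  f <- schofield_bmr(kid("female"))
  # 0.071*31.3 + 0.677*1.329 + 1.553 = 4.67497 MJ/day
  expect_equal(f$bmr_kcal_day, 4.67497 * 239.006, tolerance = 1e-4)

  old <- kid("male")
  old$age_years <- 12
  expect_error(schofield_bmr(old), "Schofield band")
})

test_that("BMR is strictly increasing in weight and height for each sex", {
  grid <- tidyr::expand_grid(
    sex = c("male", "female"),
    weight_kg = c(20, 30, 40),
    height_cm = c(110, 130, 150)
  ) |>
    dplyr::mutate(child_id = as.character(dplyr::row_number()),
                  age_years = 8)
  bmr <- schofield_bmr(grid) |> dplyr::bind_cols(grid[c("sex", "weight_kg",
                                                        "height_cm")])
  by_h <- bmr |>
    dplyr::group_by(sex, height_cm) |>
    dplyr::arrange(weight_kg, .by_group = TRUE) |>
    dplyr::summarise(mono = all(diff(bmr_kcal_day) > 0), .groups = "drop")
  by_w <- bmr |>
    dplyr::group_by(sex, weight_kg) |>
    dplyr::arrange(height_cm, .by_group = TRUE) |>
    dplyr::summarise(mono = all(diff(bmr_kcal_day) > 0), .groups = "drop")
  expect_true(all(by_h$mono) && all(by_w$mono))
})

test_that("mean predicted BMR for the default cohort is near 1.58", {
  vals <- vapply(1:20, function(i) {
    cohort <- generate_cohort(seed = 100 + i)
    mean(schofield_bmr(cohort)$bmr_kcal_kg_hr)
  }, numeric(1))
  expect_true(all(vals > 1.50 & vals < 1.66))
})

test_that("METs are energy expenditure over predicted BMR", {
  expect_equal(compute_mets(1.58, 1.58), 1)
  expect_equal(compute_mets(4.74, 1.58), 3)
  expect_equal(compute_mets(0, 1.58), 0)
  expect_error(compute_mets(1, 0), "positive")
})

test_that("reduce_study yields one summary per child and activity", {
  s <- cached_default_summaries()
  expect_equal(nrow(s), 53 * 7)
  expect_true(all(s$n_epochs_used == 8))
  expect_true(all(s$mean_cpm >= 0 & s$ee_kcal_kg_hr >= 0 & s$mets >= 0))
})

test_that("reduce_study reports missing child-activity pairs", {
  study <- generate_study(study_config(n_children = 3, n_male = 1), seed = 2)
  epochs <- dplyr::filter(study$epochs,
                          !(child_id == "c002" & activity == "jog"))
  expect_error(reduce_study(epochs, study$vo2, study$anthro),
               "c002.*jog")
})

test_that("a degenerate-SD study reproduces the configured means exactly", {
  acts <- default_activity_params() |>
    dplyr::filter(activity %in% c("slow_walk", "brisk_walk", "jog")) |>
    dplyr::mutate(
      sd_cpm = 0, sd_ee = 0,
      mean_cpm = c(1600, 2880, 4836) # divisible by 4 so epochs are integral
    )
  cfg <- study_config(n_children = 3, n_male = 2, activities = acts)
  study <- generate_study(cfg, seed = 1)
  s <- reduce_study(study$epochs, study$vo2, study$anthro) |>
    dplyr::left_join(acts[c("activity", "mean_cpm", "mean_ee")],
                     by = "activity", suffix = c("", "_cfg"))
  expect_equal(s$mean_cpm, s$mean_cpm_cfg)
  # EE from the plateau window is within the residual of the rise profile
  expect_equal(s$ee_kcal_kg_hr, s$mean_ee, tolerance = 0.002)
})
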