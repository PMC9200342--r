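test_that("cosinor signal honours its parameters", {
  # flat rhythm and peak location
  expect_equal(circadian_signal(c(0, 123, 999), mesor = 5, amplitude = 0,
                                acrophase = 300), rep(5, 3))
  expect_equal(circadian_signal(720, mesor = 10, amplitude = 3,
                                acrophase = 720), 13)
  # mean over one full period sampled at 96 equal steps returns the mesor
  t <- seq(0, 1440, length.out = 97)[-97]
  expect_equal(mean(circadian_signal(t, mesor = 36.5, amplitude = 0.8,
                                     acrophase = 555)), 36.5,
               tolerance = 1e-9)
  expect_error(circadian_signal(0, 1, 1, 0, period = 0), "period")
  expect_error(circadian_signal(0, 1, -1, 0), "amplitude")
})

test_that("injury effects scale amplitude and mesor as configured", {
  circ <- default_circadian()
  expect_identical(apply_injury_effect(circ, "naive", 1), circ)
  inj1 <- apply_injury_effect(circ, "injured", 1)
  expect_equal(inj1$amplitude, circ$amplitude * 0.3)
  dist_row <- function(d) d[d$channel == "distance_mm", ]
  expect_equal(dist_row(inj1)$mesor, dist_row(circ)$mesor * 0.5)
  # recovery: amplitude factors are non-decreasing in week
  amps <- vapply(1:5, function(w) {
    dist_row(apply_injury_effect(circ, "injured", w))$amplitude
  }, numeric(1))
  expect_true(all(diff(amps) >= 0))
  # injured week-1 deficit is at least as severe as sham's
  sham1 <- apply_injury_effect(circ, "sham", 1)
  expect_true(all(inj1$amplitude <= sham1$amplitude))
  expect_true(all(sham1$amplitude <= circ$amplitude))
  expect_error(apply_injury_effect(circ, "mouse", 1), "group")
})

test_that("cohort generation matches the configured structure", {
  cfg <- cohort_config(seed = 7)
  cohort <- simulate_cohort(cfg)
  aw <- dplyr::distinct(cohort, animal_id, week)
  expect_equal(nrow(aw), 4 + 30 + 30)
  expect_true(all(dplyr::count(cohort, animal_id, week)$n == 290))
  # 15-minute grid starting at 0
  ts <- cohort$timestamp[cohort$animal_id == "naive_01"]
  expect_equal(ts, (0:289) * 15)
  # physical invariants
  expect_true(all(cohort$distance_mm >= 0))
  expect_true(all(cohort$separation_mm >= 0))
  expect_true(all(cohort$transitions >= 0 &
                    cohort$transitions == round(cohort$transitions)))
  expect_true(all(cohort$temperature_c > 30 & cohort$temperature_c < 42))
})

test_that("identical seeds give bitwise-identical cohorts", {
  expect_identical(simulate_cohort(cohort_config(seed = 11)),
                   simulate_cohort(cohort_config(seed = 11)))
  c2 <- simulate_cohort(cohort_config(seed = 12))
  expect_false(identical(simulate_cohort(cohort_config(seed = 11)), c2))
})

test_that("noise-free naive channels equal the exact cosine", {
  cfg <- tiny_config(seed = 3, noise = FALSE)
  cohort <- simulate_cohort(cfg)
  naive <- dplyr::filter(cohort, group == "naive", animal_id == "naive_01")
  for (ch in c("distance_mm", "temperature_c", "separation_mm")) {
    par <- cfg$circadian[cfg$circadian$channel == ch, ]
    expected <- circadian_signal(naive$timestamp, par$mesor, par$amplitude,
                                 par$acrophase_minutes, par$period_minutes)
    expect_equal(naive[[ch]], pmax(expected, if (ch == "temperature_c") -Inf else 0),
                 tolerance = 1e-12)
  }
})

test_that("widening the injured-sham week-1 gap separates group means", {
  base <- default_injury_effects()
  widen <- dplyr::mutate(base, amplitude_factor = ifelse(
    group == "injured" & week == 1, amplitude_factor * 0.5, amplitude_factor
  ))
  # Euclidean distance between the groups' per-bin mean-distance profiles:
  # phase-sensitive, so a flatter injured rhythm moves the profiles apart
  mean_gap <- function(eff) {
    cfg <- cohort_config(
      group_sizes = c(injured = 2, sham = 2),
      weeks = list(injured = 1L, sham = 1L),
      samples_per_week = 96,
      circadian = dplyr::mutate(default_circadian(), noise_sd = 0),
      injury_effects = eff, seed = 5
    )
    f <- record_features(bin_observations(simulate_cohort(cfg), 6))
    prof <- dplyr::summarise(dplyr::group_by(f, group, bin),
                             m = mean(distance_mm), .groups = "drop")
    sqrt(sum((prof$m[prof$group == "injured"] -
                prof$m[prof$group == "sham"])^2))
  }
  expect_gt(mean_gap(widen), mean_gap(base))
})
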