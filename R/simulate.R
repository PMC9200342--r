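#' Cosinor circadian signal
#'
#' Evaluates a single-harmonic cosinor model
#' `mesor + amplitude * cos(2 * pi * (t - acrophase) / period)`, the simplest
#' parametric description of a circadian rhythm: `mesor` is the rhythm-adjusted
#' midline, `amplitude` half the peak-to-trough range and `acrophase` the time
#' of the daily peak.
#'
#' @param t Time in minutes since session start (vectorised).
#' @param mesor Midline level, in the channel's units.
#' @param amplitude Half peak-to-trough range (same units); must be >= 0.
#' @param acrophase Peak time in minutes.
#' @param period Rhythm period in minutes; defaults to one day (1440).
#' @return Numeric vector of signal values, same length as `t`.
#' @export
#' @examples
#' circadian_signal(c(0, 360, 720), mesor = 10, amplitude = 4, acrophase = 720)
circadian_signal <- function(t, mesor, amplitude, acrophase, period = 1440) {
  if (!is.numeric(period) || any(period <= 0)) {
    abort("`period` must be a positive number of minutes.")
  }
  if (any(amplitude < 0)) abort("`amplitude` must be >= 0.")
  mesor + amplitude * cos(2 * pi * (t - acrophase) / period)
}

default_circadian <- function() {
  tibble::tibble(
    channel   = hca_channels(),
    mesor     = c(2000, 36.5, 150, 30),
    amplitude = c(1500, 0.8, 60, 20),
    acrophase_minutes = c(900, 900, 900, 900),
    period_minutes    = 1440,
    noise_sd  = c(200, 0.25, 15, 0)
  )
}

# Default injury-effect schedule: multiplicative factors on cosinor amplitude
# and mesor, per group x week x channel. Injury flattens the rhythm (amplitude
# down) and lowers overall activity (mesor down on the activity channels),
# with monotone recovery over the five post-intervention weeks. Body
# temperature keeps a physiological mesor (small week-1 dip only); sham
# animals show a milder, faster-recovering deficit than injured ones.
default_injury_effects <- function() {
  act <- setdiff(hca_channels(), "temperature_c")
  grid <- tidyr::expand_grid(
    group = c("injured", "sham"),
    week = 1:5,
    channel = hca_channels()
  )
  amp <- list(injured = c(0.3, 0.45, 0.6, 0.75, 0.9),
              sham    = c(0.7, 0.85, 0.95, 1, 1))
  mes_act <- list(injured = c(0.5, 0.65, 0.8, 0.9, 0.95),
                  sham    = c(0.9, 0.95, 1, 1, 1))
  mes_tmp <- list(injured = c(0.99, 0.995, 1, 1, 1),
                  sham    = c(0.995, 1, 1, 1, 1))
  dplyr::mutate(
    grid,
    amplitude_factor = purrr::map2_dbl(.data$group, .data$week, ~ amp[[.x]][.y]),
    mesor_factor = purrr::pmap_dbl(
      list(.data$group, .data$week, .data$channel),
      function(g, w, ch) if (ch %in% act) mes_act[[g]][w] else mes_tmp[[g]][w]
    )
  )
}

#' Configuration for a synthetic home-cage cohort
#'
#' Bundles every parameter of the synthetic generator: cohort structure
#' (animals per group and the weeks each group is recorded), sampling grid,
#' per-channel cosinor parameters with additive Gaussian noise, and the
#' injury-effect schedule (multiplicative amplitude/mesor factors per group,
#' week and channel). Defaults encode the reference cohort design: 4 naive animals
#' recorded for a single baseline week, 6 injured and 6 sham animals recorded
#' for 5 post-intervention weeks, 290 samples per 72-hour weekly session at
#' 15-minute resolution, a flattened rhythm with reduced activity in week 1
#' post-injury and progressive recovery thereafter.
#'
#' @param group_sizes Named integer vector: animals per group.
#' @param weeks Named list: for each group either one integer vector of week
#'   indices shared by all its animals, or a list of per-animal week vectors
#'   (length `group_sizes[[group]]`).
#' @param samples_per_week Samples recorded per animal-week (default 290).
#' @param sample_interval Minutes between samples (default 15).
#' @param circadian Tibble with columns `channel`, `mesor`, `amplitude`,
#'   `acrophase_minutes`, `period_minutes`, `noise_sd`.
#' @param injury_effects Tibble with columns `group`, `week`, `channel`,
#'   `amplitude_factor`, `mesor_factor`. Naive animals are never modified.
#' @param seed Integer seed driving all randomness in [simulate_cohort()].
#' @return A list of class `hc_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$group_sizes
cohort_config <- function(group_sizes = c(naive = 4, injured = 6, sham = 6),
                          weeks = list(naive = 1L, injured = 1:5, sham = 1:5),
                          samples_per_week = 290,
                          sample_interval = 15,
                          circadian = default_circadian(),
                          injury_effects = default_injury_effects(),
                          seed = 1L) {
  if (any(group_sizes < 1)) abort("Every listed group needs >= 1 animal.")
  if (!all(names(group_sizes) %in% hca_groups())) {
    abort("Group names must be among naive/injured/sham.")
  }
  if (!setequal(names(weeks), names(group_sizes))) {
    abort("`weeks` must name the same groups as `group_sizes`.")
  }
  if (samples_per_week < 1) abort("`samples_per_week` must be >= 1.")
  if (any(circadian$amplitude < 0)) abort("Circadian amplitudes must be >= 0.")
  if (any(circadian$noise_sd < 0)) abort("`noise_sd` must be >= 0.")
  fac <- c(injury_effects$amplitude_factor, injury_effects$mesor_factor)
  if (any(fac < 0 | fac > 2)) abort("Injury-effect factors must lie in [0, 2].")
  structure(
    list(
      group_sizes = group_sizes, weeks = weeks,
      samples_per_week = as.integer(samples_per_week),
      sample_interval = sample_interval,
      circadian = circadian, injury_effects = injury_effects,
      seed = as.integer(seed)
    ),
    class = "hc_config"
  )
}

#' Injury-adjusted cosinor parameters for one group and week
#'
#' Applies the configured multiplicative injury factors to the baseline
#' per-channel cosinor parameters. Naive animals are returned unchanged;
#' injured and sham animals have amplitude and mesor scaled by their group's
#' factors for the given week.
#'
#' @param circadian Baseline per-channel cosinor tibble (see [cohort_config()]).
#' @param group One of `"naive"`, `"injured"`, `"sham"`.
#' @param week Week index (must be present in the effect schedule for
#'   non-naive groups).
#' @param effects Injury-effect tibble (see [cohort_config()]).
#' @return Tibble like `circadian` with adjusted `mesor` and `amplitude`.
#' @export
apply_injury_effect <- function(circadian, group, week,
                                effects = default_injury_effects()) {
  if (!group %in% hca_groups()) {
    abort(paste0("Unknown group label: ", group))
  }
  if (identical(group, "naive")) return(circadian)
  eff <- dplyr::filter(effects, .data$group == !!group, .data$week == !!week)
  if (nrow(eff) == 0) {
    abort(paste0("No injury effects configured for ", group, " week ", week))
  }
  out <- dplyr::left_join(circadian, eff[, c("channel", "amplitude_factor",
                                             "mesor_factor")], by = "channel")
  dplyr::select(
    dplyr::mutate(out,
      amplitude = .data$amplitude * dplyr::coalesce(.data$amplitude_factor, 1),
      mesor = .data$mesor * dplyr::coalesce(.data$mesor_factor, 1)
    ),
    -"amplitude_factor", -"mesor_factor"
  )
}

animal_week_plan <- function(config) {
  purrr::list_rbind(purrr::imap(config$weeks, function(wks, grp) {
    n <- config$group_sizes[[grp]]
    if (!is.list(wks)) wks <- rep(list(as.integer(wks)), n)
    if (length(wks) != n) {
      abort(paste0("`weeks$", grp, "` must have one entry per animal."))
    }
    purrr::list_rbind(purrr::imap(wks, function(w, i) {
      tibble::tibble(
        animal_id = sprintf("%s_%02d", grp, i),
        group = grp, week = as.integer(w)
      )
    }))
  }))
}

#' Simulate a synthetic home-cage cohort
#'
#' Generates one record per animal-week on a regular 15-minute grid. Each
#' channel is an injury-adjusted cosinor evaluated on the grid plus seeded
#' Gaussian noise; distance and separation are clipped at zero, and the
#' transition channel is drawn from a Poisson distribution whose rate is the
#' (non-negative part of the) cosinor signal, because it is a count. Identical
#' configurations and seeds produce bitwise-identical cohorts.
#'
#' @param config An [cohort_config()] object.
#' @return A tibble with one row per sample and columns `animal_id`, `group`,
#'   `week`, `timestamp` (minutes since session start), `distance_mm`,
#'   `temperature_c`, `separation_mm`, `transitions`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 7))
#' dplyr::count(cohort, group)
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "hc_config"))
  plan <- animal_week_plan(config)
  tgrid <- (seq_len(config$samples_per_week) - 1) * config$sample_interval
  withr::with_seed(config$seed, {
    recs <- purrr::pmap(plan, function(animal_id, group, week) {
      par <- apply_injury_effect(config$circadian, group, week,
                                 config$injury_effects)
      vals <- purrr::pmap(par, function(channel, mesor, amplitude,
                                        acrophase_minutes, period_minutes,
                                        noise_sd) {
        mu <- circadian_signal(tgrid, mesor, amplitude, acrophase_minutes,
                               period_minutes)
        if (channel == "transitions") {
          as.numeric(rpois(length(tgrid), lambda = pmax(mu, 0)))
        } else {
          x <- mu + rnorm(length(tgrid), sd = noise_sd)
          if (channel %in% c("distance_mm", "separation_mm")) x <- pmax(x, 0)
          x
        }
      })
      names(vals) <- par$channel
      tibble::tibble(
        animal_id = animal_id, group = group, week = week,
        timestamp = tgrid, !!!vals
      )
    })
    purrr::list_rbind(recs)
  })
}

#' Synthetic cohort with the reference class structure
#'
#' Convenience configuration with 16 naive, 54 injured and 48 sham
#' animal-weeks of 290 samples each, so that 6-bin binning yields 708
#' observations split 96 / 324 / 288 across the three classes — the class
#' structure this pipeline's dataset construction is designed around. It is
#' a synthetic structural stand-in for a real HCA export (none is shipped
#' with the package), useful for exercising the dataset-construction
#' arithmetic end to end.
#'
#' @param seed Integer seed.
#' @return An [cohort_config()] object.
#' @export
reference_cohort_config <- function(seed = 1L) {
  cohort_config(
    group_sizes = c(naive = 16, injured = 11, sham = 10),
    weeks = list(
      naive = 1L,
      injured = c(rep(list(1:5), 10), list(1:4)),
      sham = c(rep(list(1:5), 9), list(1:3))
    ),
    seed = seed
  )
}
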