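#' Specification of a synthetic thermography cohort
#'
#' Describes the simulated study population: bilateral breast temperature
#' grids plus a medical-record table. Class balance defaults to 211 healthy /
#' 153 sick, and the record priors default to a mean age of 57.0 years and a
#' mean age at last menstrual period of 48.1 years, matching the cohort the
#' diagnostic network is designed for. Each breast is simulated as a smooth
#' elliptical body-temperature field over a cool ambient background; sick
#' cases additionally receive an isotropic Gaussian hot-spot on the affected
#' side, emulating the local hyperthermia produced by tumour-associated
#' blood flow.
#'
#' @param n_healthy,n_sick class counts.
#' @param grid_height,grid_width per-breast grid size in pixels.
#' @param ambient_temp background temperature, degC; kept below any sensible
#'   segmentation threshold so thresholding has work to do.
#' @param body_temp_mean,body_temp_sd per-patient baseline body surface
#'   temperature distribution, degC.
#' @param smooth_amp amplitude of the smooth low-frequency within-breast
#'   variation, degC; also bounds the left/right asymmetry of tumour-free
#'   fields (the asymmetry bound is `2 * smooth_amp`).
#' @param hotspot_delta_range peak temperature elevation of the hot-spot,
#'   degC, drawn uniformly per sick case.
#' @param hotspot_sigma_range spatial standard deviation of the hot-spot,
#'   pixels, drawn uniformly per sick case.
#' @param noise_sd i.i.d. Gaussian pixel noise on body cells, degC.
#' @param age_mean,age_sd,lmp_mean,lmp_sd medical-record priors (years);
#'   ages are truncated to [18, 95] and last-menstrual-period ages to
#'   [30, 60] before rounding.
#' @param seed integer seed; every draw in the cohort derives from it.
#' @return A list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_healthy = 211L, n_sick = 153L,
                        grid_height = 32L, grid_width = 32L,
                        ambient_temp = 22, body_temp_mean = 31.5,
                        body_temp_sd = 0.8, smooth_amp = 0.3,
                        hotspot_delta_range = c(2, 4),
                        hotspot_sigma_range = c(2, 4),
                        noise_sd = 0.25,
                        age_mean = 57.0, age_sd = 10,
                        lmp_mean = 48.1, lmp_sd = 5,
                        seed = 1L) {
  spec <- list(n_healthy = as.integer(n_healthy), n_sick = as.integer(n_sick),
               grid_height = as.integer(grid_height),
               grid_width = as.integer(grid_width),
               ambient_temp = ambient_temp, body_temp_mean = body_temp_mean,
               body_temp_sd = body_temp_sd, smooth_amp = smooth_amp,
               hotspot_delta_range = as.numeric(hotspot_delta_range),
               hotspot_sigma_range = as.numeric(hotspot_sigma_range),
               noise_sd = noise_sd, age_mean = age_mean, age_sd = age_sd,
               lmp_mean = lmp_mean, lmp_sd = lmp_sd, seed = as.integer(seed))
  with(spec, {
    stopifnot(n_healthy >= 0L, n_sick >= 0L, grid_height >= 4L,
              grid_width >= 4L, body_temp_sd >= 0, noise_sd >= 0,
              smooth_amp >= 0, length(hotspot_delta_range) == 2L,
              hotspot_delta_range[1] <= hotspot_delta_range[2],
              hotspot_sigma_range[1] <= hotspot_sigma_range[2],
              hotspot_sigma_range[1] > 0, age_sd >= 0, lmp_sd >= 0)
  })
  structure(spec, class = "cohort_spec")
}

# deterministic per-patient substream: cohorts are extensible without
# reshuffling earlier patients; kept well below .Machine$integer.max
derive_seed <- function(seed, i, stream = 0L) {
  (as.integer(seed) %% 65521L) * 29L + i * 2011L + stream * 7L
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  for (k in 1:100) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

# smooth low-frequency field with sup-norm <= amp, built from a few random
# low-order cosine modes
smooth_field <- function(h, w, amp) {
  if (amp == 0) return(matrix(0, h, w))
  ri <- (seq_len(h) - 0.5) / h
  ci <- (seq_len(w) - 0.5) / w
  f <- matrix(0, h, w)
  coef <- stats::runif(4, -1, 1)
  ph <- stats::runif(4, 0, 2 * pi)
  fr <- stats::runif(4, 0.5, 1.5)
  f <- f + coef[1] * outer(cos(2 * pi * fr[1] * ri + ph[1]), rep(1, w))
  f <- f + coef[2] * outer(rep(1, h), cos(2 * pi * fr[2] * ci + ph[2]))
  f <- f + coef[3] * outer(cos(2 * pi * fr[3] * ri + ph[3]),
                           cos(2 * pi * fr[4] * ci + ph[4]))
  f <- f + coef[4] * outer(ri - 0.5, ci - 0.5) * 4
  f * amp / max(abs(range(f)), 1e-12)
}

body_ellipse <- function(h, w) {
  r0 <- (h + 1) / 2; c0 <- (w + 1) / 2
  a <- 0.45 * h; b <- 0.42 * w
  outer(seq_len(h), seq_len(w),
        function(i, j) ((i - r0) / a)^2 + ((j - c0) / b)^2 <= 1)
}

one_breast <- function(spec, base, hotspot_delta = 0, hotspot_sigma = NULL) {
  h <- spec$grid_height; w <- spec$grid_width
  body <- body_ellipse(h, w)
  v <- matrix(spec$ambient_temp, h, w)
  field <- base + smooth_field(h, w, spec$smooth_amp)
  if (hotspot_delta > 0) {
    # center uniform in the inner half of the ellipse so the peak lies on a
    # cell and the full delta is realized there
    r0 <- round(stats::runif(1, h * 0.3, h * 0.7))
    c0 <- round(stats::runif(1, w * 0.3, w * 0.7))
    d2 <- outer((seq_len(h) - r0)^2, (seq_len(w) - c0)^2, `+`)
    field <- field + hotspot_delta * exp(-d2 / (2 * hotspot_sigma^2))
  }
  if (spec$noise_sd > 0)
    field <- field + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
  v[body] <- field[body]
  v <- pmin(pmax(v, 0), 45)
  v
}

#' Simulate one bilateral thermogram pair
#'
#' Generates `(left, right)` temperature grids for a single patient under the
#' cohort's generation law: identical smooth body fields statistics on both
#' sides, plus, for a sick patient, a Gaussian hot-spot with peak elevation
#' drawn from `spec$hotspot_delta_range` on the affected side.
#'
#' @param spec a [cohort_spec()].
#' @param record one patient record row (list or one-row data.frame with
#'   `diagnosis` and `affected_side`).
#' @param seed integer seed for this pair.
#' @return A list with [thermogram] elements `left` and `right`; when a
#'   hot-spot was placed, its peak cell, peak delta and spatial sigma are in
#'   the affected grid's `meta` (`hotspot_row`, `hotspot_col`,
#'   `hotspot_delta`, `hotspot_sigma`).
#' @export
generate_thermogram_pair <- function(spec, record, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  base <- stats::rnorm(1, spec$body_temp_mean, spec$body_temp_sd)
  sick <- as.integer(record$diagnosis) == 1L
  delta <- 0; sigma <- NULL; hs <- NULL
  if (sick) {
    delta <- stats::runif(1, spec$hotspot_delta_range[1],
                          spec$hotspot_delta_range[2])
    sigma <- stats::runif(1, spec$hotspot_sigma_range[1],
                          spec$hotspot_sigma_range[2])
  }
  side <- if (sick) as.character(record$affected_side) else "none"
  make <- function(this_side) {
    if (sick && this_side == side) {
      v <- one_breast(spec, base, delta, sigma)
    } else {
      v <- one_breast(spec, base)
    }
    v
  }
  # draw in fixed order for determinism
  vl <- make("left")
  vr <- make("right")
  meta_l <- list(laterality = "left"); meta_r <- list(laterality = "right")
  if (sick) {
    # recover the peak cell of the affected grid for ground-truth checks
    aff <- if (side == "left") vl else vr
    oth <- if (side == "left") vr else vl
    p <- arrayInd(which.max(aff), dim(aff))
    info <- list(hotspot_row = p[1L], hotspot_col = p[2L],
                 hotspot_delta = delta, hotspot_sigma = sigma)
    if (side == "left") meta_l <- c(meta_l, info) else meta_r <- c(meta_r, info)
  }
  list(left = thermogram(vl, meta = meta_l),
       right = thermogram(vr, meta = meta_r))
}

#' Simulate a full cohort of records and thermogram pairs
#'
#' @param spec a [cohort_spec()].
#' @param grids if `FALSE`, only the record table is generated (useful for
#'   large statistical checks on the record priors).
#' @return A list with `records` (data.frame: `patient_id`, `age`,
#'   `last_menstrual_period`, `diagnosis`, `affected_side`) and `pairs`
#'   (list of `(left, right)` thermogram pairs, `NULL` when `grids = FALSE`).
#'   Fully reproducible from `spec$seed`.
#' @export
generate_cohort <- function(spec, grids = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_healthy + spec$n_sick
  set.seed(derive_seed(spec$seed, 0L, 1L))
  diagnosis <- sample(rep(c(0L, 1L), c(spec$n_healthy, spec$n_sick)))
  age <- as.integer(round(rnorm_trunc(n, spec$age_mean, spec$age_sd, 18, 95)))
  lmp <- round(rnorm_trunc(n, spec$lmp_mean, spec$lmp_sd, 30, 60), 1)
  side <- rep("none", n)
  if (any(diagnosis == 1L))
    side[diagnosis == 1L] <- sample(c("left", "right"), sum(diagnosis == 1L),
                                    replace = TRUE)
  records <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                        age = age, last_menstrual_period = lmp,
                        diagnosis = diagnosis, affected_side = side,
                        stringsAsFactors = FALSE)
  pairs <- NULL
  if (grids && n > 0L) {
    pairs <- lapply(seq_len(n), function(i) {
      p <- generate_thermogram_pair(spec, records[i, ],
                                    derive_seed(spec$seed, i, 2L))
      p$left$meta$patient_id <- records$patient_id[i]
      p$right$meta$patient_id <- records$patient_id[i]
      p
    })
  }
  list(records = records, pairs = pairs)
}

#' Write a cohort to disk
#'
#' Writes one CSV temperature grid per breast (`<patient>_left.csv`,
#' `<patient>_right.csv`) plus `records.csv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  for (i in seq_along(cohort$pairs)) {
    id <- cohort$records$patient_id[i]
    write_temperature_grid(cohort$pairs[[i]]$left,
                           file.path(dir, paste0(id, "_left.csv")))
    write_temperature_grid(cohort$pairs[[i]]$right,
                           file.path(dir, paste0(id, "_right.csv")))
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `records.csv` and per-breast grid CSVs.
#' @return A list with `records` and `pairs`, as from [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  records <- utils::read.csv(file.path(dir, "records.csv"),
                             stringsAsFactors = FALSE)
  pairs <- lapply(records$patient_id, function(id) {
    list(left = read_temperature_grid(file.path(dir, paste0(id, "_left.csv"))),
         right = read_temperature_grid(file.path(dir, paste0(id, "_right.csv"))))
  })
  list(records = records, pairs = pairs)
}
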