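#' Synthetic spindle presets
#'
#' A preset bundles every parameter of the generative model for one
#' experimental condition: a bipolar spindle whose poles carry 0, 1 or 2
#' centrioles, an initially-polar subpopulation of kinetochore pairs, a
#' pole-centred Aurora A activity gradient `A(d) = A_pole exp(-d^2 /
#' (2 sigma^2))` whose amplitude is `pole_amplitude` at a centriolar pole
#' and `acentriolar_factor * pole_amplitude` at an acentriolar one, a
#' congression-initiation hazard suppressed where that activity exceeds
#' `hazard_threshold` when CENP-E is inactive, constant-velocity
#' congression after initiation, and an intensity model whose pole signal
#' scales with the pole amplitude and whose kinetochore phospho-signal
#' decays with distance from the pole.
#'
#' Named presets cover the experimental arms: `control_*` (CENP-E
#' active) and `cenpe_inhibited_*` for centriole configurations `2v2`,
#' `1v1`, `1v0` and `0v0`, plus `cenpe_inhibited_2v2_auroraA_inhibited`,
#' which halves the gradient (`aurora_attenuation = 0.5`) from the drug-
#' addition time `t_drug` onward and ends the simulation (snapshot
#' fixation) `t_fixation_after_drug` minutes later. Any field can be
#' overridden through `...`.
#'
#' @param name One of [preset_names()].
#' @param ... Named field overrides (see field list below).
#'
#' @section Fields:
#' `centriole_config` (two integers in 0..2), `cenpe_active`,
#' `aurora_attenuation` (alpha, 1 = untreated), `n_pairs_total` (23, half
#' of the 46 kinetochores visible as pairs in one projection),
#' `lambda_polar_per_pole` (Poisson mean 4 of initially-polar pairs per
#' pole, consistent with a minority of chromosomes requiring motor-driven
#' congression), `gradient_sd` (sigma, 1.5 µm, so activity is negligible
#' beyond ~3 µm), `pole_amplitude` (1), `acentriolar_factor` (0.25, a
#' four-fold lower amplitude at acentriolar poles), `hazard_threshold`
#' (0.4), `h_max` (0.55 per minute), `speed_mean`/`speed_sd` (1.5/0.3
#' µm/min), `frame_interval` (1 min), `position_noise_sd` (0.05 µm),
#' `spindle_length` (12 µm), `polar_dist_min`/`polar_dist_max`
#' (U(0.5, 2) µm placement from the pole), intensity parameters
#' (`kappa_pole` 1000, `i_base` 50, `beta_kc` 500,
#' `reference_mean`/`reference_sd` 200/20,
#' `background_mean`/`background_sd` 30/5, `noise_cv_pole` 0.05,
#' `noise_cv_kc` 0.10), `t_nebd` (0), `t_bipolarization` (10),
#' `t_anaphase_control` (60), `t_window` (120), `t_drug` (NA = never)
#' and `t_fixation_after_drug` (8 min).
#'
#' @return A list of class `spindle_preset`.
#' @examples
#' p <- spindle_preset("cenpe_inhibited_1v0")
#' p$centriole_config
#' @export
spindle_preset <- function(name, ...) {
  base <- list(
    name = name,
    centriole_config = c(2L, 2L),
    cenpe_active = TRUE,
    aurora_attenuation = 1,
    n_pairs_total = 23L,
    lambda_polar_per_pole = 4,
    gradient_sd = 1.5,
    pole_amplitude = 1,
    acentriolar_factor = 0.25,
    hazard_threshold = 0.4,
    h_max = 0.55,
    speed_mean = 1.5,
    speed_sd = 0.3,
    frame_interval = 1,
    position_noise_sd = 0.05,
    spindle_length = 12,
    polar_dist_min = 0.5,
    polar_dist_max = 2,
    kappa_pole = 1000,
    i_base = 50,
    beta_kc = 500,
    reference_mean = 200,
    reference_sd = 20,
    background_mean = 30,
    background_sd = 5,
    noise_cv_pole = 0.05,
    noise_cv_kc = 0.10,
    t_nebd = 0,
    t_bipolarization = 10,
    t_anaphase_control = 60,
    t_window = 120,
    t_drug = NA_real_,
    t_fixation_after_drug = 8
  )
  known <- list(
    control_2v2 = list(centriole_config = c(2L, 2L), cenpe_active = TRUE),
    control_1v1 = list(centriole_config = c(1L, 1L), cenpe_active = TRUE),
    control_1v0 = list(centriole_config = c(1L, 0L), cenpe_active = TRUE),
    control_0v0 = list(centriole_config = c(0L, 0L), cenpe_active = TRUE),
    cenpe_inhibited_2v2 = list(centriole_config = c(2L, 2L),
                               cenpe_active = FALSE),
    cenpe_inhibited_1v1 = list(centriole_config = c(1L, 1L),
                               cenpe_active = FALSE),
    cenpe_inhibited_1v0 = list(centriole_config = c(1L, 0L),
                               cenpe_active = FALSE),
    cenpe_inhibited_0v0 = list(centriole_config = c(0L, 0L),
                               cenpe_active = FALSE),
    cenpe_inhibited_2v2_auroraA_inhibited = list(
      centriole_config = c(2L, 2L), cenpe_active = FALSE,
      aurora_attenuation = 0.5, t_drug = 15)
  )
  if (!name %in% names(known)) {
    stop("unknown preset '", name, "'; known presets: ",
         paste(names(known), collapse = ", "), call. = FALSE)
  }
  preset <- utils::modifyList(base, known[[name]])
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(base))
    if (length(bad)) {
      stop("unknown preset fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    preset <- utils::modifyList(preset, dots)
  }
  validate_preset(preset)
}

#' @rdname spindle_preset
#' @export
preset_names <- function() {
  c("control_2v2", "control_1v1", "control_1v0", "control_0v0",
    "cenpe_inhibited_2v2", "cenpe_inhibited_1v1", "cenpe_inhibited_1v0",
    "cenpe_inhibited_0v0", "cenpe_inhibited_2v2_auroraA_inhibited")
}

validate_preset <- function(p) {
  pos <- c("lambda_polar_per_pole", "gradient_sd", "pole_amplitude",
           "hazard_threshold", "h_max", "speed_mean", "frame_interval",
           "spindle_length", "kappa_pole", "beta_kc", "reference_mean",
           "polar_dist_min", "polar_dist_max")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) {
      stop("preset field '", f, "' must be positive", call. = FALSE)
    }
  }
  if (p$acentriolar_factor <= 0 || p$acentriolar_factor > 1) {
    stop("acentriolar_factor must lie in (0, 1]", call. = FALSE)
  }
  if (p$aurora_attenuation <= 0 || p$aurora_attenuation > 1) {
    stop("aurora_attenuation must lie in (0, 1]", call. = FALSE)
  }
  if (!all(p$centriole_config %in% 0:2) ||
      length(p$centriole_config) != 2) {
    stop("centriole_config must be two counts in {0, 1, 2}", call. = FALSE)
  }
  structure(p, class = "spindle_preset")
}

#' Aurora A activity gradient
#'
#' Gaussian fall-off of pole-centred Aurora A activity with distance:
#' `A(d) = A_pole * exp(-d^2 / (2 sigma^2))`. With the default sigma of
#' 1.5 µm the activity drops below 14% of its pole value beyond 3 µm,
#' giving the gradient its ~3 µm working radius.
#'
#' @param d Distance from the pole centre, µm (vectorized, >= 0).
#' @param a_pole Activity amplitude at the pole.
#' @param sigma Gradient length scale, µm.
#' @return Activity (same units as `a_pole`).
#' @examples
#' aurora_activity(1, 1, 1.5) # 0.8007
#' @export
aurora_activity <- function(d, a_pole, sigma) {
  stopifnot(all(d >= 0), sigma > 0)
  a_pole * exp(-d^2 / (2 * sigma^2))
}

#' Congression-initiation hazard
#'
#' Per-minute rate at which a polar kinetochore pair initiates
#' congression. With CENP-E active the motor bypasses the gradient and
#' the hazard is `h_max` everywhere. Without CENP-E the hazard is
#' suppressed in proportion to local Aurora A activity:
#' `h(d) = h_max * max(0, 1 - alpha * A(d) / hazard_threshold)`,
#' with pole amplitude `pole_amplitude` at a centriolar nearest pole and
#' `acentriolar_factor * pole_amplitude` at an acentriolar one. The
#' hazard is therefore zero wherever attenuated activity exceeds the
#' threshold — within ~2 µm of a centriolar pole at the default
#' parameters — and non-decreasing in distance from the pole.
#'
#' @param d Distance to the nearest pole centre, µm (vectorized).
#' @param preset A [spindle_preset()].
#' @param centriolar Logical (vectorized): does the nearest pole carry at
#'   least one centriole?
#' @param alpha Aurora attenuation in force at the evaluated time;
#'   defaults to the preset's `aurora_attenuation`.
#' @return Hazard, per minute.
#' @examples
#' p <- spindle_preset("cenpe_inhibited_1v0")
#' initiation_hazard(1, p, centriolar = TRUE)  # 0 (gradient above threshold)
#' initiation_hazard(1, p, centriolar = FALSE) # 0.2748
#' @export
initiation_hazard <- function(d, preset, centriolar,
                              alpha = preset$aurora_attenuation) {
  n <- max(length(d), length(centriolar))
  if (preset$cenpe_active) {
    return(rep(preset$h_max, length.out = n))
  }
  a_pole <- ifelse(centriolar, preset$pole_amplitude,
                   preset$acentriolar_factor * preset$pole_amplitude)
  a <- aurora_activity(d, a_pole, preset$gradient_sd)
  preset$h_max * pmax(0, 1 - alpha * a / preset$hazard_threshold)
}

# Inverts the cumulative hazard for one pair: hazard h1 holds from
# t_bipolarization until t_drug, h2 afterwards (h2 = h1 when there is no
# drug switch). e is a unit-rate exponential draw. Returns the initiation
# time, possibly Inf.
sample_initiation_time <- function(e, t_bip, t_drug, h1, h2) {
  if (is.na(t_drug) || t_drug <= t_bip) {
    h <- if (is.na(t_drug)) h1 else h2
    return(if (h > 0) t_bip + e / h else Inf)
  }
  budget1 <- h1 * (t_drug - t_bip)
  if (h1 > 0 && e <= budget1) return(t_bip + e / h1)
  e2 <- e - budget1
  if (h2 > 0) t_drug + e2 / h2 else Inf
}

#' Simulate one mitotic cell
#'
#' Draws the number of initially-polar kinetochore pairs per pole from a
#' Poisson distribution (capped so the total never exceeds
#' `n_pairs_total`), places them at a uniform 3D distance from their pole
#' within a plate-facing cone, starts the remaining pairs at the
#' metaphase plate, samples each polar pair's congression-initiation time
#' from its distance-dependent hazard (piecewise constant in time: the
#' Aurora attenuation switches at the preset's drug-addition time), and
#' moves initiated pairs along the spindle axis toward the equatorial
#' plane at a per-pair constant speed until they reach it. Positions are
#' simulated in 3D and projected to 2D; the emitted tracks carry
#' isotropic Gaussian observation noise. The spindle elongates linearly
#' from half to full length between NEBD and bipolarization and is
#' stationary afterwards. Identical `(preset, seed)` give identical
#' output.
#'
#' @param preset A [spindle_preset()].
#' @param seed Integer seed.
#' @return A list of class `spindle_sim`: `cell` (a [cell_record()] with
#'   observed 2D tracks), `truth` (ground-truth tibble: placement
#'   distance, nearest pole, initiation time, speed, true final 3D
#'   midpoint) and `preset`.
#' @export
simulate_cell <- function(preset, seed) {
  stopifnot(inherits(preset, "spindle_preset"))
  set.seed(as.integer(seed))
  p <- preset

  dt <- p$frame_interval
  t_fix <- if (!is.na(p$t_drug)) p$t_drug + p$t_fixation_after_drug
  else NA_real_
  t_anaphase <- if (p$cenpe_active && is.na(t_fix)) p$t_anaphase_control
  else NA_real_
  t_end <- if (!is.na(t_fix)) t_fix
  else if (!is.na(t_anaphase)) t_anaphase
  else p$t_window
  times <- seq(p$t_nebd, t_end, by = dt)
  nt <- length(times)

  half <- p$spindle_length / 2
  elong <- pmin(1, pmax(0, (times - p$t_nebd) /
                          (p$t_bipolarization - p$t_nebd)))
  half_t <- half / 2 + (half / 2) * elong
  pole_x <- cbind(-half_t, half_t) # columns: P1 (left), P2 (right)

  n_pol <- stats::rpois(2, p$lambda_polar_per_pole)
  while (sum(n_pol) > p$n_pairs_total) {
    i <- which.max(n_pol)
    n_pol[i] <- n_pol[i] - 1L
  }
  n_aligned <- p$n_pairs_total - sum(n_pol)

  pole_ids <- c("P1", "P2")
  centriolar <- p$centriole_config >= 1

  pair_rows <- list()
  truth_rows <- list()
  pair_no <- 0L

  # polar kinetochores are only resolvable individually once the spindle
  # has bipolarized, so their tracks commence at t_bipolarization;
  # plate pairs are tracked from the first frame
  idx_polar <- which(times >= p$t_bipolarization - 1e-9)

  emit_pair <- function(pair_id, mx, my, idx = seq_len(nt)) {
    n <- length(idx)
    noise <- function() stats::rnorm(n, 0, p$position_noise_sd)
    tibble::new_tibble(list(
      pair_id = rep(pair_id, n),
      frame_index = idx - 1L,
      time_min = times[idx],
      x1_um = mx[idx] - 0.45 + noise(), y1_um = my[idx] + noise(),
      x2_um = mx[idx] + 0.45 + noise(), y2_um = my[idx] + noise()
    ), nrow = n)
  }

  for (pole in 1:2) {
    np <- n_pol[pole]
    if (np == 0) next
    sgn <- if (pole == 1) 1 else -1 # plate-facing direction along x
    for (k in seq_len(np)) {
      pair_no <- pair_no + 1L
      pid <- sprintf("K%02d", pair_no)
      d <- stats::runif(1, p$polar_dist_min, p$polar_dist_max)
      theta <- stats::runif(1, -75, 75) * pi / 180
      phi <- stats::runif(1, -20, 20) * pi / 180
      off <- d * c(sgn * cos(phi) * cos(theta),
                   cos(phi) * sin(theta),
                   sin(phi))
      h1 <- initiation_hazard(d, p, centriolar[pole], alpha = 1)
      h2 <- initiation_hazard(d, p, centriolar[pole])
      t_init <- sample_initiation_time(stats::rexp(1), p$t_bipolarization,
                                       p$t_drug, h1, h2)
      v <- max(0.3, stats::rnorm(1, p$speed_mean, p$speed_sd))

      mx <- pole_x[, pole] + off[1]
      my <- rep(off[2], nt)
      moving <- times > t_init
      x_start <- pole_x[nt, pole] + off[1]
      if (any(moving)) {
        trav <- v * (times[moving] - t_init)
        mx[moving] <- x_start + sgn * pmin(trav, abs(x_start))
      }
      x_end <- if (t_end > t_init) {
        x_start + sgn * min(v * (t_end - t_init), abs(x_start))
      } else {
        x_start
      }

      pair_rows[[pair_no]] <- emit_pair(pid, mx, my, idx_polar)
      truth_rows[[pair_no]] <- list(
        pair_id = pid, initially_polar = TRUE,
        own_pole = pole_ids[pole], own_pole_centriolar = centriolar[pole],
        d_init = d, t_initiation = t_init, speed = v,
        x_end = x_end, y_end = off[2], z_end = off[3]
      )
    }
  }

  for (k in seq_len(n_aligned)) {
    pair_no <- pair_no + 1L
    pid <- sprintf("K%02d", pair_no)
    x0 <- stats::rnorm(1, 0, 0.4)
    y0 <- stats::runif(1, -3, 3)
    z0 <- stats::rnorm(1, 0, 0.5)
    pair_rows[[pair_no]] <- emit_pair(pid, rep(x0, nt), rep(y0, nt))
    truth_rows[[pair_no]] <- list(
      pair_id = pid, initially_polar = FALSE,
      own_pole = NA_character_, own_pole_centriolar = NA,
      d_init = NA_real_, t_initiation = NA_real_, speed = NA_real_,
      x_end = x0, y_end = y0, z_end = z0
    )
  }

  pole_noise <- function() stats::rnorm(nt, 0, p$position_noise_sd)
  pole_tracks <- dplyr::bind_rows(
    tibble::tibble(
      pole_id = "P1", centriole_count = p$centriole_config[1],
      frame_index = seq_len(nt) - 1L, time_min = times,
      x_um = pole_x[, 1] + pole_noise(), y_um = pole_noise()
    ),
    tibble::tibble(
      pole_id = "P2", centriole_count = p$centriole_config[2],
      frame_index = seq_len(nt) - 1L, time_min = times,
      x_um = pole_x[, 2] + pole_noise(), y_um = pole_noise()
    )
  )

  cell_id <- sprintf("%s_s%d", p$name, as.integer(seed))
  cell <- cell_record(
    cell_id = cell_id,
    condition_label = p$name,
    pole_tracks = pole_tracks,
    pair_tracks = dplyr::bind_rows(pair_rows),
    t_nebd = p$t_nebd,
    t_bipolarization = p$t_bipolarization,
    t_anaphase_onset = t_anaphase
  )
  col <- function(f, mode) vapply(truth_rows, `[[`, mode, f)
  truth <- tibble::new_tibble(list(
    pair_id = col("pair_id", character(1)),
    initially_polar = col("initially_polar", logical(1)),
    own_pole = col("own_pole", character(1)),
    own_pole_centriolar = col("own_pole_centriolar", logical(1)),
    d_init = col("d_init", numeric(1)),
    t_initiation = col("t_initiation", numeric(1)),
    speed = col("speed", numeric(1)),
    x_end = col("x_end", numeric(1)),
    y_end = col("y_end", numeric(1)),
    z_end = col("z_end", numeric(1))
  ), nrow = length(truth_rows))
  truth$cell_id <- cell_id
  truth$seed <- as.integer(seed)

  structure(list(cell = cell, truth = truth, preset = p,
                 times = times, t_end = t_end),
            class = "spindle_sim")
}

#' @export
print.spindle_sim <- function(x, ...) {
  cat(sprintf("<spindle_sim> preset %s, seed %d: %d pairs (%d polar), %d frames\n",
              x$preset$name, x$truth$seed[1], nrow(x$truth),
              sum(x$truth$initially_polar), length(x$times)))
  invisible(x)
}

# Noiseless per-pair geometry of the simulated cell at its final frame,
# from the ground-truth state: projected (2D) distances as the analysis
# would measure them, plus the true 3D distance to the nearest pole that
# drives the intensity model.
final_frame_geometry <- function(sim) {
  p <- sim$preset
  half <- p$spindle_length / 2
  tr <- sim$truth

  mx <- tr$x_end
  my <- tr$y_end
  mz <- tr$z_end
  da2 <- sqrt((mx + half)^2 + my^2)
  db2 <- sqrt((mx - half)^2 + my^2)
  da3 <- sqrt((mx + half)^2 + my^2 + mz^2)
  db3 <- sqrt((mx - half)^2 + my^2 + mz^2)
  nearest_a <- da2 <= db2
  centriolar <- p$centriole_config >= 1

  tibble::tibble(
    pair_id = tr$pair_id,
    mx = mx, my = my,
    dist_plane = abs(mx),
    dist_center = sqrt(mx^2 + my^2),
    dist_pole_near = pmin(da2, db2),
    dist_pole_near_3d = ifelse(nearest_a, da3, db3),
    sister_dist_plane_min = pmin(abs(mx - 0.45), abs(mx + 0.45)),
    nearest_pole_id = ifelse(nearest_a, "P1", "P2"),
    nearest_centriolar = ifelse(nearest_a, centriolar[1], centriolar[2])
  )
}

#' Simulate immunofluorescence intensity samples for one cell
#'
#' Emulates the fixed-cell intensity readouts on the simulated cell at
#' its final frame: one pole sample per spindle pole with mean signal
#' `kappa_pole * A_pole * (1 + eps)`, and one kinetochore-pair sample per
#' pair with mean `i_base + beta_kc * alpha * A(d) * (1 + eps)`, where
#' `d` is the pair's true 3D distance to its nearest pole and `A` that
#' pole's Aurora gradient. Cytoplasmic background is added to the raw
#' signal and reported separately, so background subtraction recovers the
#' clean signal; the reference (CENP-A) channel is drawn per kinetochore
#' pair. Location classes come from the congression classification of the
#' noiseless projected geometry.
#'
#' @param sim A `spindle_sim` from [simulate_cell()].
#' @param seed Integer seed.
#' @param channel Channel label for the kinetochore samples, default
#'   `"pKnl1"`.
#' @param cfg An [analysis_config()] (for the location classes).
#' @return A tibble of intensity samples (one row per ROI) with columns
#'   `cell_id`, `roi_id`, `channel`, `roi_kind`, `mean_signal`,
#'   `background_mean`, `reference_mean`, `n_z_planes`, `location_class`,
#'   `dist_to_nearest_pole`, `dist_to_plane`.
#' @export
simulate_intensities <- function(sim, seed, channel = "pKnl1",
                                 cfg = analysis_config()) {
  stopifnot(inherits(sim, "spindle_sim"))
  set.seed(as.integer(seed))
  p <- sim$preset
  cell_id <- sim$cell$cell_id
  centriolar <- p$centriole_config >= 1
  pole_ids <- c("P1", "P2")

  n_pole <- 2L
  final <- final_frame_geometry(sim)
  n_kc <- nrow(final)

  draw <- function(n, mu, sd) if (sd > 0) stats::rnorm(n, mu, sd)
  else rep(mu, n)
  mult <- function(n, cv) if (cv > 0) 1 + stats::rnorm(n, 0, cv)
  else rep(1, n)

  a_pole <- ifelse(centriolar, p$pole_amplitude,
                   p$acentriolar_factor * p$pole_amplitude)
  bg_pole <- pmax(0, draw(n_pole, p$background_mean, p$background_sd))
  sig_pole <- p$kappa_pole * a_pole * mult(n_pole, p$noise_cv_pole)
  poles <- tibble::tibble(
    cell_id = cell_id,
    roi_id = paste0("pole_", pole_ids),
    channel = "pAurA",
    roi_kind = "pole",
    mean_signal = sig_pole + bg_pole,
    background_mean = bg_pole,
    reference_mean = NA_real_,
    n_z_planes = 16L,
    location_class = ifelse(centriolar, "pole_centriolar",
                            "pole_acentriolar"),
    dist_to_nearest_pole = 0,
    dist_to_plane = p$spindle_length / 2
  )

  cls <- classify_pair(final, cfg)
  a_near <- ifelse(final$nearest_centriolar, p$pole_amplitude,
                   p$acentriolar_factor * p$pole_amplitude)
  act <- aurora_activity(final$dist_pole_near_3d, a_near, p$gradient_sd)
  bg_kc <- pmax(0, draw(n_kc, p$background_mean, p$background_sd))
  sig_kc <- (p$i_base + p$beta_kc * p$aurora_attenuation * act) *
    mult(n_kc, p$noise_cv_kc)
  kcs <- tibble::tibble(
    cell_id = cell_id,
    roi_id = final$pair_id,
    channel = channel,
    roi_kind = "kinetochore_pair",
    mean_signal = sig_kc + bg_kc,
    background_mean = bg_kc,
    reference_mean = pmax(0, draw(n_kc, p$reference_mean, p$reference_sd)),
    n_z_planes = 16L,
    location_class = cls,
    dist_to_nearest_pole = final$dist_pole_near,
    dist_to_plane = final$dist_plane
  )
  dplyr::bind_rows(poles, kcs)
}

#' Simulate a cohort of cells
#'
#' Runs [simulate_cell()] (and optionally [simulate_intensities()]) for
#' `n_cells` cells, with per-cell child seeds derived deterministically
#' from `root_seed`. Two cohorts with the same preset and root seed are
#' identical.
#'
#' @param preset A [spindle_preset()].
#' @param n_cells Number of cells, >= 1.
#' @param root_seed Integer root seed.
#' @param with_intensities Also draw per-cell intensity samples
#'   (default TRUE).
#' @param channel Channel label passed to [simulate_intensities()].
#' @return A list of class `spindle_cohort`: `cells` (list of
#'   [cell_record()]), `sims` (list of `spindle_sim`), `truth` (bound
#'   ground-truth tibble), `intensities` (bound tibble or NULL) and
#'   `manifest` (preset name, parameter hash, seeds, n_cells).
#' @export
simulate_experiment <- function(preset, n_cells, root_seed,
                                with_intensities = TRUE,
                                channel = "pKnl1") {
  stopifnot(inherits(preset, "spindle_preset"), n_cells >= 1)
  set.seed(as.integer(root_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_cells)
  cell_seeds <- seeds[seq_len(n_cells)]
  int_seeds <- seeds[n_cells + seq_len(n_cells)]

  sims <- lapply(seq_len(n_cells), function(i) {
    simulate_cell(preset, cell_seeds[i])
  })
  intensities <- NULL
  if (with_intensities) {
    intensities <- dplyr::bind_rows(lapply(seq_len(n_cells), function(i) {
      simulate_intensities(sims[[i]], int_seeds[i], channel = channel)
    }))
  }
  manifest <- list(
    preset = preset$name,
    preset_hash = rlang::hash(unclass(preset)),
    root_seed = as.integer(root_seed),
    n_cells = as.integer(n_cells),
    cell_seeds = as.integer(cell_seeds),
    intensity_seeds = as.integer(int_seeds),
    channel = channel
  )
  structure(
    list(cells = lapply(sims, `[[`, "cell"),
         sims = sims,
         truth = dplyr::bind_rows(lapply(sims, `[[`, "truth")),
         intensities = intensities,
         manifest = manifest),
    class = "spindle_cohort"
  )
}
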