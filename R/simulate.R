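#' Condition preset for the congression simulator
#'
#' Each experimental condition (e.g. motor reactivated vs continuously
#' inhibited) is encoded phenomenologically by the rate at which polar
#' pairs initiate congression and by how long the checkpoint-signal decay
#' leads the fast movement; the movement itself (fast-phase speed, slow
#' drift, measurement noise) is condition-invariant by default, encoding
#' the observation that perturbing the motor changes whether congression
#' starts, not how fast pairs move once it has started.
#'
#' @param lambda_init 1/min; rate of the exponential congression-initiation
#'   delay.
#' @param v_fast um/min; typical fast-phase speed toward the plate.
#' @param v_slow um/min; slow drift toward the plate before initiation.
#' @param sigma_noise um; sd of positional measurement noise per frame.
#' @param tau_pre minutes; lead of checkpoint-signal decay before the fast
#'   movement starts.
#' @return A list of class `condition_preset`.
#' @export
condition_preset <- function(lambda_init, v_fast = 0.8, v_slow = 0.05,
                             sigma_noise = 0.1, tau_pre = 2) {
  if (lambda_init < 0 || v_fast <= 0 || v_slow < 0 || sigma_noise < 0)
    stop("invalid condition parameters", call. = FALSE)
  structure(list(lambda_init = lambda_init, v_fast = v_fast, v_slow = v_slow,
                 sigma_noise = sigma_noise, tau_pre = tau_pre),
            class = "condition_preset")
}

#' Configuration of the synthetic congression experiment
#'
#' Defaults describe a generic human-cell spindle imaged every minute for
#' an hour: 12-um pole separation, mostly polar pairs starting 1-3 um from
#' a pole, biphasic center motion (slow drift, then near-constant fast
#' movement to the plate after an exponential initiation delay),
#' interkinetochore distance rising logistically from its lateral to its
#' bioriented value around initiation, sister axis reorienting toward the
#' spindle axis after initiation, and a checkpoint-like intensity that
#' starts decaying `tau_pre` minutes before fast movement (slow decay for
#' pairs that never initiate). Per-pair fast speeds and decay rates are
#' lognormal with correlation `rho`, which is what couples movement speed
#' to signal loss.
#'
#' @param n_cells Cells per condition.
#' @param pairs_per_cell Kinetochore pairs per cell.
#' @param polar_fraction Fraction of pairs that start polar.
#' @param spindle_length um; pole separation.
#' @param elongation_rate um/min; optional linear spindle elongation from
#'   `spindle_start` up to `spindle_length` (0 = fixed length).
#' @param spindle_start um; initial pole separation when elongating.
#' @param dt minutes; frame interval.
#' @param duration minutes; imaging duration.
#' @param conditions Named list of [condition_preset()]s.
#' @param delta_lat,delta_bio um; interkinetochore distance when lateral /
#'   bioriented.
#' @param rise_time minutes; width of the interkinetochore distance rise.
#' @param mad2_i0 a.u.; initial checkpoint intensity.
#' @param mad2_k_fast,mad2_k_slow 1/min; decay rates after initiation and
#'   for never-initiating pairs.
#' @param mad2_cv Coefficient of variation of multiplicative measurement
#'   noise on intensities.
#' @param rho Correlation between per-pair log fast speed and log decay
#'   rate, in \[-1, 1\].
#' @param sigma_v,sigma_k Lognormal sd (log scale) of per-pair fast speed
#'   and decay rate.
#' @param master_seed Integer master seed; every cell/pair derives its own
#'   substream from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 10, pairs_per_cell = 6,
                              polar_fraction = 0.75,
                              spindle_length = 12, elongation_rate = 0,
                              spindle_start = spindle_length,
                              dt = 1, duration = 60,
                              conditions = list(
                                reactivated = condition_preset(0.1),
                                inhibited = condition_preset(0.01)),
                              delta_lat = 0.6, delta_bio = 1.1,
                              rise_time = 4,
                              mad2_i0 = 1, mad2_k_fast = 0.15,
                              mad2_k_slow = 0.02, mad2_cv = 0.1,
                              rho = 0.8, sigma_v = 0.2, sigma_k = 0.3,
                              master_seed = 1L) {
  stopifnot(n_cells >= 1, pairs_per_cell >= 1,
            polar_fraction >= 0, polar_fraction <= 1,
            spindle_length > 0, dt > 0, duration > 0,
            delta_bio >= delta_lat, rise_time > 0,
            rho >= -1, rho <= 1)
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be a named list", call. = FALSE)
  structure(list(n_cells = n_cells, pairs_per_cell = pairs_per_cell,
                 polar_fraction = polar_fraction,
                 spindle_length = spindle_length,
                 elongation_rate = elongation_rate,
                 spindle_start = spindle_start,
                 dt = dt, duration = duration, conditions = conditions,
                 delta_lat = delta_lat, delta_bio = delta_bio,
                 rise_time = rise_time,
                 mad2_i0 = mad2_i0, mad2_k_fast = mad2_k_fast,
                 mad2_k_slow = mad2_k_slow, mad2_cv = mad2_cv,
                 rho = rho, sigma_v = sigma_v, sigma_k = sigma_k,
                 master_seed = as.integer(master_seed)),
            class = "simulation_config")
}

#' @keywords internal
substream_seed <- function(master, cell_index, pair_index = 0L, salt = 0L) {
  # deterministic 31-bit substream per (cell, pair); any pair is
  # reproducible in isolation
  s <- (as.double(master) %% 65521) * 31013 +
    cell_index * 4099 + pair_index * 127 + salt * 17
  as.integer(s %% 2147483647)
}

#' Simulate one cell
#'
#' Generates pole and sister-kinetochore trajectories for a single cell
#' under one condition, together with the per-pair ground truth. The
#' spindle is built along the x axis and the whole cell is then given a
#' random in-plane rotation and translation, so downstream geometry is
#' exercised in a general frame. Trajectories are projected-2D (z = 0).
#'
#' @param config A [simulation_config()].
#' @param condition Name of a condition in `config$conditions`.
#' @param cell_index 1-based cell index (determines the random substream).
#' @return List with `tracks` (tibble in the trajectory-table schema) and
#'   `truth` (per-pair ground truth tibble).
#' @export
simulate_cell <- function(config, condition, cell_index) {
  if (!condition %in% names(config$conditions))
    stop("unknown condition label: ", condition, call. = FALSE)
  cp <- config$conditions[[condition]]
  cell_id <- sprintf("%s_c%03d", condition, cell_index)
  times <- seq(0, config$duration, by = config$dt)
  frames <- seq_along(times) - 1L
  nt <- length(times)

  # cell-level randomness: rigid frame + per-pair roles
  set.seed(substream_seed(config$master_seed, cell_index, 0L,
                          salt = match(condition, names(config$conditions))))
  ang <- stats::runif(1, 0, 2 * pi)
  shift <- stats::runif(2, -20, 20)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  n_polar <- round(config$pairs_per_cell * config$polar_fraction)
  is_polar_pair <- seq_len(config$pairs_per_cell) <= n_polar

  L_t <- pmin(config$spindle_length,
              config$spindle_start + config$elongation_rate * times)
  pole_ax <- -L_t / 2; pole_bx <- L_t / 2

  noise <- function(n) stats::rnorm(n, 0, cp$sigma_noise)

  truth <- list(); track_rows <- list()
  salt_c <- match(condition, names(config$conditions))
  for (j in seq_len(config$pairs_per_cell)) {
    set.seed(substream_seed(config$master_seed, cell_index, j, salt = salt_c))
    z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
    v_i <- cp$v_fast * exp(config$sigma_v * z1)
    k_i <- config$mad2_k_fast *
      exp(config$sigma_k * (config$rho * z1 + sqrt(1 - config$rho^2) * z2))
    if (is_polar_pair[j]) {
      pole <- if (stats::runif(1) < 0.5) "A" else "B"
      sgn <- if (pole == "A") 1 else -1   # inward direction along x
      d0 <- stats::runif(1, 1, 3)
      psi <- stats::runif(1, 0, 50) * pi / 180
      lat_sign <- sample(c(-1, 1), 1)
      Tinit <- stats::rexp(1, rate = max(cp$lambda_init, 1e-12))
      if (cp$lambda_init == 0) Tinit <- Inf
      a0 <- (if (pole == "A") pole_ax[1] else pole_bx[1]) + sgn * d0 * cos(psi)
      y0 <- lat_sign * d0 * sin(psi)
      a_final <- sgn * -1 * stats::runif(1, 0, 0.8) # resting plate position
      # axial coordinate: slow drift, then fast movement, then plate
      slow_phase <- times < Tinit
      a_slow <- a0 + sgn * cp$v_slow * times
      if (is.finite(Tinit)) {
        aT <- a0 + sgn * cp$v_slow * Tinit
        ai <- aT + sgn * v_i * (times - Tinit)
        # stop at the plate (|a| <= 1 um zone), rest at a_final
        a_fast <- ifelse(sgn * ai >= -1, a_final, ai)
        a <- ifelse(slow_phase, a_slow, a_fast)
        y <- ifelse(slow_phase, y0, y0 * exp(-(times - Tinit) / 5))
      } else {
        a <- a_slow
        y <- rep(y0, nt)
      }
      phi0 <- stats::runif(1, 40, 90)
      phi <- ifelse(times < Tinit, phi0, phi0 * exp(-(times - Tinit) / 3))
      dkt <- config$delta_lat + (config$delta_bio - config$delta_lat) /
        (1 + exp(-(times - Tinit) / (config$rise_time / 4)))
      if (!is.finite(Tinit)) dkt <- rep(config$delta_lat, nt)
    } else {
      pole <- NA_character_; d0 <- NA_real_; Tinit <- 0
      a <- stats::rnorm(1, 0, 0.4) + numeric(nt)
      y <- stats::runif(1, -3, 3) + numeric(nt)
      phi <- rep(stats::runif(1, 0, 20), nt)
      dkt <- rep(config$delta_bio, nt)
    }
    phi_sign <- sample(c(-1, 1), 1)
    dirx <- cos(phi * pi / 180)
    diry <- phi_sign * sin(phi * pi / 180)
    cxy <- cbind(a + noise(nt), y + noise(nt))
    s1 <- cxy - cbind(dirx, diry) * dkt / 2
    s2 <- cxy + cbind(dirx, diry) * dkt / 2
    s1 <- sweep(s1 %*% t(R), 2, -shift)
    s2 <- sweep(s2 %*% t(R), 2, -shift)
    truth[[j]] <- tibble::new_tibble(list(
      cell_id = cell_id, pair_id = j, condition = condition,
      polar = is_polar_pair[j], pole = pole, d0_um = d0,
      t_init_min = if (is_polar_pair[j]) Tinit else 0,
      v_fast_true = v_i, k_decay_true = k_i,
      seed = substream_seed(config$master_seed, cell_index, j,
                            salt = salt_c)), nrow = 1L)
    n2 <- 2L * nt
    track_rows[[j]] <- tibble::new_tibble(list(
      cell_id = rep(cell_id, n2), condition = rep(condition, n2),
      object_id = rep(sprintf("pair%02d_s%d", j, 1:2), each = nt),
      object_type = rep("kinetochore", n2),
      pair_id = rep(as.character(j), n2),
      sister = rep(1:2, each = nt),
      frame = rep(frames, 2), t_min = rep(times, 2),
      x_um = c(s1[, 1], s2[, 1]), y_um = c(s1[, 2], s2[, 2]),
      z_um = rep(0, n2)), nrow = n2)
  }
  # pole tracks share the cell's measurement noise level
  set.seed(substream_seed(config$master_seed, cell_index, 0L,
                          salt = salt_c + 1000L))
  pa <- cbind(pole_ax + noise(nt), noise(nt))
  pb <- cbind(pole_bx + noise(nt), noise(nt))
  pa <- sweep(pa %*% t(R), 2, -shift)
  pb <- sweep(pb %*% t(R), 2, -shift)
  n2 <- 2L * nt
  poles <- tibble::new_tibble(list(
    cell_id = rep(cell_id, n2), condition = rep(condition, n2),
    object_id = rep(c("pole_A", "pole_B"), each = nt),
    object_type = rep("pole", n2), pair_id = rep(NA_character_, n2),
    sister = rep(NA_integer_, n2),
    frame = rep(frames, 2), t_min = rep(times, 2),
    x_um = c(pa[, 1], pb[, 1]), y_um = c(pa[, 2], pb[, 2]),
    z_um = rep(0, n2)), nrow = n2)
  list(tracks = rbind(poles, do.call(rbind, track_rows)),
       truth = do.call(rbind, truth))
}

#' Simulate a checkpoint-protein intensity series for one pair
#'
#' Intensity stays at `mad2_i0` until `tau_pre` minutes before the pair's
#' initiation time, then decays exponentially at the pair's own rate; pairs
#' that never initiate within the recording decay slowly from the start.
#' Multiplicative lognormal measurement noise with the configured CV is
#' applied (mean-preserving).
#'
#' @param truth_row One row of the ground-truth table from
#'   [simulate_cell()].
#' @param config The [simulation_config()] used to simulate it.
#' @return Tibble with `t_min` and `intensity`.
#' @export
simulate_mad2 <- function(truth_row, config) {
  times <- seq(0, config$duration, by = config$dt)
  cp <- config$conditions[[truth_row$condition]]
  Tinit <- truth_row$t_init_min
  if (isTRUE(truth_row$polar) && Tinit <= config$duration) {
    tstart <- Tinit - cp$tau_pre
    I <- ifelse(times < tstart, config$mad2_i0,
                config$mad2_i0 * exp(-truth_row$k_decay_true *
                                       (times - tstart)))
  } else if (isTRUE(truth_row$polar)) {
    I <- config$mad2_i0 * exp(-config$mad2_k_slow * times)
  } else {
    # aligned pairs carry little checkpoint signal
    I <- config$mad2_i0 * 0.1 * exp(-config$mad2_k_slow * times)
  }
  if (config$mad2_cv > 0) {
    set.seed((truth_row$seed + 7L) %% 2147483647L)
    sdl <- sqrt(log(1 + config$mad2_cv^2))
    I <- I * exp(stats::rnorm(length(I), -sdl^2 / 2, sdl))
  }
  tibble::new_tibble(list(t_min = times, intensity = I),
                     nrow = length(times))
}

#' Simulate a full multi-condition experiment
#'
#' Runs [simulate_cell()] for every condition and cell index and
#' [simulate_mad2()] for every pair.
#'
#' @param config A [simulation_config()].
#' @return List with `tracks`, `truth` and `mad2` tibbles (`mad2` in long
#'   format keyed by `cell_id`, `pair_id`).
#' @export
simulate_experiment <- function(config) {
  tracks <- list(); truth <- list(); mad2 <- list()
  for (cond in names(config$conditions)) {
    for (ci in seq_len(config$n_cells)) {
      sim <- simulate_cell(config, cond, ci)
      tracks[[length(tracks) + 1]] <- sim$tracks
      truth[[length(truth) + 1]] <- sim$truth
      for (j in seq_len(nrow(sim$truth))) {
        m <- simulate_mad2(sim$truth[j, ], config)
        m$cell_id <- sim$truth$cell_id[j]
        m$pair_id <- sim$truth$pair_id[j]
        mad2[[length(mad2) + 1]] <- m
      }
    }
  }
  list(tracks = do.call(rbind, tracks), truth = do.call(rbind, truth),
       mad2 = do.call(rbind, mad2))
}

#' Render a synthetic two-channel kinetochore image stack
#'
#' Renders each kinetochore as a 3D Gaussian spot of programmed integrated
#' amplitude on a constant cytoplasmic background, optionally with Poisson
#' noise; the ground truth against which intensity quantification is
#' validated. Positions are in um with the origin at the field corner.
#'
#' @param positions Matrix (n x 3) of spot centers in um (z measured from
#'   the first plane).
#' @param amplitudes Matrix (n x n_channel) of integrated amplitudes
#'   (total counts per spot and channel); column names are channel names.
#' @param optics List: `nx`, `ny`, `nz` (field size), `pixel_size_xy` (um),
#'   `z_step` (um), `sigma_xy` (um), `sigma_z` (um), `background`
#'   (counts/voxel), `poisson` (logical).
#' @param seed Seed for the Poisson noise, if enabled.
#' @return An [image_stack()].
#' @export
render_stack <- function(positions, amplitudes, optics, seed = 1L) {
  positions <- as.matrix(positions)
  amplitudes <- as.matrix(amplitudes)
  channels <- colnames(amplitudes)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(amplitudes)))
  vox <- array(optics$background,
               dim = c(optics$ny, optics$nx, length(channels), optics$nz))
  sx <- optics$sigma_xy / optics$pixel_size_xy
  sz <- optics$sigma_z / optics$z_step
  xs <- seq_len(optics$nx); ys <- seq_len(optics$ny); zs <- seq_len(optics$nz)
  for (s in seq_len(nrow(positions))) {
    px <- positions[s, 1] / optics$pixel_size_xy + 0.5
    py <- positions[s, 2] / optics$pixel_size_xy + 0.5
    pz <- positions[s, 3] / optics$z_step + 0.5
    if (px < 1 || px > optics$nx || py < 1 || py > optics$ny) {
      warning("spot ", s, " lies outside the field; clipped")
      px <- min(max(px, 1), optics$nx)
      py <- min(max(py, 1), optics$ny)
    }
    pz <- min(max(pz, 1), optics$nz)
    wx <- stats::dnorm(xs, px, sx)
    wy <- stats::dnorm(ys, py, sx)
    wz <- stats::dnorm(zs, pz, sz)
    wz <- wz / sum(wz)   # few z planes: renormalize so flux is conserved
    spot <- outer(wy, wx)
    for (ch in seq_along(channels)) {
      A <- amplitudes[s, ch]
      if (A == 0) next
      for (k in zs) vox[, , ch, k] <- vox[, , ch, k] + A * wz[k] * spot
    }
  }
  if (isTRUE(optics$poisson)) {
    set.seed(seed)
    vox[] <- stats::rpois(length(vox), vox)
  }
  image_stack(vox, pixel_size_xy = optics$pixel_size_xy,
              z_step = optics$z_step, channels = channels)
}

#' Default optics for rendered stacks
#'
#' Confocal-like sampling: 0.1 um pixels, 0.5 um z step, PSF sd 0.2 um
#' laterally and 0.5 um axially, flat background of 20 counts.
#'
#' @param nx,ny,nz Field size in pixels/planes.
#' @param poisson Add Poisson noise.
#' @return Optics list for [render_stack()].
#' @export
default_optics <- function(nx = 64, ny = 64, nz = 5, poisson = FALSE) {
  list(nx = nx, ny = ny, nz = nz, pixel_size_xy = 0.1, z_step = 0.5,
       sigma_xy = 0.2, sigma_z = 0.5, background = 20, poisson = poisson)
}
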