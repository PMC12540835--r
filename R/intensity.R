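#' Multi-channel image stack container
#'
#' A light container for a 3D multi-channel fluorescence stack: a 4-D
#' array with dimensions (y, x, channel, z), pixel size in the imaging
#' plane and the z step, with named channels. Pixel indices are 1-based
#' with the origin at the top-left corner, x indexing columns and y rows.
#'
#' @param voxels Non-negative numeric 4-D array, dim (ny, nx, n_channel, nz).
#' @param pixel_size_xy um per pixel in the projection plane.
#' @param z_step um between z planes.
#' @param channels Character vector of unique channel names.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_xy, z_step,
                        channels = dimnames(voxels)[[3]]) {
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 4-D array (y, x, channel, z)", call. = FALSE)
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("voxel intensities must be finite and non-negative", call. = FALSE)
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(voxels)[3]))
  if (length(channels) != dim(voxels)[3] || anyDuplicated(channels))
    stop("channel names must be unique and match the channel dimension",
         call. = FALSE)
  dimnames(voxels)[[3]] <- channels
  structure(list(voxels = voxels, pixel_size_xy = pixel_size_xy,
                 z_step = z_step, channels = channels),
            class = "image_stack")
}

#' Sum intensity projection of one channel
#'
#' Pixel-wise sum of all z planes of the selected channel, the projection
#' on which integrated kinetochore intensities are measured. The number of
#' z planes that entered the sum is attached as attribute `n_z` and used
#' downstream to convert integrated intensities to per-plane means.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @return Numeric matrix (y, x) with attribute `n_z`.
#' @export
sum_projection <- function(stack, channel) {
  if (!channel %in% stack$channels)
    stop("unknown channel: ", channel, call. = FALSE)
  v <- stack$voxels[, , channel, , drop = FALSE]
  proj <- apply(v, c(1, 2), sum)
  attr(proj, "n_z") <- dim(stack$voxels)[4]
  proj
}

#' Seed-based kinetochore spot region
#'
#' Deterministic replacement for a manually drawn oval around a
#' kinetochore: within a window of radius `r_max` around the seed, pixels
#' at or above half of the local dynamic range (local peak minus local
#' floor) that are 8-connected to the seed form the region. If
#' thresholding yields fewer than 3 pixels (flat signal), a disk of radius
#' 2 px around the seed is used instead.
#'
#' @param projection Reference-channel projection (matrix, y rows, x cols).
#' @param seed Integer vector `c(x, y)` in 1-based pixel indices.
#' @param r_max Region radius cap in pixels. Default 6.
#' @return Logical matrix of the same size as `projection` (the mask).
#' @export
define_spot_region <- function(projection, seed, r_max = 6) {
  ny <- nrow(projection); nx <- ncol(projection)
  sx <- as.integer(round(seed[1])); sy <- as.integer(round(seed[2]))
  if (sx < 1 || sx > nx || sy < 1 || sy > ny)
    stop("seed lies outside the image", call. = FALSE)
  xs <- pmax(1, sx - r_max):pmin(nx, sx + r_max)
  ys <- pmax(1, sy - r_max):pmin(ny, sy + r_max)
  win <- projection[ys, xs, drop = FALSE]
  peak <- max(win); floor_ <- min(win)
  thr <- floor_ + 0.5 * (peak - floor_)
  within <- outer(ys, xs, function(yy, xx) (yy - sy)^2 + (xx - sx)^2) <= r_max^2
  # no local dynamic range (flat signal): fall through to the disk fallback
  cand <- if (peak > floor_) (win >= thr) & within else
    matrix(FALSE, nrow(win), ncol(win))
  mask <- matrix(FALSE, ny, nx)
  if (isTRUE(cand[match(sy, ys), match(sx, xs)])) {
    # flood fill (8-connectivity) from the seed within the candidate set
    lab <- matrix(FALSE, nrow(cand), ncol(cand))
    queue <- list(c(match(sy, ys), match(sx, xs)))
    lab[queue[[1]][1], queue[[1]][2]] <- TRUE
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      for (dy in -1:1) for (dx in -1:1) {
        yy <- q[1] + dy; xx <- q[2] + dx
        if (yy >= 1 && yy <= nrow(cand) && xx >= 1 && xx <= ncol(cand) &&
            cand[yy, xx] && !lab[yy, xx]) {
          lab[yy, xx] <- TRUE
          queue[[length(queue) + 1]] <- c(yy, xx)
        }
      }
    }
    mask[ys, xs] <- lab
  }
  if (sum(mask) < 3) {
    mask[, ] <- FALSE
    for (yy in pmax(1, sy - 2):pmin(ny, sy + 2))
      for (xx in pmax(1, sx - 2):pmin(nx, sx + 2))
        if ((yy - sy)^2 + (xx - sx)^2 <= 4) mask[yy, xx] <- TRUE
  }
  mask
}

#' Annular background region around a seed
#'
#' Cytoplasmic background region for synthetic data: an annulus around the
#' seed (inner radius 8 px, outer 12 px by default) minus any pixels in
#' `exclude` (e.g. neighbouring spot masks).
#'
#' @inheritParams define_spot_region
#' @param r_inner,r_outer Annulus radii in pixels.
#' @param exclude Optional logical mask of pixels to drop.
#' @return Logical mask matrix.
#' @export
annulus_background_region <- function(projection, seed, r_inner = 8,
                                      r_outer = 12, exclude = NULL) {
  ny <- nrow(projection); nx <- ncol(projection)
  sx <- round(seed[1]); sy <- round(seed[2])
  d2 <- outer(seq_len(ny), seq_len(nx),
              function(yy, xx) (yy - sy)^2 + (xx - sx)^2)
  mask <- d2 >= r_inner^2 & d2 <= r_outer^2
  if (!is.null(exclude)) mask <- mask & !exclude
  if (!any(mask)) stop("empty background region", call. = FALSE)
  mask
}

#' Background-corrected mean kinetochore intensity
#'
#' Integrated intensity over the spot region on the sum projection, minus
#' the mean per-pixel cytoplasmic background times the region area,
#' divided by the number of z planes of the projection:
#' `(sum(region) - mean(background) * area) / n_z`. Negative corrected
#' values are retained (not clipped) and flagged so group means stay
#' unbiased.
#'
#' @param projection Sum projection (matrix).
#' @param region Logical spot mask.
#' @param background Logical cytoplasm mask, disjoint from `region`.
#' @param n_z Number of z planes summed into the projection.
#' @param object_id Optional identifier carried through.
#' @return A one-row tibble: `object_id`, `raw_integrated`,
#'   `background_per_pixel`, `area_px`, `n_z`, `mean_intensity`,
#'   `negative_flag`.
#' @export
measure_kinetochore_intensity <- function(projection, region, background,
                                          n_z, object_id = NA_character_) {
  if (!any(region) || !any(background))
    stop("spot and background regions must be non-empty", call. = FALSE)
  if (any(region & background))
    stop("spot and background regions overlap", call. = FALSE)
  if (n_z < 1) stop("n_z must be >= 1", call. = FALSE)
  raw <- sum(projection[region])
  bg <- mean(projection[background])
  area <- sum(region)
  mi <- (raw - bg * area) / n_z
  tibble::tibble(object_id = object_id, raw_integrated = raw,
                 background_per_pixel = bg, area_px = area, n_z = n_z,
                 mean_intensity = mi, negative_flag = mi < 0)
}

#' Normalize a target intensity to a reference channel
#'
#' Ratio of the background-corrected target intensity to the
#' background-corrected reference intensity measured in the same region
#' (e.g. a checkpoint protein normalized to the centromere marker
#' CENP-A). The ratio cancels acquisition gain.
#'
#' @param target,reference Background-corrected mean intensities, either
#'   numeric or one-row records from [measure_kinetochore_intensity()].
#' @return Dimensionless ratio.
#' @export
normalize_to_reference <- function(target, reference) {
  tv <- if (is.data.frame(target)) target$mean_intensity else target
  rv <- if (is.data.frame(reference)) reference$mean_intensity else reference
  if (any(rv <= 0))
    stop("reference intensity must be positive", call. = FALSE)
  tv / rv
}

#' Within-cell normalization to the aligned kinetochore group
#'
#' Divides each kinetochore's reference-normalized intensity by the mean
#' over the aligned kinetochores of the same cell, and each pole distance
#' by the aligned group's mean pole distance. This puts cells with
#' different expression levels and spindle sizes on a common scale: an
#' aligned kinetochore averages 1 on both axes by construction.
#'
#' @param records Data frame with columns `cell_id`, `ref_ratio`, `d_pole`
#'   and logical `aligned`.
#' @return The input with `group_norm` and `d_pole_norm` columns added.
#' @export
normalize_within_cell_to_aligned <- function(records) {
  need <- c("cell_id", "ref_ratio", "d_pole", "aligned")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- records
  out$group_norm <- NA_real_
  out$d_pole_norm <- NA_real_
  for (cell in unique(records$cell_id)) {
    sel <- records$cell_id == cell
    al <- sel & records$aligned
    if (!any(al))
      stop("cell ", cell, " has no aligned kinetochores to normalize to",
           call. = FALSE)
    mr <- mean(records$ref_ratio[al])
    md <- mean(records$d_pole[al])
    if (mr <= 0)
      stop("cell ", cell, ": aligned group mean ratio is not positive",
           call. = FALSE)
    out$group_norm[sel] <- records$ref_ratio[sel] / mr
    out$d_pole_norm[sel] <- records$d_pole[sel] / md
  }
  out
}

#' Binned mean profile
#'
#' Equal-width binning of `y` over the range of `x`: per-bin mean,
#' standard deviation and count, as used for mean +/- sd profiles of
#' intensity versus distance. Empty bins are reported with `NA` mean/sd
#' and n = 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Number of equal-width bins over `[min(x), max(x)]`.
#' @return Tibble with `bin_center`, `mean`, `sd`, `n`.
#' @export
binned_profile <- function(x, y, n_bins) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < n_bins) stop("fewer points than bins", call. = FALSE)
  rng <- range(x)
  if (diff(rng) <= 0) stop("degenerate x range", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  m <- s <- rep(NA_real_, n_bins)
  n <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    yy <- y[idx == b]
    n[b] <- length(yy)
    if (n[b] > 0) m[b] <- mean(yy)
    if (n[b] > 1) s[b] <- stats::sd(yy)
    if (n[b] == 1) s[b] <- 0
  }
  tibble::tibble(bin_center = centers, mean = m, sd = s, n = n)
}

#' Checkpoint-signal loss over a time window
#'
#' Fractional loss of a kinetochore intensity series between `t0` and
#' `t1`: `(I(t0) - I(t1)) / I(t0)`. The nearest samples to each endpoint
#' are used. With `absolute = TRUE` the unnormalized difference
#' `I(t0) - I(t1)` is returned instead. An intensity that rises gives a
#' negative loss.
#'
#' @param t,intensity Numeric vectors: sample times (minutes) and
#'   intensities (arbitrary units).
#' @param t0,t1 Window endpoints (minutes).
#' @param absolute Return the absolute rather than fractional loss.
#' @return Dimensionless fractional loss (or a.u. if `absolute`).
#' @export
signal_loss <- function(t, intensity, t0, t1, absolute = FALSE) {
  i0 <- which.min(abs(t - t0)); i1 <- which.min(abs(t - t1))
  I0 <- intensity[i0]; I1 <- intensity[i1]
  if (absolute) return(I0 - I1)
  if (I0 <= 0) stop("intensity at t0 must be positive", call. = FALSE)
  (I0 - I1) / I0
}
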