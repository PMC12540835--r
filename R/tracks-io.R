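#' @keywords internal
tracks_schema <- c("cell_id", "object_id", "object_type", "pair_id",
                   "sister", "frame", "t_min", "x_um", "y_um")

#' Write a trajectory table to CSV
#'
#' One row per tracked object per frame, positions in um and time in
#' minutes, numeric columns written with 6 decimals. Columns: `cell_id`,
#' `object_id`, `object_type` (`pole`/`kinetochore`), `pair_id` (empty for
#' poles), `sister` (1/2, empty for poles), `frame` (0-based), `t_min`,
#' `x_um`, `y_um`, `z_um`. Missing frames are absent rows.
#'
#' @param tracks Trajectory tibble (e.g. from [simulate_cell()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  miss <- setdiff(tracks_schema, names(tracks))
  if (length(miss) > 0)
    stop("tracks table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- tracks
  if (is.null(out$z_um)) out$z_um <- 0
  for (col in c("t_min", "x_um", "y_um", "z_um"))
    out[[col]] <- round(out[[col]], 6)
  keep <- c(tracks_schema, "z_um",
            intersect("condition", names(out)))
  readr::write_csv(out[, keep], path)
  invisible(path)
}

#' Read a trajectory table from CSV
#'
#' Validates the schema of [write_tracks_csv()]; a missing mandatory
#' column is an error naming the column. Rows out of frame order within an
#' object are sorted with a warning. `z_um` is optional and read as 0 when
#' absent (projected-2D data).
#'
#' @param path CSV file.
#' @return Trajectory tibble.
#' @export
read_tracks_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          cell_id = readr::col_character(),
                          object_id = readr::col_character(),
                          object_type = readr::col_character(),
                          pair_id = readr::col_character(),
                          sister = readr::col_integer()))
  miss <- setdiff(tracks_schema, names(tr))
  if (length(miss) > 0)
    stop("tracks CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(tr$object_type %in% c("pole", "kinetochore")))
    stop("object_type must be 'pole' or 'kinetochore'", call. = FALSE)
  if (is.null(tr$z_um)) tr$z_um <- 0
  key <- paste(tr$cell_id, tr$object_id)
  ord <- order(key, tr$frame)
  by_obj <- split(tr$frame, key)
  if (any(vapply(by_obj, is.unsorted, logical(1), strictly = TRUE))) {
    warning("rows out of frame order; sorting per object")
    tr <- tr[ord, ]
  }
  tr
}

#' Write / read an image stack as multi-page TIFF
#'
#' Pages are written z-major then channel (page = (z-1)*n_channel +
#' channel index), as 32-bit floats. The geometry (`pixel_size_xy`,
#' `z_step`, channel names, `n_z`) is not stored in the TIFF and must be
#' supplied on read.
#'
#' @param stack An [image_stack()].
#' @param path TIFF file.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$voxels)
  pages <- list()
  for (z in seq_len(d[4])) for (ch in seq_len(d[3]))
    pages[[length(pages) + 1]] <- stack$voxels[, , ch, z]
  mx <- max(1, max(stack$voxels))
  pages <- lapply(pages, function(p) p / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  attr(path, "scale") <- mx
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param channels Channel names, in page order within each z.
#' @param pixel_size_xy,z_step Voxel geometry in um.
#' @param scale Intensity scale the stack was divided by on write (TIFF
#'   stores floats in \[0, 1\]).
#' @export
read_stack_tiff <- function(path, channels, pixel_size_xy, z_step,
                            scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(channels)
  if (length(pages) %% nc != 0)
    stop("page count is not a multiple of the channel count", call. = FALSE)
  nz <- length(pages) / nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  vox <- array(0, dim = c(ny, nx, nc, nz))
  k <- 1
  for (z in seq_len(nz)) for (ch in seq_len(nc)) {
    vox[, , ch, z] <- pages[[k]] * scale
    k <- k + 1
  }
  image_stack(vox, pixel_size_xy = pixel_size_xy, z_step = z_step,
              channels = channels)
}
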