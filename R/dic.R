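# Subset-based digital image correlation.
#
# Each video frame is matched against one fixed reference frame (the field
# of view at rest): for every subset center, the integer displacement
# maximizing the zero-normalized cross-correlation over a bounded search
# window is refined to subpixel precision by a parabolic fit to the 3x3
# correlation neighborhood of the peak. ZNCC is invariant to uniform
# brightness gain and offset, which is what bright-field contraction
# videos need. Flat (zero-variance) subsets are flagged invalid, never
# silently zero.

#' Build a regular subset grid
#'
#' Centers are laid out at `spacing_px` with margins trimmed so every
#' subset lies fully inside the image. Defaults follow common practice for
#' cell-scale contraction videos: 32-px subsets at 8-px spacing.
#'
#' @param image_shape `c(H, W)` in pixels.
#' @param subset_size_px square subset edge length.
#' @param spacing_px grid spacing (>= 1).
#' @return a `subset_grid` tibble with columns `point_id`, `row`, `col`
#'   (pixel coordinates of subset centers) and attributes
#'   `subset_size_px`, `spacing_px`, `image_shape`, `grid_dim`.
#' @examples
#' g <- build_grid(c(128, 128), 32, 8)
#' nrow(g)
#' @export
build_grid <- function(image_shape, subset_size_px = 32L, spacing_px = 8L) {
  H <- image_shape[1L]; W <- image_shape[2L]
  if (subset_size_px > min(H, W))
    stop_bad_arg("subset larger than the image")
  if (spacing_px < 1) stop_bad_arg("`spacing_px` must be >= 1")
  half <- subset_size_px %/% 2L
  # subset covers rows r - half .. r + (size - half) - 1; centers are kept
  # a full half-subset from every border
  r_min <- half + 1L
  r_max <- H - half
  c_min <- half + 1L
  c_max <- W - half
  if (r_max < r_min || c_max < c_min)
    stop_bad_arg("no valid subset centers for this geometry")
  rows <- seq(r_min, r_max, by = spacing_px)
  cols <- seq(c_min, c_max, by = spacing_px)
  grid <- tidyr::expand_grid(row = rows, col = cols)
  grid <- tibble::add_column(grid, point_id = seq_len(nrow(grid)),
                             .before = 1L)
  structure(grid,
            subset_size_px = as.integer(subset_size_px),
            spacing_px = as.integer(spacing_px),
            image_shape = as.integer(c(H, W)),
            grid_dim = c(length(rows), length(cols)),
            class = c("subset_grid", class(grid)))
}

#' Match one subset between two frames
#'
#' @param ref_frame,cur_frame numeric matrices of identical shape.
#' @param center subset center `c(row, col)` in pixels.
#' @param subset_size_px subset edge length.
#' @param search_radius_px maximum integer displacement searched in each
#'   direction.
#' @return one-row tibble `u_x`, `u_y` (pixels; `u_x` along +col, `u_y`
#'   image-up), `quality` (peak correlation in `[-1, 1]`), `valid`.
#'   Zero-variance subsets return `valid = FALSE` with `NA` displacements.
#' @export
match_subset <- function(ref_frame, cur_frame, center, subset_size_px = 32L,
                         search_radius_px = 10L) {
  stopifnot(all(dim(ref_frame) == dim(cur_frame)))
  m <- .dic_match_cpp(ref_frame, cur_frame,
                      as.integer(center[1L]), as.integer(center[2L]),
                      as.integer(subset_size_px), as.integer(search_radius_px))
  tibble::tibble(u_x = m[1L, 2L], u_y = -m[1L, 1L], quality = m[1L, 3L],
                 valid = is.finite(m[1L, 3L]))
}

#' Track a full stack against a fixed reference frame
#'
#' Every frame is matched against the single reference frame (no
#' frame-to-frame chaining, so there is no drift accumulation). Invalid
#' points (flat texture, failed match) carry `NA` displacements and
#' `valid = FALSE`.
#'
#' @param stack an [image_stack()].
#' @param grid a [build_grid()] result.
#' @param reference_frame_index frame used as the undeformed reference
#'   (default 1; pick a frame during diastole/relaxation).
#' @param search_radius_px integer search radius in pixels.
#' @return a `displacement_field` tibble: `frame`, `point_id`, `row`,
#'   `col`, `u_x`, `u_y` (pixels, y up), `u_x_um`, `u_y_um`, `quality`,
#'   `valid`; attributes carry the grid geometry and calibration.
#' @export
track_stack <- function(stack, grid, reference_frame_index = 1L,
                        search_radius_px = 10L) {
  stopifnot(inherits(stack, "image_stack"), inherits(grid, "subset_grid"))
  if (nrow(grid) == 0L) stop_bad_arg("empty subset grid")
  T_ <- n_frames(stack)
  if (reference_frame_index < 1L || reference_frame_index > T_)
    stop_bad_arg("`reference_frame_index` out of range")
  ref <- get_frame(stack, reference_frame_index)
  size <- attr(grid, "subset_size_px")
  pixel_um <- attr(stack, "pixel_um")
  res <- purrr::map(seq_len(T_), function(k) {
    m <- .dic_match_cpp(ref, get_frame(stack, k),
                        as.integer(grid$row), as.integer(grid$col),
                        as.integer(size), as.integer(search_radius_px))
    tibble::tibble(frame = k, point_id = grid$point_id,
                   row = grid$row, col = grid$col,
                   u_x = m[, 2L], u_y = -m[, 1L], quality = m[, 3L],
                   valid = is.finite(m[, 3L]))
  })
  out <- dplyr::bind_rows(res)
  out$u_x_um <- out$u_x * pixel_um
  out$u_y_um <- out$u_y * pixel_um
  structure(out,
            subset_size_px = size,
            spacing_px = attr(grid, "spacing_px"),
            grid_dim = attr(grid, "grid_dim"),
            image_shape = attr(grid, "image_shape"),
            pixel_um = pixel_um,
            frame_interval_s = attr(stack, "frame_interval_s"),
            reference_frame_index = as.integer(reference_frame_index),
            class = c("displacement_field", class(out)))
}
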