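# Pad layout of the PDMS stamp: a grid of square pads (pillars), each
# carrying one (DNA motif, reference duplex length) condition, imaged on a
# common field of view. Pixel coordinates are 0-based, pads are half-open
# rectangles [r0, r1) x [c0, c1).

#' Default pad conditions for a grid
#'
#' Cycles the six standard conditions — {no, low, high affinity} motifs
#' crossed with {20, 40 bp} shear references — over the pads in row-major
#' order, so a 4x4 grid holds each condition at least twice.
#'
#' @param grid_rows,grid_cols Grid dimensions.
#' @return Data frame with columns `row`, `col`, `motif_label`,
#'   `reference_n_bp` (one row per pad, row-major).
#' @export
default_pad_conditions <- function(grid_rows = 4, grid_cols = 4) {
  combos <- expand.grid(motif_label = c("high", "low", "no"),
                        reference_n_bp = c(20L, 40L),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_pads <- grid_rows * grid_cols
  idx <- ((seq_len(n_pads) - 1L) %% nrow(combos)) + 1L
  pads <- expand.grid(col = seq_len(grid_cols), row = seq_len(grid_rows),
                      KEEP.OUT.ATTRS = FALSE)[, c("row", "col")]
  data.frame(row = pads$row, col = pads$col,
             motif_label = combos$motif_label[idx],
             reference_n_bp = combos$reference_n_bp[idx])
}

#' Pad layout of the stamp on the image
#'
#' @param grid_rows,grid_cols Number of pad rows/columns (default 4x4, the
#'   stamp's 16 pillars).
#' @param pad_size_px Side length of each square pad in pixels.
#' @param pitch_px Centre-to-centre pad spacing in pixels; must be >=
#'   `pad_size_px` so pads do not overlap.
#' @param image_shape `(height, width)` in pixels; default leaves a
#'   half-pitch border around the grid.
#' @param offset_px `(row, col)` 0-based offset of the first pad's corner;
#'   default half a pitch.
#' @param pad_conditions Data frame as from [default_pad_conditions()].
#' @return An object of class `pad_layout`.
#' @examples
#' lay <- pad_layout()
#' lay$image_shape
#' @export
pad_layout <- function(grid_rows = 4, grid_cols = 4, pad_size_px = 48,
                       pitch_px = 64, image_shape = NULL, offset_px = NULL,
                       pad_conditions = NULL) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, pad_size_px >= 1,
            pitch_px >= 1)
  if (pad_size_px > pitch_px && (grid_rows > 1 || grid_cols > 1))
    stop("layout error: pads overlap (pad_size_px > pitch_px)")
  if (is.null(offset_px)) offset_px <- c(pitch_px, pitch_px) %/% 2L
  offset_px <- as.integer(rep(offset_px, length.out = 2L))
  if (is.null(image_shape)) {
    image_shape <- c(
      2L * offset_px[1] + (grid_rows - 1L) * pitch_px + pad_size_px,
      2L * offset_px[2] + (grid_cols - 1L) * pitch_px + pad_size_px)
  }
  image_shape <- as.integer(image_shape)
  last_r <- offset_px[1] + (grid_rows - 1L) * pitch_px + pad_size_px
  last_c <- offset_px[2] + (grid_cols - 1L) * pitch_px + pad_size_px
  if (last_r > image_shape[1] || last_c > image_shape[2])
    stop("layout error: pads do not fit inside image_shape")
  if (is.null(pad_conditions))
    pad_conditions <- default_pad_conditions(grid_rows, grid_cols)
  stopifnot(is.data.frame(pad_conditions),
            all(c("row", "col", "motif_label", "reference_n_bp") %in%
                  names(pad_conditions)),
            nrow(pad_conditions) == grid_rows * grid_cols)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 pad_size_px = as.integer(pad_size_px),
                 pitch_px = as.integer(pitch_px),
                 image_shape = image_shape,
                 offset_px = offset_px,
                 pad_conditions = pad_conditions),
            class = "pad_layout")
}

#' @export
print.pad_layout <- function(x, ...) {
  cat(sprintf("Pad layout: %dx%d pads of %d px (pitch %d px) on %dx%d image\n",
              x$grid_rows, x$grid_cols, x$pad_size_px, x$pitch_px,
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

# 0-based half-open pad rectangles, one row per pad (row-major order).
pad_rects <- function(layout) {
  pc <- layout$pad_conditions
  ord <- order(pc$row, pc$col)
  pc <- pc[ord, , drop = FALSE]
  data.frame(
    pad_id = sprintf("%d-%d", pc$row, pc$col),
    row = pc$row, col = pc$col,
    motif_label = pc$motif_label, reference_n_bp = pc$reference_n_bp,
    r0 = layout$offset_px[1] + (pc$row - 1L) * layout$pitch_px,
    c0 = layout$offset_px[2] + (pc$col - 1L) * layout$pitch_px,
    stringsAsFactors = FALSE
  ) |> transform(r1 = r0 + layout$pad_size_px, c1 = c0 + layout$pad_size_px)
}

#' Per-pad pixel masks
#'
#' Returns one logical mask per pad, eroded inward by `margin_px` on every
#' side to exclude pad-edge pixels (stamp edges are optically ill-defined).
#' A margin of at least half the pad size yields an empty mask; downstream
#' fitting then reports the pad as `failed`.
#'
#' @param layout A [pad_layout()].
#' @param margin_px Non-negative erosion margin in pixels.
#' @return Named list of logical matrices (names `"row-col"`), disjoint by
#'   construction.
#' @export
segment_pads <- function(layout, margin_px = 2) {
  stopifnot(inherits(layout, "pad_layout"), margin_px >= 0)
  m <- as.integer(margin_px)
  rects <- pad_rects(layout)
  masks <- vector("list", nrow(rects))
  names(masks) <- rects$pad_id
  for (i in seq_len(nrow(rects))) {
    msk <- matrix(FALSE, layout$image_shape[1], layout$image_shape[2])
    r0 <- rects$r0[i] + m; r1 <- rects$r1[i] - m
    c0 <- rects$c0[i] + m; c1 <- rects$c1[i] - m
    if (r1 > r0 && c1 > c0)
      msk[(r0 + 1L):r1, (c0 + 1L):c1] <- TRUE  # 0-based -> R indices
    masks[[i]] <- msk
  }
  masks
}

# Logical mask of the inter-pad background region (no erosion).
background_mask <- function(layout) {
  msk <- matrix(TRUE, layout$image_shape[1], layout$image_shape[2])
  rects <- pad_rects(layout)
  for (i in seq_len(nrow(rects)))
    msk[(rects$r0[i] + 1L):rects$r1[i],
        (rects$c0[i] + 1L):rects$c1[i]] <- FALSE
  msk
}
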