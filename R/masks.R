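#' Build the anatomical mask set on a voxel grid
#'
#' Constructs, on the simulated cord geometry, the label volumes used by the
#' amplitude and spatial-specificity analyses: a circular cord mask, its four
#' quadrants (split at the in-plane midlines), four gray-matter "horn" blobs,
#' the dilated quadrants (quadrant plus an in-plane dilation ring covering
#' draining-vein territory), a CSF ring, a dorsal-surface vein shell, and a
#' division of the slice stack into four contiguous segmental levels
#' (labelled C5--C8; the target level is C6).
#'
#' The in-plane axes are interpreted as x = left to right and y = ventral to
#' dorsal, so the "left dorsal" quadrant sits at low x / high y. Dilation is
#' Euclidean: a voxel belongs to the dilated cord when its in-plane distance
#' to the nearest cord voxel is at most `dilation` voxels.
#'
#' @param grid_shape integer triple (nx, ny, n_slices).
#' @param dilation dilation radius in in-plane voxels.
#' @param cord_radius radius of the cord disc in voxels; default
#'   `min(nx, ny)/4`.
#' @param horn_radius radius of the gray-matter horn blobs; default
#'   `max(1, cord_radius/3)`.
#'
#' @return A `mask_set` list with logical 3-D arrays `cord`, `csf_ring`,
#'   `vein_shell`, named lists `horns`, `quadrants`, `dilated` (names
#'   `DL`, `DR`, `VL`, `VR`), and `segments`, a named list of slice-index
#'   vectors.
#' @export
#' @examples
#' m <- build_masks(c(16, 16, 8))
#' sum(m$horns$DL)
build_masks <- function(grid_shape, dilation = 6,
                        cord_radius = NULL, horn_radius = NULL) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2), dilation >= 0)
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  if (is.null(cord_radius)) cord_radius <- min(nx, ny) / 4
  if (is.null(horn_radius)) horn_radius <- max(1, cord_radius / 3)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2

  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  d2 <- (xs - cx)^2 + (ys - cy)^2
  cord2d <- d2 <= cord_radius^2

  # Euclidean distance (in-plane) from every voxel to the cord set
  cord_idx <- which(cord2d, arr.ind = TRUE)
  dist2cord <- matrix(Inf, nx, ny)
  for (k in seq_len(nrow(cord_idx))) {
    dk <- sqrt((xs - cord_idx[k, 1])^2 + (ys - cord_idx[k, 2])^2)
    dist2cord <- pmin(dist2cord, dk)
  }
  dil2d <- dist2cord <= dilation

  left  <- xs < cx; right <- xs > cx
  dors  <- ys > cy; vent  <- ys < cy
  quad2d <- list(DL = left & dors, DR = right & dors,
                 VL = left & vent, VR = right & vent)

  horn_off <- max(1, round(cord_radius / 2))
  horn_ctr <- list(DL = c(cx - horn_off, cy + horn_off),
                   DR = c(cx + horn_off, cy + horn_off),
                   VL = c(cx - horn_off, cy - horn_off),
                   VR = c(cx + horn_off, cy - horn_off))
  horn2d <- lapply(horn_ctr, function(ctr) {
    ((xs - ctr[1])^2 + (ys - ctr[2])^2 <= horn_radius^2) & cord2d
  })

  # dorsal-surface shell: out-of-cord voxels touching the cord from above
  shell2d <- !cord2d & dist2cord <= 1.5 & ys > cy
  # fluid compartment: ring around the cord, excluding the vein shell so
  # the CSF nuisance signal never carries the evoked venous response
  csf2d <- !cord2d & dist2cord <= max(2, dilation / 2) & !shell2d

  to3d <- function(m2d) array(rep(m2d, nz), dim = c(nx, ny, nz))
  # contiguous segmental blocks C5..C8, as even as the slice count allows
  seg_id <- rep(1:4, each = ceiling(nz / 4), length.out = nz)
  segments <- lapply(1:4, function(i) which(seg_id == i))
  names(segments) <- c("C5", "C6", "C7", "C8")

  out <- list(
    cord = to3d(cord2d),
    quadrants = lapply(quad2d, function(q) to3d(q & cord2d)),
    dilated = lapply(names(quad2d), function(nm) to3d(quad2d[[nm]] & dil2d)),
    horns = lapply(horn2d, to3d),
    vein_shell = to3d(shell2d),
    csf_ring = to3d(csf2d),
    segments = segments,
    grid_shape = grid_shape,
    cord_radius = cord_radius, horn_radius = horn_radius,
    dilation = dilation
  )
  names(out$dilated) <- names(quad2d)
  class(out) <- "mask_set"
  out
}

#' Restrict a mask to one segmental level
#'
#' @param mask logical 3-D array.
#' @param maskset a [build_masks()] result.
#' @param segment segment label, one of `names(maskset$segments)`.
#' @return A logical array of the same shape, `TRUE` only on the segment's
#'   slices.
#' @export
mask_on_segment <- function(mask, maskset, segment = "C6") {
  stopifnot(segment %in% names(maskset$segments))
  out <- mask & FALSE
  zz <- maskset$segments[[segment]]
  out[, , zz] <- mask[, , zz]
  out
}
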