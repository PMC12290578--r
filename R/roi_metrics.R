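#' Amplitude metrics within a region of interest
#'
#' Summarizes a statistic map over a mask with the three amplitude metrics
#' used throughout the reliability analysis: the mean over the ROI, the
#' peak (maximum) value, and the mean of the top 10% of values, where the
#' number of top voxels is `ceiling(0.1 * n)` (ties at the cutoff resolved
#' by voxel index order through the sort).
#'
#' @param statmap a `stat_map`, or a plain 3-D array of voxel values.
#' @param mask logical 3-D array, non-empty.
#' @param what which field of a `stat_map` to summarize (`"beta"` or
#'   `"z"`); ignored for array input.
#' @return A one-row tibble with `mean`, `peak`, `top10_mean`, `n_voxels`.
#' @export
#' @examples
#' a <- array(1:10, dim = c(10, 1, 1))
#' extract_metrics(a, array(TRUE, dim = c(10, 1, 1)))
extract_metrics <- function(statmap, mask, what = "beta") {
  vals <- if (inherits(statmap, "stat_map")) statmap[[what]] else statmap
  stopifnot(all(dim(vals) == dim(mask)))
  v <- vals[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("mask is empty (or all values undefined)",
                           call. = FALSE)
  n_top <- ceiling(0.1 * length(v))
  top <- sort(v, decreasing = TRUE)[seq_len(n_top)]
  tibble::tibble(mean = mean(v), peak = max(v), top10_mean = mean(top),
                 n_voxels = length(v))
}

#' Dice overlap of two binary masks
#'
#' `2 * V_overlap / (V1 + V2)` where `V1`, `V2` count the active voxels of
#' each mask and `V_overlap` the voxels active in both. When both masks
#' are empty the coefficient is reported as 0 with `both_empty = TRUE`.
#'
#' @param mask_a,mask_b logical arrays of identical dimension.
#' @return A one-row tibble `v1`, `v2`, `v_overlap`, `dice`, `both_empty`.
#' @export
#' @examples
#' a <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
#' b <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
#' dice(a, b) # 2*2/(3+5) = 0.5
dice <- function(mask_a, mask_b) {
  stopifnot(length(mask_a) == length(mask_b))
  v1 <- sum(mask_a); v2 <- sum(mask_b)
  vo <- sum(mask_a & mask_b)
  d <- if (v1 + v2 > 0) 2 * vo / (v1 + v2) else 0
  tibble::tibble(v1 = v1, v2 = v2, v_overlap = vo, dice = d,
                 both_empty = v1 + v2 == 0)
}

#' Individual-level spatial overlap across days
#'
#' Binarizes each day's z map at `|z| >= z_thresh` within the ROI and
#' computes the Dice overlap of the two suprathreshold sets, reporting also
#' whether each day has any suprathreshold voxel (participants without
#' suprathreshold voxels on both days are excluded from group averages of
#' the individual Dice).
#'
#' @param zmap_day1,zmap_day2 `stat_map`s or 3-D z arrays.
#' @param roi_mask logical 3-D array.
#' @param z_thresh absolute z threshold.
#' @return A one-row tibble as [dice()], plus `any_day1`, `any_day2`.
#' @export
individual_overlap <- function(zmap_day1, zmap_day2, roi_mask,
                               z_thresh = 1.96) {
  z1 <- if (inherits(zmap_day1, "stat_map")) zmap_day1$z else zmap_day1
  z2 <- if (inherits(zmap_day2, "stat_map")) zmap_day2$z else zmap_day2
  b1 <- !is.na(z1) & abs(z1) >= z_thresh & roi_mask
  b2 <- !is.na(z2) & abs(z2) >= z_thresh & roi_mask
  out <- dice(b1, b2)
  out$any_day1 <- any(b1)
  out$any_day2 <- any(b2)
  out
}

#' Spatial-specificity table of suprathreshold voxels
#'
#' Counts, per segmental level, the voxels of an uncorrected group p map
#' below `threshold` (strict inequality) in each cord quadrant and each
#' gray-matter horn, and expresses quadrant counts as percentages of the
#' segment's total suprathreshold count within the cord.
#'
#' @param group_p_map 3-D array of uncorrected p-values (`NA` outside the
#'   analysis mask).
#' @param threshold p threshold (default 0.001).
#' @param maskset a [build_masks()] result.
#' @return A tibble with columns `segment`, `region` (quadrant or horn
#'   label), `type` (`"quadrant"` or `"horn"`), `n_voxels`, `percent`
#'   (quadrants only: percent of the segment's cord total; `NA` when the
#'   total is 0).
#' @export
count_suprathreshold <- function(group_p_map, threshold = 0.001, maskset) {
  stopifnot(all(dim(group_p_map) == dim(maskset$cord)))
  sup <- !is.na(group_p_map) & group_p_map < threshold
  rows <- list()
  for (seg in names(maskset$segments)) {
    seg_tot <- sum(sup & mask_on_segment(maskset$cord, maskset, seg))
    for (q in names(maskset$quadrants)) {
      nq <- sum(sup & mask_on_segment(maskset$quadrants[[q]], maskset, seg))
      rows[[length(rows) + 1]] <- tibble::tibble(
        segment = seg, region = q, type = "quadrant", n_voxels = nq,
        percent = if (seg_tot > 0) 100 * nq / seg_tot else NA_real_)
    }
    for (h in names(maskset$horns)) {
      nh <- sum(sup & mask_on_segment(maskset$horns[[h]], maskset, seg))
      rows[[length(rows) + 1]] <- tibble::tibble(
        segment = seg, region = h, type = "horn", n_voxels = nh,
        percent = NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}
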