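## Image statistics: somatodendritic Tau-missorting MFI, IgLON5 surface
## cluster density/size on the MAP2+ dendrite mask, nucleus counts and the
## tangle fraction.

# global automatic threshold -> logical mask. Otsu (EBImage) on the
# intensity range; a constant channel has no foreground.
auto_threshold_mask <- function(channel, smoothing_sigma = 0) {
  rng <- range(channel)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(channel), ncol(channel)))
  if (smoothing_sigma > 0) {
    channel <- EBImage::gblur(EBImage::Image(channel),
                              sigma = smoothing_sigma)@.Data
    rng <- range(channel)
    if (diff(rng) == 0) return(matrix(FALSE, nrow(channel), ncol(channel)))
  }
  scaled <- (channel - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  matrix(scaled > thr, nrow(channel), ncol(channel))
}

#' Somatodendritic Tau-missorting mean fluorescence intensity
#'
#' The missorting statistic: summed Tau intensity over the soma minus the
#' nucleus, divided by the corresponding area difference —
#' `MFI = (RawIntDen_soma - RawIntDen_nucleus) / (Area_soma - Area_nucleus)`,
#' i.e. the mean Tau intensity over the cytoplasmic (soma-minus-nucleus)
#' region.
#'
#' @param tau_channel Numeric matrix of Tau intensities.
#' @param rois A `RoiSet` ([roi_set()]); masks must match the channel shape.
#' @return A `MissortingResult`: list with `mfi`, `rawintden_soma`,
#'   `rawintden_nucleus`, `area_soma`, `area_nucleus` (pixel counts).
#' @export
#' @examples
#' tau <- matrix(7, 32, 32)
#' rois <- roi_set(disk_mask <- matrix(TRUE, 32, 32),
#'                 rbind(matrix(TRUE, 16, 32), matrix(FALSE, 16, 32)))
#' missorting_mfi(tau, rois)$mfi  # 7
missorting_mfi <- function(tau_channel, rois) {
  stopifnot(is.matrix(tau_channel), inherits(rois, "RoiSet"))
  if (!identical(dim(tau_channel), dim(rois$soma_mask))) {
    stop_invalid("ROI masks do not match the Tau channel shape")
  }
  area_soma <- sum(rois$soma_mask)
  area_nucleus <- sum(rois$nucleus_mask)
  if (area_soma == area_nucleus) {
    stop(errorCondition("soma and nucleus areas are equal",
                        class = c("iq_degenerate_roi", "error")))
  }
  rid_soma <- sum(tau_channel[rois$soma_mask])
  rid_nucleus <- sum(tau_channel[rois$nucleus_mask])
  structure(
    list(mfi = (rid_soma - rid_nucleus) / (area_soma - area_nucleus),
         rawintden_soma = rid_soma, rawintden_nucleus = rid_nucleus,
         area_soma = area_soma, area_nucleus = area_nucleus),
    class = "MissortingResult")
}

#' Segment surface clusters and compute density on the MAP2+ area
#'
#' The MAP2 channel is thresholded automatically (Otsu) to a dendrite mask;
#' the IgLON5 channel is Gaussian-smoothed, thresholded (Otsu), restricted
#' to the MAP2+ mask, and labelled into 8-connected components; components
#' smaller than `min_area_px` are discarded. Density is the cluster count
#' per MAP2+ pixel (and per square micrometre if `pixel_size` is given).
#'
#' @param iglon5_channel,map2_channel Numeric matrices of identical shape.
#' @param smoothing_sigma Gaussian smoothing SD for the IgLON5 channel in
#'   pixels (default 1; 0 disables).
#' @param min_area_px Minimum component area in pixels (default 2).
#' @param pixel_size Optional micrometres/pixel for areas in square
#'   micrometres.
#' @return A `ClusterStats`: list with `n_clusters`, `cluster_areas` (px),
#'   `mean_area` (px; `NA` when no clusters), `equivalent_radii`
#'   (`sqrt(area/pi)`, px), `map2_area` (px), `density` (clusters/px of
#'   MAP2+ area), and `mean_area_um2`/`density_per_um2` when `pixel_size`
#'   is given.
#' @export
segment_clusters <- function(iglon5_channel, map2_channel,
                             smoothing_sigma = 1, min_area_px = 2,
                             pixel_size = NULL) {
  stopifnot(is.matrix(iglon5_channel), is.matrix(map2_channel))
  if (!identical(dim(iglon5_channel), dim(map2_channel))) {
    stop_invalid("IgLON5 and MAP2 channels differ in shape")
  }
  check_number(smoothing_sigma, "smoothing_sigma", lower = 0)
  check_number(min_area_px, "min_area_px", lower = 0)
  map2_mask <- auto_threshold_mask(map2_channel)
  map2_area <- sum(map2_mask)
  if (map2_area == 0) {
    stop(errorCondition("MAP2+ area is empty",
                        class = c("iq_empty_mask", "error")))
  }
  fg <- auto_threshold_mask(iglon5_channel, smoothing_sigma) & map2_mask
  labels <- label_components(fg, connectivity = 8)
  areas <- tabulate(labels[labels > 0])
  areas <- areas[areas >= min_area_px]
  n <- length(areas)
  res <- list(
    n_clusters = n,
    cluster_areas = areas,
    mean_area = if (n > 0) mean(areas) else NA_real_,
    equivalent_radii = sqrt(areas / pi),
    map2_area = map2_area,
    density = n / map2_area)
  if (!is.null(pixel_size)) {
    res$mean_area_um2 <- res$mean_area * pixel_size^2
    res$density_per_um2 <- res$density / pixel_size^2
  }
  structure(res, class = "ClusterStats")
}

#' Count nuclei in a DAPI channel
#'
#' Automatic (Otsu) threshold, 8-connected components, size filter. Two
#' touching nuclei merge into one component — a documented limitation of
#' the plain connectivity rule; the synthetic fixtures place nuclei
#' disjointly.
#'
#' @param dapi_channel Numeric matrix; a constant (blank) channel counts 0.
#' @param min_area_px Minimum nucleus area in pixels (default 5).
#' @return Integer count.
#' @export
count_nuclei <- function(dapi_channel, min_area_px = 5) {
  stopifnot(is.matrix(dapi_channel))
  if (length(dapi_channel) == 0L) stop_invalid("empty DAPI channel")
  check_number(min_area_px, "min_area_px", lower = 0)
  fg <- auto_threshold_mask(dapi_channel)
  labels <- label_components(fg, connectivity = 8)
  areas <- tabulate(labels[labels > 0])
  sum(areas >= min_area_px)
}

#' Tangle fraction: tangle-bearing neurons per DAPI+ nucleus
#'
#' @param n_tangles Number of neurons with tangle-like aggregates.
#' @param n_nuclei Number of DAPI-positive nuclei (`> 0`,
#'   `>= n_tangles`).
#' @return Percentage, `100 * n_tangles / n_nuclei`.
#' @export
#' @examples
#' tangle_fraction(5, 100)  # 5
tangle_fraction <- function(n_tangles, n_nuclei) {
  check_number(n_tangles, "n_tangles", lower = 0)
  if (!is.numeric(n_nuclei) || length(n_nuclei) != 1L || n_nuclei <= 0) {
    stop(errorCondition("n_nuclei must be > 0",
                        class = c("iq_division_error", "error")))
  }
  if (n_tangles > n_nuclei) {
    stop(errorCondition("n_tangles exceeds n_nuclei",
                        class = c("iq_inconsistency_error", "error")))
  }
  100 * n_tangles / n_nuclei
}
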