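## Synthetic multi-channel microscopy fixtures (DAPI / MAP2 / Tau / IgLON5)
## with known ground truth. Geometry is simple by design: disk somata and
## nuclei, straight neurites/dendrites, disk-shaped surface puncta — enough
## to exercise every quantification contract, not a model of real neurons.

# logical disk; centre in (row, col) pixel coordinates
disk_mask <- function(nrow, ncol, center, radius) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# logical strip of half-width w/2 around the segment p1 -> p2
segment_mask <- function(nrow, ncol, p1, p2, width) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  v <- p2 - p1
  len2 <- sum(v^2)
  t <- ((r - p1[1]) * v[1] + (cc - p1[2]) * v[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  d2 <- (r - (p1[1] + t * v[1]))^2 + (cc - (p1[2] + t * v[2]))^2
  d2 <= (width / 2)^2
}

add_noise <- function(channel, noise_sd, seed) {
  if (noise_sd <= 0) return(channel)
  noisy <- channel + withr::with_seed(
    as.integer(seed),
    matrix(stats::rnorm(length(channel), sd = noise_sd), nrow(channel)))
  pmax(noisy, 0)  # intensities stay non-negative
}

#' Construct a multi-channel labelled image
#'
#' @param channels Named list of same-shaped non-negative numeric matrices;
#'   names are channel roles (e.g. `"DAPI"`, `"MAP2"`, `"Tau"`, `"IgLON5"`).
#' @param pixel_size Optional pixel size in micrometres/pixel.
#' @return A `LabeledImage` object.
#' @export
labeled_image <- function(channels, pixel_size = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop_invalid("channels must be a named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(!vapply(channels, is.matrix, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop_invalid("all channels must be matrices of identical shape")
  }
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    stop_invalid("channel intensities must be >= 0")
  }
  structure(list(channels = channels, pixel_size = pixel_size),
            class = "LabeledImage")
}

#' Construct a soma/nucleus ROI set
#'
#' @param soma_mask,nucleus_mask Logical matrices of identical shape; the
#'   nucleus must lie strictly inside the soma (subset, with smaller area).
#' @param provenance `"manual"` or `"synthetic"`.
#' @return A `RoiSet` object.
#' @export
roi_set <- function(soma_mask, nucleus_mask, provenance = "synthetic") {
  stopifnot(is.matrix(soma_mask), is.matrix(nucleus_mask))
  if (!identical(dim(soma_mask), dim(nucleus_mask))) {
    stop_invalid("soma and nucleus masks differ in shape")
  }
  soma_mask <- soma_mask != 0
  nucleus_mask <- nucleus_mask != 0
  if (any(nucleus_mask & !soma_mask)) {
    stop(errorCondition("nucleus mask is not contained in the soma mask",
                        class = c("iq_invalid_roi", "error")))
  }
  if (sum(soma_mask) <= sum(nucleus_mask)) {
    stop(errorCondition("soma area must exceed nucleus area",
                        class = c("iq_degenerate_roi", "error")))
  }
  provenance <- match.arg(provenance, c("manual", "synthetic"))
  structure(list(soma_mask = soma_mask, nucleus_mask = nucleus_mask,
                 provenance = provenance),
            class = "RoiSet")
}

#' Synthesise a Tau-missorting image with known ground truth
#'
#' Renders DAPI/MAP2/Tau channels of a single neuron: a disk soma with a
#' strictly interior disk nucleus and straight neurites. A fixed total Tau
#' budget is split between the somatodendritic cytoplasm (fraction
#' `allocation_somatic`) and the neurites (the axonal pool), on top of a
#' uniform background, so the cytoplasmic Tau mean intensity — the
#' missorting statistic — is controlled exactly. The stored truth is the
#' statistic recomputed from the noiseless rendering by [missorting_mfi()].
#'
#' @param size Image side length in pixels.
#' @param soma_radius,nucleus_radius Disk radii in pixels;
#'   `nucleus_radius < soma_radius` (strict containment).
#' @param n_neurites Number of straight neurites leaving the soma.
#' @param neurite_width Neurite width in pixels.
#' @param allocation_somatic Fraction of the Tau budget allocated to the
#'   somatodendritic cytoplasm, in `[0, 1]`.
#' @param tau_total Integrated Tau intensity budget (a.u.).
#' @param background Uniform background intensity on every channel.
#' @param noise_sd Additive Gaussian noise SD (clipped at 0); 0 for
#'   noiseless fixtures.
#' @param seed Integer seed (soma placement jitter, neurite angles, noise).
#' @return List with `image` (`LabeledImage`, channels DAPI/MAP2/Tau),
#'   `rois` (`RoiSet`), and `truth` (list: `true_missorting_mfi`,
#'   `allocation_somatic`).
#' @export
synthesize_missorting_image <- function(size = 128, soma_radius = 18,
                                        nucleus_radius = 9, n_neurites = 3,
                                        neurite_width = 3,
                                        allocation_somatic = 0.5,
                                        tau_total = 50000, background = 5,
                                        noise_sd = 0, seed = 1) {
  check_number(allocation_somatic, "allocation_somatic", lower = 0, upper = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (nucleus_radius >= soma_radius) {
    stop(errorCondition("nucleus must be strictly inside the soma",
                        class = c("iq_generation_error", "error")))
  }
  seeds <- derive_seeds(seed, 4)
  center <- withr::with_seed(seeds[1],
                             size / 2 + stats::runif(2, -size / 8, size / 8))
  soma <- disk_mask(size, size, center, soma_radius)
  nucleus <- disk_mask(size, size, center, nucleus_radius)
  angles <- withr::with_seed(seeds[2], {
    stats::runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = n_neurites + 1L)[-1L]
  })
  neurites <- matrix(FALSE, size, size)
  for (a in angles) {
    p1 <- center + soma_radius * c(sin(a), cos(a))
    p2 <- center + (soma_radius + size / 3) * c(sin(a), cos(a))
    p2 <- pmin(pmax(p2, 2), size - 1)
    neurites <- neurites | segment_mask(size, size, p1, p2, neurite_width)
  }
  neurites <- neurites & !soma
  cyto <- soma & !nucleus
  tau <- matrix(background, size, size)
  tau[cyto] <- background + allocation_somatic * tau_total / sum(cyto)
  if (sum(neurites) > 0) {
    tau[neurites] <- background +
      (1 - allocation_somatic) * tau_total / sum(neurites)
  }
  dapi <- matrix(background, size, size)
  dapi[nucleus] <- 200
  map2 <- matrix(background, size, size)
  map2[soma | neurites] <- 150
  rois <- roi_set(soma, nucleus, provenance = "synthetic")
  truth <- list(
    true_missorting_mfi = missorting_mfi(tau, rois)$mfi,
    allocation_somatic = allocation_somatic)
  channels <- list(
    DAPI = add_noise(dapi, noise_sd, seeds[3]),
    MAP2 = add_noise(map2, noise_sd, seeds[4]),
    Tau = add_noise(tau, noise_sd, seeds[3] + 1L))
  list(image = labeled_image(channels), rois = rois, truth = truth)
}

#' Synthesise an IgLON5 surface-cluster image with known ground truth
#'
#' Renders a MAP2 dendrite mask (straight strips) and an IgLON5 channel
#' with `n_clusters` disjoint disk-shaped puncta placed entirely inside the
#' dendrite mask with a guard gap, so the cluster count is exact by
#' construction. The stored truth (`true_cluster_count`,
#' `true_cluster_mean_area`) is what [segment_clusters()] with default
#' parameters returns on the noiseless rendering.
#'
#' @param n_clusters Number of puncta (`>= 0`).
#' @param cluster_radius_range Numeric length-2, min/max punctum radius in
#'   pixels (drawn uniformly).
#' @param size Image side length in pixels.
#' @param n_dendrites Number of dendrite strips.
#' @param dendrite_width Strip width in pixels.
#' @param cluster_intensity,background Punctum and background intensity
#'   (a.u.).
#' @param noise_sd Additive Gaussian noise SD (clipped at 0).
#' @param seed Integer seed.
#' @param max_tries Placement attempts per punctum before giving up.
#' @return List with `image` (`LabeledImage`, channels MAP2/IgLON5) and
#'   `truth` (list: `true_cluster_count`, `true_cluster_mean_area`,
#'   `centers`, `radii`).
#' @export
synthesize_cluster_image <- function(n_clusters, cluster_radius_range = c(2, 3),
                                     size = 128, n_dendrites = 4,
                                     dendrite_width = 11,
                                     cluster_intensity = 150, background = 5,
                                     noise_sd = 0, seed = 1,
                                     max_tries = 500) {
  check_number(n_clusters, "n_clusters", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  seeds <- derive_seeds(seed, 3)
  dendrites <- matrix(FALSE, size, size)
  ends <- withr::with_seed(seeds[1], {
    lapply(seq_len(n_dendrites), function(i) {
      # strips crossing the full field at random angle/offset
      a <- stats::runif(1, 0, pi)
      off <- stats::runif(1, 0.25, 0.75) * size
      ctr <- c(off, size / 2)
      d <- c(sin(a), cos(a)) * size
      list(p1 = ctr - d, p2 = ctr + d)
    })
  })
  for (e in ends) {
    dendrites <- dendrites | segment_mask(size, size, e$p1, e$p2,
                                          dendrite_width)
  }
  gap <- 4  # guard gap between puncta rims, px
  placed_c <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  if (n_clusters > 0) {
    ok <- withr::with_seed(seeds[2], {
      for (i in seq_len(n_clusters)) {
        done <- FALSE
        for (try in seq_len(max_tries)) {
          ctr <- stats::runif(2, 2, size - 1)
          r <- stats::runif(1, cluster_radius_range[1], cluster_radius_range[2])
          # punctum (plus 1 px halo for smoothing) must sit inside the mask
          halo <- disk_mask(size, size, ctr, r + 1)
          if (!all(dendrites[halo])) next
          if (nrow(placed_c) > 0) {
            d <- sqrt((placed_c[, 1] - ctr[1])^2 + (placed_c[, 2] - ctr[2])^2)
            if (any(d < radii + r + gap)) next
          }
          placed_c <- rbind(placed_c, ctr)
          radii <- c(radii, r)
          done <- TRUE
          break
        }
        if (!done) break
      }
      nrow(placed_c) == n_clusters
    })
    if (!ok) {
      stop(errorCondition(
        sprintf("could not place %d non-overlapping clusters (placed %d)",
                n_clusters, nrow(placed_c)),
        class = c("iq_generation_error", "error")))
    }
  }
  iglon5 <- matrix(background, size, size)
  for (i in seq_len(nrow(placed_c))) {
    iglon5[disk_mask(size, size, placed_c[i, ], radii[i])] <- cluster_intensity
  }
  map2 <- matrix(background, size, size)
  map2[dendrites] <- 120
  noiseless <- labeled_image(list(MAP2 = map2, IgLON5 = iglon5))
  stats_noiseless <- segment_clusters(iglon5, map2)
  truth <- list(true_cluster_count = stats_noiseless$n_clusters,
                true_cluster_mean_area = stats_noiseless$mean_area,
                centers = placed_c, radii = radii)
  image <- labeled_image(list(MAP2 = add_noise(map2, noise_sd, seeds[3]),
                              IgLON5 = add_noise(iglon5, noise_sd,
                                                 seeds[3] + 1L)))
  list(image = image, truth = truth)
}

#' Synthesise a DAPI nuclei field with known count
#'
#' Fixture helper for [count_nuclei()] and [tangle_fraction()]: disjoint
#' disk nuclei on a uniform background.
#'
#' @param n_nuclei Number of nuclei.
#' @param size Image side length in pixels.
#' @param radius_range Min/max nucleus radius in pixels.
#' @param intensity,background Nucleus and background intensity.
#' @param noise_sd Additive Gaussian noise SD (clipped at 0).
#' @param seed Integer seed.
#' @param max_tries Placement attempts per nucleus.
#' @return List with `dapi` (matrix) and `truth` (list: `true_count`).
#' @export
synthesize_nuclei_image <- function(n_nuclei, size = 128,
                                    radius_range = c(4, 7), intensity = 180,
                                    background = 5, noise_sd = 0, seed = 1,
                                    max_tries = 500) {
  check_number(n_nuclei, "n_nuclei", lower = 0)
  seeds <- derive_seeds(seed, 2)
  placed_c <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  if (n_nuclei > 0) {
    ok <- withr::with_seed(seeds[1], {
      for (i in seq_len(n_nuclei)) {
        done <- FALSE
        for (try in seq_len(max_tries)) {
          r <- stats::runif(1, radius_range[1], radius_range[2])
          ctr <- stats::runif(2, r + 2, size - r - 1)
          if (nrow(placed_c) > 0) {
            d <- sqrt((placed_c[, 1] - ctr[1])^2 + (placed_c[, 2] - ctr[2])^2)
            if (any(d < radii + r + 4)) next
          }
          placed_c <- rbind(placed_c, ctr)
          radii <- c(radii, r)
          done <- TRUE
          break
        }
        if (!done) break
      }
      nrow(placed_c) == n_nuclei
    })
    if (!ok) {
      stop(errorCondition("could not place disjoint nuclei",
                          class = c("iq_generation_error", "error")))
    }
  }
  dapi <- matrix(background, size, size)
  for (i in seq_len(nrow(placed_c))) {
    dapi[disk_mask(size, size, placed_c[i, ], radii[i])] <- intensity
  }
  list(dapi = add_noise(dapi, noise_sd, seeds[2]),
       truth = list(true_count = n_nuclei))
}
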