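# Image statistics: missorting MFI, cluster segmentation, nucleus counts,
# tangle fraction.

square_rois <- function(size = 40) {
  soma <- matrix(FALSE, size, size); soma[6:35, 6:35] <- TRUE
  nuc <- matrix(FALSE, size, size); nuc[15:26, 15:26] <- TRUE
  roi_set(soma, nuc)
}

test_that("missorting MFI implements the RawIntDen difference quotient", {
  rois <- square_rois()
  # uniform image: MFI equals the uniform intensity for any valid ROI pair
  expect_equal(missorting_mfi(matrix(7, 40, 40), rois)$mfi, 7)

  # hand-computed arithmetic: soma 1000/100px, nucleus 400/50px -> 12
  soma <- matrix(FALSE, 20, 20); soma[1:10, 1:10] <- TRUE
  nuc <- matrix(FALSE, 20, 20); nuc[1:5, 1:10] <- TRUE
  tau <- matrix(0, 20, 20)
  tau[nuc] <- 8                      # 50 px * 8 = 400
  tau[soma & !nuc] <- 12             # 50 px * 12 = 600; soma total 1000
  res <- missorting_mfi(tau, roi_set(soma, nuc))
  expect_equal(res$rawintden_soma, 1000)
  expect_equal(res$rawintden_nucleus, 400)
  expect_equal(res$mfi, 12)
})

test_that("missorting MFI equals the pixelwise cytoplasmic mean exactly", {
  rois <- square_rois()
  withr::with_seed(8, {
    for (i in 1:10) {
      tau <- matrix(rexp(1600, 0.1), 40, 40)
      got <- missorting_mfi(tau, rois)$mfi
      oracle <- mean(tau[rois$soma_mask & !rois$nucleus_mask])
      expect_equal(got, oracle, tolerance = 1e-12)
    }
  })
})

test_that("missorting MFI ignores intensity outside the soma and scales with gain", {
  rois <- square_rois()
  withr::with_seed(2, tau <- matrix(rexp(1600), 40, 40))
  base <- missorting_mfi(tau, rois)$mfi
  outside <- tau
  outside[!rois$soma_mask] <- outside[!rois$soma_mask] + 50
  expect_equal(missorting_mfi(outside, rois)$mfi, base, tolerance = 1e-12)
  expect_equal(missorting_mfi(3 * tau, rois)$mfi, 3 * base, tolerance = 1e-12)
})

test_that("cluster segmentation recovers counts, density and filters", {
  # three disjoint 5-px blobs inside a bright MAP2 region
  map2 <- matrix(0, 50, 50); map2[11:30, 1:50] <- 100  # 1000 px
  ig <- matrix(0, 50, 50)
  plus <- function(r, c) cbind(r + c(0, -1, 1, 0, 0), c + c(0, 0, 0, -1, 1))
  ig[plus(15, 10)] <- 200
  ig[plus(20, 25)] <- 200
  ig[plus(25, 40)] <- 200
  st <- segment_clusters(ig, map2, smoothing_sigma = 0)
  expect_equal(st$n_clusters, 3)
  expect_equal(st$map2_area, 1000)
  expect_equal(st$density, 0.003)
  expect_equal(st$cluster_areas, rep(5, 3))
  expect_equal(st$equivalent_radii, rep(sqrt(5 / pi), 3))

  # blank channel: zero clusters, zero density
  st0 <- segment_clusters(matrix(0, 50, 50), map2)
  expect_equal(st0$n_clusters, 0)
  expect_equal(st0$density, 0)

  # single 1-px blob removed by the size filter
  ig1 <- matrix(0, 50, 50); ig1[20, 20] <- 200
  expect_equal(segment_clusters(ig1, map2, smoothing_sigma = 0,
                                min_area_px = 2)$n_clusters, 0)

  expect_error(segment_clusters(ig, matrix(0, 50, 50)),
               class = "iq_empty_mask")
})

test_that("cluster counts match fixture truth for n = 0..20", {
  for (n in 0:20) {
    fx <- synthesize_cluster_image(n, seed = 100 + n)
    st <- segment_clusters(fx$image$channels$IgLON5, fx$image$channels$MAP2)
    expect_equal(st$n_clusters, n)
    expect_equal(st$density, n / st$map2_area)
  }
})

test_that("density is invariant under MAP2-negative padding", {
  fx <- synthesize_cluster_image(6, seed = 9)
  ig <- fx$image$channels$IgLON5
  map2 <- fx$image$channels$MAP2
  bg <- map2[1, 1]
  pad <- function(m, fill) rbind(matrix(fill, 20, ncol(m) + 40),
                                 cbind(matrix(fill, nrow(m), 20), m,
                                       matrix(fill, nrow(m), 20)),
                                 matrix(fill, 20, ncol(m) + 40))
  st <- segment_clusters(ig, map2)
  stp <- segment_clusters(pad(ig, ig[1, 1]), pad(map2, bg))
  expect_equal(stp$n_clusters, st$n_clusters)
  expect_equal(stp$density, st$density)
})

test_that("nucleus counting uses 8-connected components with a size filter", {
  fx <- synthesize_nuclei_image(7, seed = 13)
  expect_equal(count_nuclei(fx$dapi), 7)
  expect_equal(count_nuclei(matrix(0, 30, 30)), 0)
  # two touching blobs merge into one count (documented limitation)
  d <- matrix(0, 30, 30)
  d[10:14, 10:14] <- 180
  d[14:18, 14:18] <- 180
  expect_equal(count_nuclei(d), 1)
})

test_that("tangle fraction is a guarded percentage", {
  expect_equal(tangle_fraction(5, 100), 5)
  expect_equal(tangle_fraction(0, 50), 0)
  expect_error(tangle_fraction(3, 0), class = "iq_division_error")
  expect_error(tangle_fraction(11, 10), class = "iq_inconsistency_error")
})
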