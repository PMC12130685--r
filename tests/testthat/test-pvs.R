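test_that("EPC is the clipped T1w/T2w ratio with flagged denominators", {
  mask <- array(TRUE, c(4, 4, 4))
  t1 <- array(2, c(4, 4, 4)); t2 <- array(1, c(4, 4, 4))
  epc <- compute_epc(t1, t2, mask)
  expect_equal(unique(as.numeric(epc$data)), 2)
  expect_false(any(epc$clipped))
  t2[1, 1, 1] <- 0
  epc2 <- compute_epc(t1, t2, mask, eps = 1e-6)
  expect_true(is.finite(epc2$data[1, 1, 1]))
  expect_true(epc2$clipped[1, 1, 1])
  expect_equal(sum(epc2$clipped), 1L)
  expect_error(compute_epc(t1, array(1, c(3, 4, 4)), mask), "grid mismatch")
})

test_that("vesselness is zero on constant volumes and bounded in [0,1]", {
  v <- frangi_vesselness(array(5, c(12, 12, 12)))
  expect_equal(max(v), 0)
  ph <- small_phantom()
  st <- simulate_structural(ph, seed = 2)
  epc <- compute_epc(st$t1w, st$t2w, ph$masks$brain)
  ves <- frangi_vesselness(epc$data, roi_mask = ph$masks$wm)
  expect_true(all(ves >= 0 & ves <= 1))
})

test_that("a cylinder out-scores an equal-intensity sphere and survives rotation", {
  shp <- c(24, 24, 24)
  cyl <- array(0, shp); cyl[8:16, 12, 12] <- 1
  sph <- array(0, shp); sph[12, 12, 12] <- 1
  p <- vesselness_params(polarity = "bright")
  v_cyl <- max(frangi_vesselness(cyl, p))
  v_sph <- max(frangi_vesselness(sph, p))
  expect_gt(v_cyl, v_sph)
  # 90-degree rotation changes the response by < 5%
  rot <- array(0, shp); rot[12, 8:16, 12] <- 1
  v_rot <- max(frangi_vesselness(rot, p))
  expect_lt(abs(v_rot - v_cyl) / v_cyl, 0.05)
})

test_that("segmentation restricts to WM, excludes WMH and prunes small clusters", {
  ph <- small_phantom()
  wm <- ph$masks$wm
  expect_equal(sum(segment_pvs(array(0, ph$shape) + 1e-9, wm)), 0L)
  # tubule overlapping a WMH blob loses the overlap voxels
  ves <- array(0, ph$shape)
  ves[ph$masks$pvs_truth] <- 0.9
  wmh <- array(FALSE, ph$shape)
  overlap <- which(ph$masks$pvs_truth)[1:3]
  wmh[overlap] <- TRUE
  seg <- segment_pvs(ves, wm, wmh, min_cluster_voxels = 1)
  expect_false(any(seg[overlap]))
  expect_true(all(seg[setdiff(which(ph$masks$pvs_truth), overlap)]))
  # isolated single voxels fall below the cluster-size rule
  ves1 <- array(0, ph$shape)
  lone <- which(wm & !ph$masks$pvs_truth)[1]
  ves1[lone] <- 0.9
  expect_equal(sum(segment_pvs(ves1, wm, min_cluster_voxels = 2)), 0L)
  expect_error(segment_pvs(ves, array(FALSE, ph$shape)), "WM mask")
})

test_that("phantom tubule is segmented with high overlap and exact burden", {
  ph <- make_phantom()
  st <- simulate_structural(ph, seed = 3)
  epc <- compute_epc(st$t1w, st$t2w, ph$masks$brain)
  ves <- frangi_vesselness(epc$data, roi_mask = ph$masks$wm)
  seg <- segment_pvs(ves, ph$masks$wm, ph$masks$wmh)
  truth <- ph$masks$pvs_truth
  dice <- 2 * sum(seg & truth) / (sum(seg) + sum(truth))
  expect_gte(dice, 0.5)
  burden <- pvs_burden(seg, ph$masks$wm)
  truth_burden <- pvs_burden(truth, ph$masks$wm)
  expect_lt(abs(burden - truth_burden) / truth_burden, 0.10)
})

test_that("burden is counting arithmetic, invariant to voxel volume", {
  pvs <- array(FALSE, c(10, 10, 10)); pvs[1:15] <- TRUE
  wm <- array(TRUE, c(10, 10, 10))
  expect_equal(pvs_burden(pvs, wm), 1.5)
  expect_equal(pvs_burden(array(FALSE, c(10, 10, 10)), wm), 0)
  expect_equal(pvs_burden(pvs, wm, voxel_volume_mm3 = 2), 1.5)
  expect_error(pvs_burden(pvs, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("burden is monotone in threshold and WMH exclusion", {
  ph <- small_phantom()
  st <- simulate_structural(ph, seed = 5)
  epc <- compute_epc(st$t1w, st$t2w, ph$masks$brain)
  ves <- frangi_vesselness(epc$data, roi_mask = ph$masks$wm)
  burdens <- vapply(c(0.1, 0.2, 0.4, 0.6, 0.8), function(th)
    pvs_burden(segment_pvs(ves, ph$masks$wm, threshold = th), ph$masks$wm), 1)
  expect_true(all(diff(burdens) <= 0))
  # growing the WMH mask never increases PVS volume
  wmh_small <- ph$masks$wmh
  wmh_big <- wmh_small | ph$masks$pvs_truth
  v_small <- sum(segment_pvs(ves, ph$masks$wm, wmh_small))
  v_big <- sum(segment_pvs(ves, ph$masks$wm, wmh_big))
  expect_lte(v_big, v_small)
})

test_that("26-connectivity labelling joins diagonal voxels", {
  m <- array(FALSE, c(5, 5, 5))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE   # diagonal neighbours
  m[5, 5, 5] <- TRUE                       # separate component
  lab <- label_components(m)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_false(lab[5, 5, 5] == lab[1, 1, 1])
  expect_equal(max(lab), 2L)
})
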