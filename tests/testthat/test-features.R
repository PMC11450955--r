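test_that("morphology features recover analytic volumes and axes", {
  # 10x10x10 voxel cube at 1 mm -> exactly 1 cm^3
  a <- array(FALSE, c(14, 14, 14)); a[3:12, 3:12, 3:12] <- TRUE
  cube <- binary_mask(a, c(1, 1, 1))
  mf <- morphology_features(cube, cube)
  expect_equal(unname(mf["EAT_vol"]), 1)
  expect_equal(unname(mf["SAC_vol"]), 1)
  expect_equal(unname(mf["EAT_frac"]), 1)

  # uniform ball: each axis 4*sqrt(r^2/5) ~ 1.789 r, aspect ratio 1
  r <- 20
  ph <- generate_phantom(shell_phantom(r_mm = r, t_mm = 5, h_mm = 1))
  mb <- morphology_features(ph$sac, ph$eat)
  expect_equal(unname(mb["Major_Axis"]), 4 * sqrt(r^2 / 5), tolerance = 0.02)
  expect_equal(unname(mb["Aspect_Ratio"]), 1, tolerance = 0.02)

  # ellipsoid semi-axes (40, 30, 20): ordering preserved, ratio ~ 2
  pe <- phantom_spec(dim = c(50, 100, 120), spacing = c(2, 1, 1),
                     semiaxes = c(20, 30, 40),
                     thickness = list(type = "constant", t0 = 5))
  phe <- generate_phantom(pe)
  me <- morphology_features(phe$sac, phe$eat)
  expect_true(me["Major_Axis"] > me["Intermediate_Axis"])
  expect_true(me["Intermediate_Axis"] > me["Minor_Axis"])
  expect_equal(unname(me["Aspect_Ratio"]), 2, tolerance = 0.05)
  expect_equal(unname(me["Major_Axis"] / (4 * sqrt(40^2 / 5))), 1, tolerance = 0.03)
})

test_that("HU statistics match hand-computed moments", {
  d <- c(2, 2, 2)
  mk <- function(v) {
    vol <- image_volume(array(v, d), c(1, 1, 1))
    msk <- binary_mask(array(TRUE, d), c(1, 1, 1))
    hu_statistics(vol, msk)
  }
  # {-50,-50,-50,-190} repeated twice keeps the same moments
  st <- mk(rep(c(-50, -50, -50, -190), 2))
  expect_equal(unname(st["EAT_HUmean"]), -85)
  expect_equal(unname(st["EAT_HUskewness"]), -1.154701, tolerance = 1e-6)
  expect_equal(unname(st["Negative_skewness"]), 1.154701, tolerance = 1e-6)
  expect_equal(unname(st["EAT_HUmin"]), -190)
  expect_equal(unname(st["EAT_HUmax"]), -50)

  # symmetric sample: zero skewness
  st2 <- mk(c(-60, -80, -100, -80, -60, -80, -100, -80))
  expect_equal(unname(st2["EAT_HUskewness"]), 0)

  # Gaussian sample: non-excess kurtosis -> 3
  set.seed(8)
  n <- 1e5
  big <- image_volume(array(rnorm(n, -80, 20), c(10, 100, 100)), c(1, 1, 1))
  bigm <- binary_mask(array(TRUE, c(10, 100, 100)), c(1, 1, 1))
  expect_equal(unname(hu_statistics(big, bigm)["EAT_HUkurtosis"]), 3, tolerance = 0.1)

  # too few voxels
  tiny <- binary_mask(array(c(TRUE, TRUE, rep(FALSE, 6)), d), c(1, 1, 1))
  expect_error(hu_statistics(image_volume(array(-80, d), c(1, 1, 1)), tiny), ">= 3")
})

test_that("HU histogram bins partition the window with exact bookkeeping", {
  set.seed(3)
  d <- c(20, 40, 40)
  msk <- binary_mask(array(TRUE, d), c(1, 1, 1))
  vol <- image_volume(array(runif(prod(d), -190, -30), d), c(1, 1, 1))
  h8 <- hu_histogram_features(vol, msk, 8)
  pro <- h8[grep("^Pro_", names(h8))]
  expect_equal(sum(pro), 1)
  expect_lt(max(abs(pro - 0.125)), 0.01)
  # bin volumes sum to the windowed volume
  vols <- h8[grep("^vol_", names(h8))]
  expect_equal(sum(vols), prod(d) / 1000)

  # all mass at -40 HU lands in vol_50_30
  vol2 <- image_volume(array(-40, d), c(1, 1, 1))
  h2 <- hu_histogram_features(vol2, msk, 8)
  expect_equal(unname(h2["vol_50_30"]), prod(d) / 1000)
  expect_equal(sum(h2[grep("^vol_", names(h2))]) - h2[["vol_50_30"]], 0)

  # 4-bin names span 40 HU each
  h4 <- hu_histogram_features(vol, msk, 4)
  expect_named(h4, c("vol_190_150", "vol_150_110", "vol_110_70", "vol_70_30",
                     "Pro_190_150", "Pro_150_110", "Pro_110_70", "Pro_70_30"))
})

test_that("binmix phantoms reproduce a 37% upper-bin probability", {
  probs <- c(0.07, 0.08, 0.09, 0.09, 0.10, 0.10, 0.10, 0.37)
  ph <- generate_phantom(phantom_spec(
    dim = c(30, 64, 64), spacing = c(2, 1.25, 1.25), semiaxes = c(26, 36, 34),
    thickness = list(type = "constant", t0 = 10),
    hu_eat = list(type = "binmix", probs = probs), seed = 21))
  expect_gt(sum(ph$eat$data), 1e4)
  h <- hu_histogram_features(ph$volume, ph$eat, 8)
  expect_lt(abs(h[["Pro_50_30"]] - 0.37), 0.01)
})

test_that("ray-cast thickness matches spherical-shell geometry", {
  ph <- generate_phantom(shell_phantom(r_mm = 25, t_mm = 8, h_mm = 1))
  tm <- thickness_map(ph$eat, ph$sac)
  expect_equal(length(tm), 64800L)
  expect_equal(dim(unclass(tm)), c(180L, 360L))
  tol <- min(ph$sac$spacing) / 2 + sqrt(sum(ph$sac$spacing^2)) / 2
  expect_true(all(tm >= 8 - tol & tm <= 8 + tol))
})

test_that("rays through fat-free directions report zero thickness", {
  ph <- generate_phantom(shell_phantom(r_mm = 20, t_mm = 6, h_mm = 1))
  # keep fat only where x exceeds the centroid by a voxel margin (so the
  # voxelized polar cap cannot leak across x = 0): azimuths with a clearly
  # negative x-component see no fat at any polar angle
  ctr <- (dim(ph$eat$data)[3] - 1) / 2
  hemi <- ph$eat$data
  hemi[, , seq_len(floor(ctr) + 2)] <- FALSE
  tm <- thickness_map(binary_mask(hemi, ph$eat$spacing), ph$sac)
  v <- unclass(tm)
  expect_true(all(v[, 136:226] == 0)) # theta in [135, 225] degrees
  expect_true(any(v[, c(1:45, 315:360)] > 0))
})

test_that("thickness features summarize the 64,800 measurements", {
  const <- structure(matrix(10, 180, 360), class = c("thickness_map", "matrix"))
  tf <- thickness_features(const)
  expect_equal(unname(tf["Thickness_Mean"]), 10)
  expect_equal(unname(tf["Thickness_Max"]), 10)
  expect_equal(unname(tf["Thickness_SD"]), 0)
  expect_equal(unname(tf["Thickness_Frac_8_16"]), 1)
  expect_equal(unname(tf["Thickness_N_8_16"]), 64800)

  ph <- generate_phantom(shell_phantom(r_mm = 22, t_mm = 10, h_mm = 1))
  tf2 <- thickness_features(thickness_map(ph$eat, ph$sac))
  expect_equal(unname(tf2["Thickness_Max"]), 10, tolerance = 0.15)
  expect_equal(sum(tf2[grep("^Thickness_Frac_", names(tf2))]), 1)
})

test_that("full extraction yields 148 uniquely named, conserved features", {
  ph <- generate_phantom(small_ellipsoid_phantom(
    seed = 6, hu_eat = list(type = "gaussian", mean = -85, sd = 25)))
  fv <- extract_features(ph$volume, ph$sac)
  expect_length(fv, 148L)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_identical(names(fv), feature_catalog()$name)

  # slab and shell EAT volumes are conserved
  expect_equal(sum(fv[paste0("Vol_PQ", 1:4)]), unname(fv["EAT_vol"]))
  expect_equal(sum(fv[paste0("Vol_Shell", 1:4)]), unname(fv["EAT_vol"]))
  # 8-bin volumes equal the (windowed) EAT volume
  expect_equal(sum(fv[c("vol_190_170", "vol_170_150", "vol_150_130", "vol_130_110",
                        "vol_110_90", "vol_90_70", "vol_70_50", "vol_50_30")]),
               unname(fv["EAT_vol"]))
  expect_true(all(fv[grep("^Pro_", names(fv))] >= 0))
  expect_true(all(fv[grep("^Pro_", names(fv))] <= 1))
  expect_true(all(fv[grep("^(vol_|Vol_|EAT_vol|SAC_vol)", names(fv))] >= 0))
})

test_that("extraction is deterministic and geometry ignores the HU seed", {
  spec1 <- small_ellipsoid_phantom(seed = 31,
                                   hu_eat = list(type = "gaussian", mean = -85, sd = 0))
  ph1 <- generate_phantom(spec1)
  fv_a <- extract_features(ph1$volume, ph1$sac)
  fv_b <- extract_features(ph1$volume, ph1$sac)
  expect_identical(unclass(fv_a)[seq_along(fv_a)], unclass(fv_b)[seq_along(fv_b)])

  # different HU noise seed, same geometry: morphology identical
  spec2 <- small_ellipsoid_phantom(seed = 77,
                                   hu_eat = list(type = "gaussian", mean = -85, sd = 0))
  ph2 <- generate_phantom(spec2)
  morph <- c("EAT_vol", "SAC_vol", "EAT_frac", "Major_Axis", "Intermediate_Axis",
             "Minor_Axis", "Aspect_Ratio")
  expect_identical(fv_a[morph], extract_features(ph2$volume, ph2$sac)[morph])
})

test_that("rotating a phantom about z leaves thickness statistics stable", {
  ph <- generate_phantom(phantom_spec(
    dim = c(30, 60, 60), spacing = c(2, 1.5, 1.5), semiaxes = c(26, 40, 34),
    thickness = list(type = "lobed", t0 = 9, a = 3),
    hu_eat = list(type = "gaussian", mean = -80, sd = 0), seed = 13))
  rot90z <- function(m) { # (z, y, x) -> 90 deg about z for square in-plane grids
    binary_mask(aperm(m$data, c(1, 3, 2))[, , dim(m$data)[2]:1], m$spacing)
  }
  tf1 <- thickness_features(thickness_map(ph$eat, ph$sac))
  tf2 <- thickness_features(thickness_map(rot90z(ph$eat), rot90z(ph$sac)))
  expect_equal(unname(tf1["Thickness_Mean"]), unname(tf2["Thickness_Mean"]),
               tolerance = 0.02)
  expect_equal(unname(tf1["Thickness_Max"]), unname(tf2["Thickness_Max"]),
               tolerance = 0.05)
})
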