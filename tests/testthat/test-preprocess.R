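# Denoising chain: smoothing, temporal filtering, masking, nuisance
# regression, motion correction.

test_that("smoothing leaves constants unchanged and conserves impulse mass", {
  d <- c(16, 16, 10)
  const <- array(5, dim = d)
  sm <- smooth_gaussian(const, fwhm_mm = 4, voxel_size = c(3.4, 3.4, 5))
  interior <- sm[3:14, 3:14, 3:8]
  expect_lt(max(abs(interior - 5)), 1e-10)
  imp <- array(0, dim = d)
  imp[8, 8, 5] <- 1
  smi <- smooth_gaussian(imp, fwhm_mm = 4, voxel_size = c(3.4, 3.4, 5))
  expect_equal(sum(smi), 1, tolerance = 1e-6)
})

test_that("impulse peak equals the product of sampled-kernel centers", {
  vx <- c(3.4, 3.4, 5)
  fwhm <- 4
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / vx
  # independent closed-form evaluation of the sampled, normalized kernel
  centre <- vapply(sigma_vox, function(s) {
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    (k / sum(k))[r + 1]
  }, numeric(1))
  imp <- array(0, dim = c(15, 15, 9))
  imp[8, 8, 5] <- 1
  smi <- smooth_gaussian(imp, fwhm_mm = fwhm, voxel_size = vx)
  expect_equal(smi[8, 8, 5], prod(centre), tolerance = 1e-10)
  expect_error(smooth_gaussian(imp, fwhm_mm = -1, voxel_size = vx),
               "non-negative")
})

test_that("high-pass filtering rejects drift, preserves mean and the alternation frequency", {
  tr <- 3400
  nt <- 104
  # pure DC
  y <- matrix(7, 1, nt)
  yf <- highpass_butterworth(y, tr_ms = tr)
  expect_lt(max(abs(yf - 7)), 1e-8)
  # slow sinusoid on a long series: attenuation equals the squared
  # magnitude response (forward-backward) at that frequency
  fs <- 1000 / tr
  bf <- signal::butter(2, 0.01 / (fs / 2), type = "high")
  nlong <- 4000
  tt <- (0:(nlong - 1)) / fs
  for (f0 in c(0.001, 0.004)) {
    # analytic forward-backward gain |H(e^{i w})|^2 from the digital
    # transfer function itself
    z <- exp(1i * 2 * pi * f0 / fs)
    hz <- sum(bf$b * z^-(seq_along(bf$b) - 1)) /
      sum(bf$a * z^-(seq_along(bf$a) - 1))
    gain2 <- Mod(hz)^2
    y <- matrix(sin(2 * pi * f0 * tt), 1)
    yf <- highpass_butterworth(y, tr_ms = tr)
    mid <- 1000:3000
    # project the filtered mid-series onto the sinusoid basis to isolate
    # the amplitude at f0 from the re-added mean
    s_b <- sin(2 * pi * f0 * tt[mid]); c_b <- cos(2 * pi * f0 * tt[mid])
    co <- stats::coef(stats::lm(yf[mid] ~ s_b + c_b))
    amp <- sqrt(co["s_b"]^2 + co["c_b"]^2)
    expect_lt(abs(amp - gain2), 0.05 * gain2 + 1e-4)
  }
  # label/control alternation at Nyquist is preserved within 1%
  alt <- matrix(rep(c(1, -1), nt / 2) * 3 + 10, 1)
  altf <- highpass_butterworth(alt, tr_ms = tr)
  mid <- 20:84
  expect_lt(max(abs(altf[mid] - alt[mid])) / 3, 0.01)
  # cutoff at or above Nyquist is rejected
  expect_error(highpass_butterworth(alt, cutoff_hz = fs / 2, tr_ms = tr),
               "Nyquist")
})

test_that("brain mask covers the tissue, is scale-free, and rejects empty input", {
  m0 <- m0_volume(fx_clean$series)
  mask <- make_brain_mask(m0)
  ts <- fx_clean$tissue
  tissue_sum <- ts$gm + ts$wm + ts$csf
  expect_true(all(mask[tissue_sum > 0.5]))
  expect_identical(mask, make_brain_mask(m0 * 1000))
  expect_error(make_brain_mask(array(0, dim = c(8, 8, 4))), "empty")
})

test_that("nuisance timecourses equal brute-force segment means", {
  ser <- fx_noisy$series
  ts <- fx_noisy$tissue
  mask <- make_brain_mask(m0_volume(ser))
  nu <- extract_nuisance_timecourses(ser, ts, mask)
  nt <- dim(ser$data)[4] - 1
  expect_length(nu$wm, nt)
  expect_length(nu$global, nt)
  # independent voxel loop for the WM mean at a few volumes
  wm_seg <- which(ts$wm > 0.9)
  for (v in c(2, 51, 105)) {
    vol <- ser$data[, , , v]
    acc <- 0
    for (ix in wm_seg) acc <- acc + vol[ix]
    expect_equal(nu$wm[v - 1], acc / length(wm_seg), tolerance = 1e-12)
  }
  # uniform series gives constant timecourses equal to the value
  d <- dim(ser$data)[1:3]
  uni <- asl_series(array(4.2, dim = c(d, 5)), ser$affine,
                    volume_labels = c("m0", "label", "control",
                                      "label", "control"))
  nuu <- extract_nuisance_timecourses(uni, ts, mask)
  expect_true(all(abs(nuu$global - 4.2) < 1e-12))
  expect_true(all(abs(nuu$csf - 4.2) < 1e-12))
  # empty segment is reported by name
  ts_bad <- ts
  ts_bad$csf <- ts$csf * 0
  expect_error(extract_nuisance_timecourses(ser, ts_bad, mask), "CSF")
})

test_that("nuisance regression removes regressors but keeps the alternation signal", {
  d <- c(6, 6, 4)
  nt <- 20
  set.seed(31)
  alt <- rep(c(-1, 1), nt / 2)
  # a motion-like regressor orthogonal to the protected intercept and
  # alternation directions, so its component is fully removable
  motion_tc <- stats::rnorm(nt)
  motion_tc <- stats::residuals(stats::lm(motion_tc ~ alt))
  pure <- array(0, dim = c(d, nt + 1))
  for (v in seq_len(nt)) pure[, , , v + 1] <- 100 + 5 * alt[v]
  labels <- make_volume_labels(nt + 1)
  # series = pure alternation + one motion-coupled component
  contaminated <- pure
  for (v in seq_len(nt)) {
    contaminated[, , , v + 1] <- contaminated[, , , v + 1] + 2 * motion_tc[v]
  }
  ser <- asl_series(contaminated, voxel_affine(c(3, 3, 3)),
                    volume_labels = labels)
  nu <- structure(list(motion = cbind(tx = motion_tc, ty = 0, tz = 0,
                                      rx = 0, ry = 0, rz = 0),
                       global = rep(0, nt), wm = rep(0, nt),
                       csf = rep(0, nt)),
                  class = "nuisance_set")
  out <- suppressWarnings(regress_nuisance(ser, nu))
  expect_equal(out$data[, , , -1], pure[, , , -1], tolerance = 1e-8)
  # residual orthogonality to the removed regressor
  y <- out$data[3, 3, 2, -1]
  expect_lt(abs(sum(y * motion_tc)), 1e-8)
  # all-zero nuisance leaves the series unchanged
  nu0 <- structure(list(motion = matrix(0, nt, 6), global = rep(0, nt),
                        wm = rep(0, nt), csf = rep(0, nt)),
                   class = "nuisance_set")
  expect_equal(regress_nuisance(ser, nu0)$data, ser$data)
})

test_that("unprotected regression leaves residuals orthogonal to every regressor", {
  nt <- 24
  set.seed(7)
  d <- c(5, 5, 3)
  data <- array(stats::rnorm(prod(d) * (nt + 1)), dim = c(d, nt + 1))
  ser <- asl_series(data, voxel_affine(c(3, 3, 3)),
                    volume_labels = make_volume_labels(nt + 1))
  nu <- structure(list(motion = matrix(stats::rnorm(nt * 6), nt, 6),
                       global = stats::rnorm(nt), wm = stats::rnorm(nt),
                       csf = stats::rnorm(nt)),
                  class = "nuisance_set")
  out <- regress_nuisance(ser, nu, protect_alternation = FALSE)
  y <- t(matrix(out$data[, , , -1], ncol = nt))   # nt x voxels
  regs <- cbind(nu$motion, nu$global, nu$wm, nu$csf)
  # sample correlation numerators between every residual timecourse and
  # every removed regressor
  cors <- crossprod(sweep(regs, 2, colMeans(regs)),
                    sweep(y, 2, colMeans(y)))
  expect_lt(max(abs(cors)), 1e-8)
})

test_that("motion correction recovers known shifts and rigid schedules", {
  sp <- phantom_spec(grid_shape = c(24, 24, 10), n_volumes = 9,
                     noise_sd = 0, drift_amplitude = 0, seed = 8)
  tp <- make_tissue_phantom(sp)
  ser <- simulate_subject_series(sp, ground_truth(tp$cbf_true, tp$tissue))
  # motionless noise-free: parameters essentially zero
  mc0 <- motion_correct(ser)
  expect_lt(max(abs(mc0$motion[, 1:3])), 0.01)
  expect_lt(max(abs(mc0$motion[, 4:6])), 0.01)
  # one volume shifted by exactly +1 voxel in x
  ser1 <- ser
  ser1$data[, , , 2] <- resample_rigid(ser$data[, , , 2], ser$affine,
                                       c(3.4, 0, 0, 0, 0, 0))
  mc1 <- motion_correct(ser1)
  expect_lt(abs(mc1$motion[2, 1] - 3.4) / 3.4, 0.1)
  # all-zero volume is flagged with zero parameters
  ser2 <- ser
  ser2$data[, , , 3] <- 0
  mc2 <- motion_correct(ser2)
  expect_true(3 %in% mc2$flagged)
  expect_true(all(mc2$motion[3, ] == 0))
})

test_that("estimated motion tracks a known schedule at default noise", {
  set.seed(12)
  nvol <- 15
  ms <- matrix(0, nvol, 6)
  ms[3:nvol, 1] <- cumsum(stats::rnorm(nvol - 2, 0, 0.4))
  ms[3:nvol, 2] <- stats::rnorm(nvol - 2, 0, 0.8)
  ms[3:nvol, 6] <- stats::rnorm(nvol - 2, 0, 1.5)
  sp <- phantom_spec(grid_shape = c(24, 24, 10), n_volumes = nvol,
                     motion_schedule = ms, seed = 21)
  tp <- make_tissue_phantom(sp)
  ser <- simulate_subject_series(
    sp, ground_truth(tp$cbf_true, tp$tissue, motion = ms))
  mc <- motion_correct(ser)
  for (a in c(1, 2, 6)) {
    expect_gt(stats::cor(mc$motion[-1, a], ms[-1, a]), 0.9)
  }
})

test_that("preprocessing chain preserves the deep-GM perfusion difference", {
  pp <- suppressWarnings(preprocess_asl(fx_clean$series, fx_clean$tissue))
  gm_deep <- fx_clean$tissue$gm > 0.95
  before <- pairwise_subtract(fx_clean$series)
  after <- pairwise_subtract(pp$series)
  m_before <- mean(apply(before$dm, 4, function(x) mean(x[gm_deep])))
  m_after <- mean(apply(after$dm, 4, function(x) mean(x[gm_deep])))
  expect_lt(abs(m_after - m_before) / abs(m_before), 0.02)
  # grids are never changed by preprocessing
  expect_identical(dim(pp$series$data), dim(fx_clean$series$data))
})
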