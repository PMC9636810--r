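test_that("pd_from_landmarks converts margin distances with the pixel pitch", {
  ann <- toy_annotation(
    margins = rep(list(rbind(c(100, 200), c(180, 200))), 3),
    acas = rep(list(rbind(c(10, 50), c(200, 50))), 3))
  tr <- pd_from_landmarks(ann)
  expect_equal(tr$pd, rep(80 * 0.0125, 3))  # 80 px * 0.0125 mm/px = 1 mm
  expect_equal(tr$t, (0:2) / 8)

  # coincident points: PD = 0 plus a validation warning
  ann0 <- toy_annotation(
    margins = rep(list(rbind(c(5, 5), c(5, 5))), 3),
    acas = rep(list(rbind(c(1, 1), c(2, 2))), 3))
  w <- testthat::capture_warnings(tr0 <- pd_from_landmarks(ann0))
  expect_true(any(grepl("coincident", w)))
  expect_equal(tr0$pd, rep(0, 3))

  # a missing margin annotation is reported with its frame index
  ann_bad <- toy_annotation(
    margins = list(rbind(c(0, 0), c(8, 0)), NULL, rbind(c(0, 0), c(8, 0))),
    acas = rep(list(rbind(c(1, 1), c(2, 2))), 3))
  expect_error(pd_from_landmarks(ann_bad), "frame 1")
})

test_that("window detection applies the onset rule and earliest-minimum end", {
  tr <- pupil_trajectory(c(4, 4, 4, 3.5, 3.0, 2.5, 2.5), fps = 8)
  w <- detect_constriction_window(tr)
  expect_equal(w$onset_idx - 1L, 3L)  # 0-based: first of two fast-decrease frames
  expect_equal(w$end_idx - 1L, 5L)    # earliest of the tied minima

  expect_error(detect_constriction_window(pupil_trajectory(rep(4, 10), fps = 8)),
               "no constriction")

  # noiseless quadratic with latency 1 s: onset within 2 frames of t = 1 s
  p <- plr_params(4, 1, latency = 1, duration = 1, recovery_rate = 0.3,
                  noise_sd = 0, profile = "quadratic")
  tr2 <- simulate_trajectory(p, fps = 8, record_len = 3)
  w2 <- detect_constriction_window(tr2)
  expect_lte(abs(tr2$t[w2$onset_idx] - 1), 2 / 8)
  expect_equal(tr2$t[w2$end_idx], 2)

  expect_error(constriction_window(5, 3, 10), "onset < end")
})

test_that("transient series are adjacent-frame finite differences", {
  tr <- pupil_trajectory(c(4.0, 3.9, 3.7), fps = 8)
  ts <- transient_series(tr, constriction_window(1, 3, 3))
  expect_equal(ts$velocity, c(0.8, 1.6))
  expect_equal(ts$acceleration, 6.4)

  # linear constriction: constant velocity, zero acceleration
  pl <- plr_params(4, 2, latency = 0, duration = 2, recovery_rate = 0,
                   noise_sd = 0, profile = "linear")
  trl <- simulate_trajectory(pl, fps = 8, record_len = 2.25)
  w <- constriction_window(1, 17, nrow(trl))
  tsl <- transient_series(trl, w)
  expect_equal(tsl$velocity, rep(1, 16))
  expect_equal(tsl$acceleration, rep(0, 15))

  expect_error(transient_series(tr, constriction_window(1, 2, 3)), "at least 3")

  # calculus limit: for PD = 4 - t^2, v equals the slope 2t at each
  # difference midpoint and acc is exactly 2 inside the constriction
  trq <- noiseless_quadratic(fps = 512)
  wq <- constriction_window(1, which.min(trq$pd), nrow(trq))
  tsq <- transient_series(trq, wq)
  mids <- trq$t[seq_along(tsq$velocity)] + 1 / 1024
  expect_equal(tsq$velocity, 2 * mids, tolerance = 1e-9)
  expect_equal(tsq$acceleration, rep(2, length(tsq$acceleration)))
})

test_that("quadratic fit is exact on quadratics and matches normal equations", {
  # exact interpolation of y = 0.3 x^2 - 1.2 x + 4
  t <- (0:20) / 8
  tr <- pupil_trajectory(0.3 * t^2 - 1.2 * t + 4, fps = 8)
  f <- fit_quadratic(tr, full_window(tr))
  expect_equal(c(f$a, f$b, f$c), c(0.3, -1.2, 4), tolerance = 1e-9)
  expect_lt(f$rss, 1e-12)

  fc <- fit_quadratic(pupil_trajectory(rep(2.5, 9), fps = 8),
                      constriction_window(1, 9, 9))
  expect_equal(c(fc$a, fc$b, fc$c), c(0, 0, 2.5), tolerance = 1e-12)

  # frames abscissa rescales the coefficients by fps, fps^2
  ff <- fit_quadratic(tr, full_window(tr), abscissa = "frames")
  expect_equal(ff$a, 0.3 / 64, tolerance = 1e-9)
  expect_equal(ff$b, -1.2 / 8, tolerance = 1e-9)

  # brute-force normal-equations oracle on random instances
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    pd <- abs(rnorm(n, 4, 0.5)) + 0.5
    trr <- pupil_trajectory(pd, fps = 8)
    fr <- fit_quadratic(trr, constriction_window(1, n, n))
    X <- cbind(1, trr$t, trr$t^2)
    beta <- solve(t(X) %*% X, t(X) %*% pd)
    expect_equal(c(fr$c, fr$b, fr$a), as.numeric(beta), tolerance = 1e-10)
  }

  # noisy quadratic: recovered curvature unbiased within 3 SE over 200 seeds
  a_hat <- vapply(1:200, function(s) {
    set.seed(s)
    tt <- (0:63) / 64
    y <- 4 - 1.5 * tt + 0.8 * tt^2 + rnorm(64, 0, 0.02)
    trn <- pupil_trajectory(y, fps = 64)
    fit_quadratic(trn, constriction_window(1, 64, 64))$a
  }, numeric(1))
  expect_lt(abs(mean(a_hat) - 0.8), 3 * sd(a_hat) / sqrt(200))
})

test_that("kinematic summary reproduces closed forms for noiseless profiles", {
  # linear constriction 4 -> 2 over 2 s
  pl <- plr_params(4, 2, latency = 0, duration = 2, recovery_rate = 0,
                   noise_sd = 0, profile = "linear")
  trl <- simulate_trajectory(pl, fps = 8, record_len = 2.25)
  kl <- kinematic_summary(trl, window = constriction_window(1, 17, nrow(trl)))
  expect_equal(kl$vpc_mean, 1); expect_equal(kl$vpc_max, 1)
  expect_equal(kl$apc_mean, 0); expect_equal(kl$apc_max, 0)
  expect_equal(kl$apc_fitting, 0, tolerance = 1e-9)

  # quadratic PD = 4 - t^2 on [0,1]: vpc_mean 1, vpc_max 2, apc* 2, 2|a| = 2
  for (fps in c(64, 256)) {
    tr <- noiseless_quadratic(fps = fps)
    ks <- kinematic_summary(tr, window = constriction_window(1, which.min(tr$pd),
                                                             nrow(tr)))
    closed <- c(1, 2, 2, 2, 2)
    got <- c(ks$vpc_mean, ks$vpc_max, ks$apc_mean, ks$apc_max, ks$apc_fitting)
    expect_true(all(abs(got - closed) <= 2 / fps))
  }

  # with the detected window the head below v_on is cut; the telescoped
  # closed form over that window is still matched exactly
  tr <- noiseless_quadratic(fps = 256)
  ks <- kinematic_summary(tr)
  w <- ks$window
  dur <- (w$end_idx - w$onset_idx) / 256
  expect_equal(ks$vpc_mean, (tr$pd[w$onset_idx] - tr$pd[w$end_idx]) / dur)
  expect_equal(ks$apc_fitting, 2, tolerance = 2 / 256)
})

test_that("summary obeys the sum rule and scale equivariance", {
  set.seed(7)
  for (rep in 1:10) {
    p <- plr_params(baseline_pd = runif(1, 4, 6), amplitude = runif(1, 0.5, 1.5),
                    latency = runif(1, 0.3, 0.8), duration = runif(1, 0.8, 2),
                    recovery_rate = 0.3, noise_sd = 0.02,
                    profile = sample(c("quadratic", "logistic", "linear"), 1))
    tr <- simulate_trajectory(p, fps = 8, record_len = 4, seed = rep)
    ks <- kinematic_summary(tr)
    w <- ks$window
    dur <- (w$end_idx - w$onset_idx) / 8
    # telescoping: mean velocity times window duration equals the PD drop
    expect_equal(ks$vpc_mean * dur, tr$pd[w$onset_idx] - tr$pd[w$end_idx])

    # scaling PD by s scales all five parameters by s (same window supplied,
    # since the onset threshold is not scale-free)
    s <- 1.7
    trs <- pupil_trajectory(tr$pd * s, fps = 8)
    kss <- kinematic_summary(trs, window = w)
    ks0 <- kinematic_summary(tr, window = w)
    for (f in c("vpc_mean", "vpc_max", "apc_mean", "apc_max", "apc_fitting"))
      expect_equal(kss[[f]], s * ks0[[f]], tolerance = 1e-9)
  }
})

test_that("kinematics_table collects parameters and 0-based window indices", {
  trs <- lapply(1:3, function(i)
    simulate_trajectory(plr_params(), fps = 8, record_len = 3, seed = i,
                        video_id = paste0("v", i)))
  tab <- kinematics_table(trs)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("video_id", "vpc_mean", "vpc_max", "apc_mean", "apc_max",
                      "apc_fitting", "a", "b", "c", "onset_idx", "end_idx"))
  expect_true(all(tab$onset_idx >= 0 & tab$end_idx > tab$onset_idx))
  expect_true(all(tab$vpc_max >= tab$vpc_mean))
  expect_true(all(tab$apc_max >= tab$apc_mean))
})
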