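test_that("detrending annihilates lines and recovers superposed rhythms", {
  fs <- FIXTURE_FS
  n <- 7 * fs
  t <- (0:(n - 1)) / fs
  ramp <- 2.5 * t + 4
  sine <- sin(2 * pi * 10 * t)
  data <- array(0, dim = c(3, 2, n))
  data[1, , ] <- rbind(ramp, ramp)            # pure line
  data[2, , ] <- rbind(rep(7, n), rep(-3, n)) # constants
  data[3, , ] <- rbind(sine + 5 * t, sine)    # rhythm + drift
  ep <- epochs_from_array(data, fs, tmin = 0, channels = c("C3", "C4"))
  out <- linear_detrend(ep)
  expect_lt(max(abs(out$data[1, , ])), 1e-9)
  expect_lt(max(abs(out$data[2, , ])), 1e-9)
  ## closed-form oracle: the line least-squares-fitted to sine + drift
  fit <- lm(I(sine + 5 * t) ~ t)
  expected <- sine + 5 * t - fitted(fit)
  interior <- seq(round(n * 0.05), round(n * 0.95))
  expect_lt(max(abs(out$data[3, 1, interior] - expected[interior])), 0.01)
})

test_that("detrending is idempotent", {
  data <- array(rnorm(2 * 3 * 100), dim = c(2, 3, 100))
  ep <- epochs_from_array(data, 100, channels = c("C3", "Cz", "C4"))
  once <- linear_detrend(ep)
  twice <- linear_detrend(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
})

test_that("the montage obeys 10/20 geometry", {
  m <- standard_montage()
  expect_equal(unname(m$positions["Cz", ]), c(0, 0, 1))
  expect_lt(max(abs(rowSums(m$positions^2) - 1)), 1e-12)
  # sagittal mirror symmetry of homologs
  for (pair in list(c("C3", "C4"), c("F3", "F4"), c("T7", "T8"), c("P7", "P8"))) {
    l <- m$positions[pair[1], ]; r <- m$positions[pair[2], ]
    expect_equal(l[["z"]], r[["z"]], tolerance = 1e-12)
    expect_equal(l[["y"]], r[["y"]], tolerance = 1e-12)
    expect_equal(l[["x"]], -r[["x"]], tolerance = 1e-12)
  }
  expect_true(all(motor_channels() %in% m$labels))
  expect_error(standard_montage(c("C3", "XX9")), "XX9")
})

test_that("spline Laplacian matches the analytic answer on degree-1 harmonics", {
  ## surface Laplacian of a degree-n spherical harmonic is -n(n+1) x itself;
  ## cross-checked against a numerical tangent-plane Laplacian of the field
  m <- standard_montage()
  Tm <- laplacian_matrix(m)
  for (ax in 1:3) {
    f <- function(p) p[ax]
    v <- m$positions[, ax]
    got <- drop(Tm %*% v)
    oracle <- vapply(seq_len(30), function(i) {
      numeric_surface_laplacian(f, m$positions[i, ])
    }, numeric(1))
    expect_equal(max(abs(oracle - (-2 * v))) / max(abs(2 * v)), 0, tolerance = 1e-3)
    expect_lt(max(abs(got - oracle)) / max(abs(oracle)), 0.05)
  }
})

test_that("Laplacian kills constants, is linear and reference-invariant", {
  m <- standard_montage()
  Tm <- laplacian_matrix(m)
  expect_lt(max(abs(Tm %*% rep(5, 30))), 5 * 1e-6)

  x <- brainswitch:::with_seed(4, rnorm(30))
  y <- brainswitch:::with_seed(5, rnorm(30))
  expect_equal(drop(Tm %*% (2 * x - 3 * y)),
               drop(2 * (Tm %*% x) - 3 * (Tm %*% y)), tolerance = 1e-10)
  shifted <- drop(Tm %*% (x + 100))
  expect_lt(max(abs(shifted - drop(Tm %*% x))) / max(abs(Tm %*% x)), 1e-8)
})

test_that("a focal bump yields a peak at its electrode, opposite-signed neighbors", {
  m <- standard_montage()
  Tm <- laplacian_matrix(m)
  v <- as.numeric(m$labels == "C3")
  out <- drop(Tm %*% v)
  expect_equal(m$labels[which.max(abs(out))], "C3")
  ## a positive focal bump has a negative Laplacian at its peak and a
  ## positive side lobe within the surrounding electrode ring
  expect_lt(out[m$labels == "C3"], 0)
  ang <- brainswitch:::montage_angles_to(m, "C3")
  ring <- ang > 0 & ang < 0.7
  expect_true(any(out[ring] > 0))
  ## the response decays away from the bump
  expect_lt(max(abs(out[ang > 1.5])), 0.1 * abs(out[m$labels == "C3"]))
})

test_that("the epoch-level Laplacian applies the operator per time sample", {
  data <- array(rnorm(2 * 9 * 50), dim = c(2, 9, 50))
  ep <- epochs_from_array(data, 100, channels = motor_channels())
  out <- spherical_spline_laplacian(ep)
  Tm <- laplacian_matrix(standard_montage(motor_channels()))
  expect_equal(out$data[1, , ], Tm %*% data[1, , ], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(dim(out$data), dim(data))
})

test_that("spline parameter validation", {
  expect_error(spline_params(m = 1), "m")
  expect_error(spline_params(n_terms = 3), "n_terms")
  expect_error(spline_params(ridge = -1), "ridge")
})
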