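# direct least-squares projection oracle for the interior SG weights
sg_weights_oracle <- function(window, degree, deriv = 0) {
  half <- (window - 1) / 2
  X <- outer(-half:half, 0:degree, "^")
  H <- X %*% solve(crossprod(X)) %*% t(X)
  if (deriv == 0) H[half + 1, ] else NULL
}

test_that("SG smoothing reproduces polynomials and the 5-point weights", {
  x <- seq_len(40)
  quad <- toy_spectra(rbind(2 + 3 * x + 0.5 * x^2,
                            1 - x + 0.25 * x^2))
  sm <- sg_filter(quad, window = 5, degree = 2, deriv = 0)
  expect_lt(max(abs(unclass(sm) - unclass(quad))), 1e-10)

  # recover the interior impulse response and compare with the LS oracle
  imp <- toy_spectra(diag(11))
  filt <- unclass(sg_filter(imp, 5, 2, 0))
  weights <- unname(filt[4:8, 6])  # response at channel 6 to impulses 4..8
  expect_equal(weights, c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)
  expect_equal(sg_weights_oracle(5, 2), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
})

test_that("SG derivatives follow the analytic derivative with step scaling", {
  x <- seq_len(30)
  lin <- toy_spectra(matrix(5 + 2 * x, nrow = 1))
  d1 <- sg_filter(lin, 5, 2, deriv = 1)           # unit channel step
  expect_equal(as.numeric(unclass(d1)), rep(2, 30), tolerance = 1e-10)
  d1nm <- sg_filter(lin, 5, 2, deriv = 1, delta = 0.5)
  expect_equal(as.numeric(unclass(d1nm)), rep(4, 30), tolerance = 1e-10)
  quad <- toy_spectra(matrix(1 + x + 3 * x^2, nrow = 1))
  d2 <- sg_filter(quad, 5, 2, deriv = 2)
  expect_equal(as.numeric(unclass(d2)), rep(6, 30), tolerance = 1e-8)
})

test_that("SG parameter validation matches its preconditions", {
  m <- toy_spectra(matrix(rnorm(20), 2))
  expect_error(sg_filter(m, window = 4), "odd")
  expect_error(sg_filter(m, window = 3, degree = 3), "exceed")
  expect_error(sg_filter(m, window = 5, degree = 2, deriv = 3), "deriv")
  expect_error(sg_filter(toy_spectra(matrix(1:3, 1)), window = 5), "shorter")
})

test_that("MSC inverts affine scatter relative to the reference", {
  ref <- c(1, 2, 3, 5, 4, 6)
  m <- toy_spectra(rbind(2 * ref + 5, ref, -0.5 * ref + 1))
  out <- msc(m, reference = ref)
  for (i in 1:3) {
    expect_equal(as.numeric(unclass(out)[i, ]), ref, tolerance = 1e-10)
  }
  # closed-form 3-point case: (4,8,12) on reference (1,2,3) -> a=4, b=0
  out3 <- msc(toy_spectra(matrix(c(4, 8, 12), 1)), reference = c(1, 2, 3))
  expect_equal(as.numeric(unclass(out3)), c(1, 2, 3), tolerance = 1e-10)
  expect_error(msc(m, reference = rep(2, 6)), "zero variance")
})

test_that("MSC with a fixed reference is idempotent", {
  set.seed(4)
  sig <- sin(seq(0, 3, length.out = 25)) + 1
  m <- toy_spectra(t(sapply(1:5, function(i) {
    runif(1, 0.5, 2) * sig + runif(1, -0.3, 0.3) + rnorm(25, 0, 0.01)
  })))
  once <- msc(m, reference = sig)
  twice <- msc(once, reference = sig)
  expect_lt(max(abs(unclass(once) - unclass(twice))), 1e-10)
})

test_that("mean centering zeroes every wavelength column", {
  m <- toy_spectra(rbind(c(1, 3), c(5, 7)))
  out <- mean_center(m)
  expect_equal(unclass(out), rbind(c(-2, -2), c(2, 2)), ignore_attr = TRUE)
  same <- mean_center(toy_spectra(rbind(c(1, 2, 3), c(1, 2, 3))))
  expect_true(all(unclass(same) == 0))
  set.seed(5)
  big <- mean_center(toy_spectra(matrix(rnorm(200), 10)))
  expect_lt(max(abs(colMeans(unclass(big)))), 1e-12)
  expect_warning(mean_center(toy_spectra(matrix(1:4, 1))), "single")
})

test_that("pipelines parse, print their signature, and compose in order", {
  p <- nir_pipeline("SG(5,2)+D1+MSC+MC")
  expect_equal(pipeline_signature(p), "SG(5,2)+D1+MSC+MC")
  expect_length(p$steps, 4)
  expect_error(nir_pipeline("SG+XY"), "unknown")

  set.seed(6)
  m <- toy_spectra(matrix(rnorm(6 * 20, 10), 6))
  # empty pipeline is the identity
  expect_equal(unclass(apply_pipeline(m, "")), unclass(m),
               ignore_attr = TRUE)
  # centering is idempotent
  expect_equal(unclass(apply_pipeline(m, "MC+MC")),
               unclass(apply_pipeline(m, "MC")), ignore_attr = TRUE)
  # pipeline equals manual left-to-right application (smooth, then the
  # derivative filter, then MSC, then centering)
  auto <- apply_pipeline(m, "SG(5,2)+D1+MSC+MC")
  manual <- mean_center(msc(sg_filter(sg_filter(m, 5, 2, 0), 5, 2, 1)))
  expect_equal(unclass(auto), unclass(manual), ignore_attr = TRUE)
  expect_equal(attr(auto, "pipeline"), "SG(5,2)+D1+MSC+MC")
  # order matters: MSC then D1 differs from D1 then MSC
  expect_gt(max(abs(unclass(apply_pipeline(m, "MSC+D1")) -
                    unclass(apply_pipeline(m, "D1+MSC")))), 1e-6)
  # and MSC after centering is degenerate: the mean reference is zero
  expect_error(apply_pipeline(m, "MC+MSC"), "zero variance")
})

test_that("finite-difference derivatives are available as an alternative", {
  x <- seq_len(25)
  lin <- toy_spectra(matrix(3 + 2 * x, nrow = 1))
  expect_equal(as.numeric(unclass(fd_derivative(lin, 1))), rep(2, 25))
  p <- nir_pipeline("D1", derivative_method = "fd")
  expect_equal(unclass(apply_pipeline(lin, p)),
               unclass(fd_derivative(lin, 1)), ignore_attr = TRUE)
})

test_that("spectra CSV round-trips with a validated wavelength grid", {
  set.seed(7)
  m <- spectra_matrix(matrix(rnorm(12), 3), c(900, 1100, 1300, 1700),
                      c("a", "b", "c"))
  path <- tempfile(fileext = ".csv")
  write_spectra(m, path)
  back <- read_spectra(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "wavelengths"), attr(m, "wavelengths"))
  unlink(path)
  expect_error(spectra_matrix(matrix(1:4, 2), c(1000, 900)), "increasing")
  expect_error(spectra_matrix(matrix(c(1, NA), 1), c(900, 1000)), "missing")
})
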