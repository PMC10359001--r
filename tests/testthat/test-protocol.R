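test_that("within differences have the right count and vanish for constants", {
  a <- const_img(12, 12, 100, 100, 100)
  b <- const_img(12, 12, 90, 90, 90)
  m <- full_mask(a)
  cfg <- protocol_config(n_pixels = 50, n_resamples = 10, attrs = "R",
                         seed = 1)
  w <- within_differences(a, m, b, m, cfg)
  expect_equal(dim(w), c(10, 1))  # 2 * floor(10/2)
  expect_true(all(w == 0))
  cfg2 <- protocol_config(n_pixels = 50, n_resamples = 2, attrs = "R",
                          seed = 1)
  expect_equal(nrow(within_differences(a, m, b, m, cfg2)), 2)
  # explicit n_pixels beyond the mask is a parameter error
  bad <- protocol_config(n_pixels = 144, n_resamples = 10, seed = 1)
  expect_error(within_differences(a, m, b, m, bad), "n_pixels")
})

test_that("within-difference spread matches the bootstrap variance", {
  # two-value image (0/255 half-half): a bootstrap mean of n pixels has
  # sd 255/(2 sqrt(n)); a difference of two independent means sqrt(2) more
  img <- const_img(50, 100, 0, 0, 0)
  img[, 51:100, ] <- 255
  m <- full_mask(img)
  cfg <- protocol_config(n_pixels = 2500, n_resamples = 100, attrs = "R",
                         seed = 2)
  w <- within_differences(img, m, img, m, cfg)
  expect_equal(mean(w), 0, tolerance = 3)
  expect_lt(abs(sd(w) - sqrt(2) * 255 / (2 * sqrt(2500))),
            0.25 * sqrt(2) * 255 / (2 * sqrt(2500)))
})

test_that("between difference is the difference of full-mask band means", {
  a <- const_img(8, 8, 100, 60, 40)
  b <- const_img(8, 8, 90, 55, 45)
  m <- full_mask(a)
  expect_equal(between_difference(a, m, a, m, "R"), c(R = 0))
  expect_equal(between_difference(a, m, b, m, "R"), c(R = 10))
  expect_equal(between_difference(a, m, b, m, c("R", "G", "B")),
               c(R = 10, G = 5, B = -5))
  # hand-built 4-pixel images
  ha <- const_img(2, 2, 0, 0, 0); ha[, , 1] <- c(10, 20, 30, 40)
  hb <- const_img(2, 2, 0, 0, 0); hb[, , 1] <- c(10, 10, 10, 10)
  expect_equal(between_difference(ha, full_mask(ha), hb, full_mask(hb), "R"),
               c(R = 25 - 10))
})

test_that("combined covariance uses n-1 and supports the pooled mode", {
  w <- matrix(c(-1, 1), ncol = 1)
  expect_equal(combined_covariance(w)[1, 1], 2)
  set.seed(15)
  w3 <- matrix(rnorm(60), ncol = 3)
  S <- combined_covariance(w3)
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE)$values > -1e-12))
  Sp <- combined_covariance(w3, between = c(5, 5, 5), mode = "pooled")
  expect_equal(Sp, cov(rbind(w3, c(5, 5, 5))))
  expect_error(combined_covariance(matrix(1:3, 1)), "raise n_resamples")
  expect_error(combined_covariance(w3[1:3, ], mode = "within"),
               "raise n_resamples")
})

test_that("the Mahalanobis quadratic form matches hand calculations", {
  expect_equal(d2_statistic(c(1, 2), c(1, 2), diag(2)), 0)
  expect_equal(d2_statistic(3, 1, matrix(4)), 1.0)
  expect_equal(d2_statistic(c(3, 4), c(0, 0), diag(2)), 25)
  expect_error(d2_statistic(c(1, 0), c(0, 0), matrix(0, 2, 2)), "singular")
  expect_warning(
    d2 <- d2_statistic(c(1, 0), c(0, 0), diag(c(1, 0)),
                       singular = "pseudoinverse"),
    "pseudoinverse"
  )
  expect_equal(d2, 1)
})

test_that("chi-squared p-values match integration and closed-form oracles", {
  expect_equal(chisq_pvalue(0, 1), 1.0)
  # df=1 oracle: numeric integration of the chi-squared density
  dens1 <- function(x) exp(-x / 2) / sqrt(2 * pi * x)
  oracle1 <- integrate(dens1, 3.8415, Inf, rel.tol = 1e-10)$value
  expect_equal(chisq_pvalue(3.8415, 1), oracle1, tolerance = 1e-9)
  expect_equal(chisq_pvalue(3.8415, 1), 0.05, tolerance = 1e-3)
  # df=2 closed form: upper tail is exp(-x/2)
  expect_equal(chisq_pvalue(5.9915, 2), exp(-5.9915 / 2), tolerance = 1e-12)
  expect_equal(chisq_pvalue(2 * log(20), 2), 0.05, tolerance = 1e-12)
  expect_error(chisq_pvalue(-1, 1), "nonnegative")
  expect_error(chisq_pvalue(1, 0), "df")
})

test_that("the full protocol is seed-reproducible and symmetric in its math", {
  set.seed(16)
  a <- noise_leaf_img(40, 40, 110, 12)
  b <- noise_leaf_img(40, 40, 118, 12)
  cfg <- protocol_config(seed = 5)
  r1 <- d2_test(a, b, config = cfg)
  r2 <- d2_test(a, b, config = cfg)
  expect_equal(r1$statistic, r2$statistic)
  expect_s3_class(r1, "htest")
  expect_equal(unname(r1$parameter), 1)
  expect_equal(r1$p.value, chisq_pvalue(unname(r1$statistic), 1))
  expect_equal(r1$n_within, 100)
  # sign symmetry: negating between and within leaves D^2 unchanged
  w <- within_differences(a, segment_leaf(a), b, segment_leaf(b), cfg)
  bet <- between_difference(a, segment_leaf(a), b, segment_leaf(b), "R")
  d2ab <- d2_statistic(bet, colMeans(w), combined_covariance(w))
  d2ba <- d2_statistic(-bet, colMeans(-w), combined_covariance(-w))
  expect_equal(d2ab, d2ba)
})

test_that("D^2 is invariant under a common affine rescaling of intensities", {
  set.seed(17)
  a <- noise_leaf_img(40, 40, 60, 8)
  b <- noise_leaf_img(40, 40, 64, 8)
  mask <- ellipse_mask(40, 40)
  cfg <- protocol_config(seed = 9)
  r <- d2_test(a, b, mask, mask, config = cfg)
  r_scaled <- d2_test(2 * a + 10, 2 * b + 10, mask, mask, config = cfg)
  expect_equal(unname(r_scaled$statistic), unname(r$statistic),
               tolerance = 1e-10)
})

test_that("degenerate inputs surface as singular-covariance errors", {
  a <- const_img(12, 12, 100, 100, 100)
  b <- const_img(12, 12, 90, 90, 90)
  m <- full_mask(a)
  cfg <- protocol_config(n_pixels = 30, seed = 1)
  expect_error(d2_test(a, b, m, m, config = cfg), "singular")
})

test_that("an image against its own copy rarely rejects", {
  set.seed(18)
  rejected_001 <- logical(40)
  for (k in 1:40) {
    img <- noise_leaf_img(36, 36, 115, 12)
    mask <- ellipse_mask(36, 36)
    r <- d2_test(img, img, mask, mask, config = protocol_config(seed = k))
    rejected_001[k] <- r$p.value <= 0.01
  }
  expect_gte(mean(!rejected_001), 0.9)
})

test_that("batch pair testing matches the single-pair entry point", {
  set.seed(19)
  imgs <- list(x = noise_leaf_img(36, 36, 110, 10),
               y = noise_leaf_img(36, 36, 120, 10),
               z = noise_leaf_img(36, 36, 150, 10))
  pairs <- data.frame(sample_a = c("x", "x"), sample_b = c("y", "z"),
                      pair_class = c("C1", "C3"))
  res <- d2_test_pairs(imgs, pairs, protocol_config(seed = 21))
  expect_equal(nrow(res), 2)
  expect_true(all(res$d2 >= 0))
  expect_equal(res$p_value, chisq_pvalue(res$d2, 1))
  single <- d2_test(imgs$x, imgs$y, config = protocol_config(seed = 21))
  expect_equal(res$d2[1], unname(single$statistic))
  expect_error(d2_test_pairs(imgs["x"], pairs), "missing")
})

test_that("QQ tables align exact chi-squared draws with the reference", {
  n <- 400
  exact <- qchisq((seq_len(n) - 0.5) / n, df = 1)
  qq <- qq_chisq(sample(exact), 1)
  expect_equal(qq$empirical, qq$theoretical, tolerance = 1e-12)
  flat <- qq_chisq(rep(2, 20), 1)
  expect_true(all(flat$empirical == 2))
  expect_error(qq_chisq(1:5, 1), "at least 10")
})

test_that("rejection rate grows with the between-image mean shift", {
  set.seed(20)
  shifts <- c(0, 1.5, 4)
  rej <- sapply(shifts, function(s) {
    mean(sapply(1:30, function(k) {
      a <- noise_leaf_img(36, 36, 110, 12)
      b <- noise_leaf_img(36, 36, 110 + s, 12)
      d2_test(a, b, ellipse_mask(36, 36), ellipse_mask(36, 36),
              config = protocol_config(seed = 100 * s + k))$p.value < 0.05
    }))
  })
  expect_true(all(diff(rej) >= 0))
  expect_gt(rej[3], rej[1])
})
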