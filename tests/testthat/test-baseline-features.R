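test_that("identical profiles zero out every difference attribute", {
  r <- c(10, 12, 11, 13, 15, 14, 12, 11, 10, 12, 13, 14)
  bf <- baseline_features(r, r, d = 3)
  expect_equal(bf$rms, 0)
  expect_equal(bf$delta_max, 0)
  expect_equal(bf$delta_min, 0)
  expect_equal(bf$sd_diff, 0)
  expect_identical(bf$sign_changes, 0L)
  expect_equal(bf$max_et_radius, 15)
  expect_equal(bf$min_et_radius, 10)
})

test_that("toy profile reproduces the closed-form attribute values", {
  bf <- baseline_features(c(3, 5, 4), c(4, 4, 4), d = 2)
  expect_equal(bf$rms, sqrt(2 / 3))      # differences (-1, 1, 0)
  expect_equal(bf$delta_max, 1)
  expect_equal(bf$delta_min, -1)
  expect_identical(bf$sign_changes, 1L)
  expect_equal(bf$sd_diff, sd(c(-1, 1, 0)))
  expect_equal(bf$sd_ht_radius, sd(c(3, 5, 4)))
})

test_that("RMS identity and MRT of shift-constant profiles", {
  set.seed(5)
  for (trial in 1:20) {
    n <- sample(10:50, 1)
    ht <- runif(n, 20, 80); et <- runif(n, 20, 80)
    d <- sample(2:(n - 1), 1)
    bf <- baseline_features(ht, et, d = d)
    expect_equal(bf$rms^2 * n, sum((ht - et)^2))     # algebraic identity
    expect_gte(bf$mrt, 0)
  }
  # constant profile has zero mean relative tremor at any displacement
  expect_equal(baseline_features(rep(7, 30), runif(30), d = 10)$mrt, 0)
  # MRT in verbatim template mode reads the ET profile instead
  ht <- runif(30); et <- rep(3, 30)
  expect_equal(baseline_features(ht, et, d = 5, mrt_on = "et")$mrt, 0)
  expect_gt(baseline_features(ht, et, d = 5, mrt_on = "ht")$mrt, 0)
})

test_that("attributes are scale-equivariant; sign changes are invariant", {
  set.seed(6)
  ht <- runif(36, 30, 60); et <- runif(36, 30, 60)
  b1 <- baseline_features(ht, et, d = 4)
  s <- 2.5
  b2 <- baseline_features(s * ht, s * et, d = 4)
  for (f in c("rms", "delta_max", "delta_min", "sd_diff", "mrt",
              "max_et_radius", "min_et_radius", "sd_ht_radius"))
    expect_equal(b2[[f]], s * b1[[f]], tolerance = 1e-12)
  expect_identical(b2$sign_changes, b1$sign_changes)
})

test_that("sign changes skip zero differences", {
  # differences: 1, 0, -1, 0, 1 -> nonzero signs 1, -1, 1 -> two flips
  ht <- c(5, 4, 3, 4, 5); et <- c(4, 4, 4, 4, 4)
  expect_identical(baseline_features(ht, et, d = 2)$sign_changes, 2L)
})

test_that("profile and attribute preconditions are enforced", {
  expect_error(baseline_features(1:5, 1:4, d = 2),
               class = "scmhand_dim_mismatch")
  expect_error(baseline_features(1:5, 5:1, d = 5),
               class = "scmhand_bad_param")
  expect_error(baseline_features(1:5, 5:1, d = 0),
               class = "scmhand_bad_param")
  single <- matrix(FALSE, 64, 64); single[32, 32] <- TRUE
  expect_error(radius_profile(single), class = "scmhand_degenerate")
})

test_that("radius profile recovers a circle and is translation-invariant", {
  circle_mask <- function(cx, cy, r0, size = 160) {
    m <- matrix(FALSE, size, size)
    th <- seq(0, 2 * pi, length.out = 3000)
    for (w in seq(-1.5, 1.5, by = 0.5))
      m[cbind(pmin(pmax(round(cy + (r0 + w) * sin(th)), 1), size),
              pmin(pmax(round(cx + (r0 + w) * cos(th)), 1), size))] <- TRUE
    m
  }
  p <- radius_profile(circle_mask(80, 80, 50), n = 36)
  expect_true(all(abs(p$radii - 50) <= 1))
  q <- radius_profile(circle_mask(70, 88, 50), n = 36)
  expect_equal(q$radii, p$radii, tolerance = 0.05)
  expect_equal(q$center - p$center, c(8, -10), tolerance = 0.5)
})
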