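test_that("rendered templates follow the analytic polar curve", {
  for (fmt in c("spiral", "meander")) {
    spec <- fixture_spec(fmt)
    tm <- render_template(spec)
    expect_true(any(tm$mask))
    expect_identical(dim(tm$mask), c(256L, 256L))
    # drawn pixels and raster agree
    expect_true(all(tm$raster[tm$mask] == 0))
    expect_true(all(tm$raster[!tm$mask] == 255))
    # every mask pixel lies within the stroke tolerance of the curve at some
    # unwrapped angle theta + 2*pi*k
    pix <- which(tm$mask, arr.ind = TRUE)
    ctr <- (spec$image_size + 1) / 2
    rho <- sqrt((pix[, 1] - ctr)^2 + (pix[, 2] - ctr)^2)
    phi <- atan2(pix[, 1] - ctr, pix[, 2] - ctr) %% (2 * pi)
    tol <- ceiling(spec$stroke_width_px / 2) + 1 +
      spec$meander_depth_px * (fmt == "meander")
    dev <- sapply(seq_along(rho), function(k) {
      th <- phi[k] + 2 * pi * (0:(spec$turns + 1))
      min(abs(rho[k] - spec$growth_px_per_rad * th))
    })
    expect_lt(max(dev), tol + 1e-9)
  }
})

test_that("template curve is a single connected stroke", {
  tm <- render_template(fixture_spec())
  lab <- EBImage::bwlabel(EBImage::Image(t(tm$mask * 1)))
  expect_equal(max(lab), 1)
})

test_that("invalid template and subject parameters are rejected", {
  expect_error(template_spec(turns = 0), class = "scmhand_bad_param")
  expect_error(template_spec(image_size = 64), class = "scmhand_bad_param")
  # too many turns at an explicit growth rate cannot fit the image
  expect_error(template_spec(turns = 12, growth_px_per_rad = 10),
               class = "scmhand_bad_param")
  expect_error(subject_spec("CG", tremor_amplitude_px = -1),
               class = "scmhand_bad_param")
  expect_error(subject_spec("PG", tremor_amplitude_px = 0),
               class = "scmhand_bad_param")
})

test_that("zero-perturbation trace reproduces the template", {
  spec <- fixture_spec()
  tm <- render_template(spec)
  tr <- render_trace(spec, subject_spec("CG", tremor_amplitude_px = 0,
                                        jitter_sd_px = 0, seed = 5))
  expect_identical(tr$mask, tm$mask)
})

test_that("traces are deterministic in the seed", {
  spec <- fixture_spec()
  s <- subject_spec("PG", seed = 42)
  expect_identical(render_trace(spec, s), render_trace(spec, s))
  s2 <- subject_spec("PG", seed = 43)
  expect_false(identical(render_trace(spec, s)$mask,
                         render_trace(spec, s2)$mask))
})

test_that("tremor amplitude drives the radial deviation (RMS in A/sqrt(2) band)", {
  spec <- fixture_spec()
  tm <- render_template(spec)
  p_et <- radius_profile(tm$mask)
  rms_at <- function(amp) {
    s <- subject_spec(if (amp > 0) "PG" else "CG", tremor_amplitude_px = amp,
                      seed = 7)
    p_ht <- radius_profile(render_trace(spec, s)$mask, center = p_et$center)
    baseline_features(p_ht, p_et)$rms
  }
  expect_gt(rms_at(6), 3)   # sine of amplitude 6 has RMS 6/sqrt(2) ~ 4.24
  expect_lt(rms_at(6), 6)
  # mean absolute deviation nondecreasing in amplitude
  rms <- sapply(c(0, 2, 4, 8), rms_at)
  expect_true(all(diff(rms) > 0))
})

test_that("generate_dataset writes a reproducible labeled manifest", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- generate_dataset(3, 5, "meander", master_seed = 9, out_dir = d1)
  expect_identical(nrow(man), 8L)
  expect_identical(sum(man$label == "CG"), 3L)
  expect_identical(names(man), c("file", "label", "format", "seed"))
  expect_true(all(file.exists(file.path(d1, man$file))))
  expect_true(all(file.exists(file.path(d1, sub("[.]png$", "_template.png",
                                                man$file)))))
  man2 <- generate_dataset(3, 5, "meander", master_seed = 9, out_dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  # and the images themselves are byte-identical
  expect_identical(readBin(file.path(d1, man$file[1]), "raw", 1e6),
                   readBin(file.path(d2, man$file[1]), "raw", 1e6))
  # degenerate empty dataset
  man0 <- generate_dataset(0, 0, "spiral", master_seed = 1,
                           out_dir = withr::local_tempdir())
  expect_identical(nrow(man0), 0L)
})

test_that("ground-truth masks align with the composed exam", {
  ex <- fixture_exam()
  expect_identical(dim(ex$exam)[1:2], dim(ex$template_mask))
  expect_identical(dim(ex$trace_mask), dim(ex$template_mask))
  gray <- to_grayscale(ex$exam)
  # template pixels are printed black even where the pen crosses them
  expect_true(all(gray[ex$template_mask] == 0))
  # pen-only pixels carry the pen luminance, clearly separated from print
  pen_only <- ex$trace_mask & !ex$template_mask
  expect_true(all(gray[pen_only] > 40))
  expect_true(all(gray[pen_only] < 200))
})
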