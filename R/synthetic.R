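#' Specify a handwriting-exam template
#'
#' An exam template is an Archimedean spiral \eqn{r = a\theta} (pixels), or a
#' meander: the same spiral carrier with a square-wave radial modulation that
#' emulates the angular excursions of printed meander forms. The growth rate
#' \code{a} (pixels/radian) defaults to the largest value for which the
#' requested number of revolutions fits inside the image with a small margin.
#'
#' @param format \code{"spiral"} or \code{"meander"}.
#' @param image_size side of the square raster in pixels (\eqn{\ge 128}).
#' @param turns number of spiral revolutions (\eqn{\ge 1}).
#' @param stroke_width_px stroke thickness in pixels (\eqn{\ge 1}).
#' @param growth_px_per_rad Archimedean growth rate \code{a}; \code{NULL} fits
#'   the spiral to the image automatically.
#' @param meander_depth_px radial depth of the meander modulation (pixels).
#' @param meander_cycles_per_rev square-wave cycles per revolution.
#' @return an object of class \code{"template_spec"}.
#' @export
template_spec <- function(format = c("spiral", "meander"),
                          image_size = 256L,
                          turns = 3L,
                          stroke_width_px = 5L,
                          growth_px_per_rad = NULL,
                          meander_depth_px = 8,
                          meander_cycles_per_rev = 8) {
  format <- match.arg(format)
  if (!is_count(image_size, 1L) || image_size < 128)
    stopf("image_size must be an integer >= 128", class = "scmhand_bad_param")
  if (!is_count(turns, 1L))
    stopf("turns must be an integer >= 1", class = "scmhand_bad_param")
  if (!is_count(stroke_width_px, 1L))
    stopf("stroke_width_px must be an integer >= 1", class = "scmhand_bad_param")
  # the curve winds from theta0 = 2*pi, leaving the central opening printed
  # exam spirals have and keeping the innermost winding resolvable
  theta_max <- 2 * pi * (turns + 1)
  margin <- stroke_width_px + meander_depth_px * (format == "meander") + 4
  r_max <- image_size / 2 - margin
  if (is.null(growth_px_per_rad)) growth_px_per_rad <- r_max / theta_max
  if (growth_px_per_rad * theta_max > r_max + 1e-9)
    stopf("image of size %d cannot contain %d turns at growth rate %.2f px/rad",
          image_size, turns, growth_px_per_rad, class = "scmhand_bad_param")
  if (growth_px_per_rad <= 0)
    stopf("growth rate must be positive", class = "scmhand_bad_param")
  structure(list(format = format, image_size = as.integer(image_size),
                 turns = as.integer(turns),
                 stroke_width_px = as.integer(stroke_width_px),
                 growth_px_per_rad = growth_px_per_rad,
                 meander_depth_px = meander_depth_px,
                 meander_cycles_per_rev = meander_cycles_per_rev),
            class = "template_spec")
}

#' Specify a synthetic subject
#'
#' The tremor model perturbs the traced radius by a sinusoid of amplitude
#' \code{tremor_amplitude_px} with \code{tremor_freq_per_rev} cycles per
#' revolution, plus white Gaussian hand jitter of sd \code{jitter_sd_px}.
#' Control-group (CG) subjects default to zero tremor amplitude; patient-group
#' (PG) subjects must have a positive amplitude.
#'
#' @param label \code{"CG"} or \code{"PG"}.
#' @param tremor_amplitude_px sinusoidal tremor amplitude in pixels
#'   (\eqn{\ge 0}); defaults to 0 for CG and 6 for PG.
#' @param tremor_freq_per_rev tremor cycles per template revolution.
#' @param jitter_sd_px sd of the Gaussian radial jitter in pixels.
#' @param seed integer RNG seed making the subject's trace reproducible.
#' @return an object of class \code{"subject_spec"}.
#' @export
subject_spec <- function(label = c("CG", "PG"),
                         tremor_amplitude_px = NULL,
                         tremor_freq_per_rev = 6,
                         jitter_sd_px = 0.5,
                         seed = 1L) {
  label <- match.arg(label)
  if (is.null(tremor_amplitude_px))
    tremor_amplitude_px <- if (label == "CG") 0 else 6
  if (!is.numeric(tremor_amplitude_px) || tremor_amplitude_px < 0)
    stopf("tremor_amplitude_px must be >= 0", class = "scmhand_bad_param")
  if (label == "PG" && tremor_amplitude_px <= 0)
    stopf("PG subjects must have positive tremor amplitude",
          class = "scmhand_bad_param")
  if (jitter_sd_px < 0)
    stopf("jitter_sd_px must be >= 0", class = "scmhand_bad_param")
  structure(list(label = label, tremor_amplitude_px = tremor_amplitude_px,
                 tremor_freq_per_rev = tremor_freq_per_rev,
                 jitter_sd_px = jitter_sd_px, seed = as.integer(seed)),
            class = "subject_spec")
}

# Template polar radius at unwrapped angle theta.
template_radius <- function(spec, theta) {
  r <- spec$growth_px_per_rad * theta
  if (spec$format == "meander") {
    # near-square wave: a steep clipped sinusoid keeps the curve connected
    w <- pmin(1, pmax(-1, 10 * sin(spec$meander_cycles_per_rev * theta)))
    r <- r + spec$meander_depth_px * w
  }
  r
}

# Dense unwrapped-angle sampling: consecutive curve points < ~0.4 px apart.
template_thetas <- function(spec) {
  theta_max <- 2 * pi * (spec$turns + 1)
  r_max <- spec$growth_px_per_rad * theta_max + 1
  seq(2 * pi, theta_max, by = 0.3 / r_max)
}

# Rasterize polar samples (r, theta) as a stroked curve; returns logical mask.
rasterize_curve <- function(r, theta, image_size, stroke_width_px) {
  ctr <- (image_size + 1) / 2
  x <- ctr + r * cos(theta)
  y <- ctr + r * sin(theta)
  half <- stroke_width_px / 2
  off <- expand.grid(dr = -ceiling(half):ceiling(half),
                     dc = -ceiling(half):ceiling(half))
  off <- off[off$dr^2 + off$dc^2 <= half^2 + 1e-9, , drop = FALSE]
  rows <- rep(round(y), each = nrow(off)) + off$dr
  cols <- rep(round(x), each = nrow(off)) + off$dc
  keep <- rows >= 1 & rows <= image_size & cols >= 1 & cols <= image_size
  mask <- matrix(FALSE, image_size, image_size)
  mask[cbind(rows[keep], cols[keep])] <- TRUE
  mask
}

#' Render a template or a subject's trace
#'
#' \code{render_template()} rasterizes the template curve; the mask marks
#' exactly the drawn pixels. \code{render_trace()} follows the same polar
#' curve with the subject's tremor perturbation applied to the radius; given
#' the same seed it is fully deterministic.
#'
#' @param spec a \code{\link{template_spec}}.
#' @return a list with \code{mask} (logical matrix of drawn pixels) and
#'   \code{raster} (grayscale matrix: curve 0 on white 255).
#' @export
render_template <- function(spec) {
  stopifnot(inherits(spec, "template_spec"))
  th <- template_thetas(spec)
  mask <- rasterize_curve(template_radius(spec, th), th,
                          spec$image_size, spec$stroke_width_px)
  raster <- matrix(255, spec$image_size, spec$image_size)
  raster[mask] <- 0
  list(mask = mask, raster = raster)
}

#' @rdname render_template
#' @param subject a \code{\link{subject_spec}}.
#' @export
render_trace <- function(spec, subject) {
  stopifnot(inherits(spec, "template_spec"), inherits(subject, "subject_spec"))
  th <- template_thetas(spec)
  r <- template_radius(spec, th) +
    subject$tremor_amplitude_px * sin(subject$tremor_freq_per_rev * th)
  if (subject$jitter_sd_px > 0)
    r <- r + with_seed(subject$seed,
                       stats::rnorm(length(th), sd = subject$jitter_sd_px))
  r <- pmax(r, 0)
  mask <- rasterize_curve(r, th, spec$image_size, spec$stroke_width_px)
  raster <- matrix(255, spec$image_size, spec$image_size)
  raster[mask] <- 0
  list(mask = mask, raster = raster)
}

#' Compose a full synthetic exam
#'
#' Draws the template in printed black and the trace in ballpoint blue on the
#' page; where ink crosses print the darker value wins per channel
#' (ink-over-print). Scanned paper exams never come out identical, so the
#' acquisition nuisances can be emulated too: ink darkness
#' (\code{pen_brightness} scales the pen color), paper tone
#' (\code{paper_value}) and sparse impulse speckle
#' (\code{speckle_frac} of pixels replaced by random intensities, seeded by
#' \code{noise_seed}). Ground-truth masks for both layers are returned.
#'
#' @inheritParams render_trace
#' @param pen_rgb length-3 pen color (0-255). The default mid-dark blue has
#'   BT.601 luminance ~69, separating it from printed black by intensity as on
#'   real scans.
#' @param pen_brightness multiplicative factor on \code{pen_rgb} (clamped to
#'   0-255).
#' @param paper_value background intensity of the page.
#' @param speckle_frac fraction of pixels hit by impulse noise.
#' @param noise_seed seed for the speckle draw.
#' @return an object of class \code{"synthetic_exam"}: list with
#'   \code{exam} (h x w x 3 RGB array), \code{template_mask},
#'   \code{trace_mask} (logical), \code{label}, \code{format}.
#' @export
synthesize_exam <- function(spec, subject, pen_rgb = c(50, 50, 220),
                            pen_brightness = 1, paper_value = 255,
                            speckle_frac = 0, noise_seed = subject$seed) {
  tmpl <- render_template(spec)
  trc <- render_trace(spec, subject)
  n <- spec$image_size
  pen <- pmin(pmax(pen_rgb * pen_brightness, 0), 255)
  exam <- array(paper_value, dim = c(n, n, 3))
  for (ch in 1:3) {
    plane <- exam[, , ch]
    plane[trc$mask] <- pen[ch]
    plane[tmpl$mask] <- pmin(plane[tmpl$mask], 0) # print is black; darker wins
    exam[, , ch] <- plane
  }
  if (speckle_frac > 0) {
    exam <- with_seed(mix_seed(noise_seed, 7919L), {
      hit <- sample(n * n, size = round(speckle_frac * n * n))
      val <- stats::runif(length(hit), 0, 255)
      for (ch in 1:3) {
        plane <- exam[, , ch]
        plane[hit] <- val
        exam[, , ch] <- plane
      }
      exam
    })
  }
  structure(list(exam = round(exam), template_mask = tmpl$mask,
                 trace_mask = trc$mask, label = subject$label,
                 format = spec$format),
            class = "synthetic_exam")
}

#' Generate a labeled synthetic exam dataset on disk
#'
#' Writes \code{n_cg + n_pg} exam PNGs with ground-truth masks and a manifest
#' CSV (\code{file,label,format,seed}). Per-sample seeds are derived
#' deterministically from \code{master_seed}, so two runs with the same seed
#' produce byte-identical manifests. The default class sizes mirror the
#' per-format composition of paper-and-pen Parkinson screening collections,
#' where patients far outnumber controls (72 controls vs 296 patients per
#' format).
#'
#' @param n_cg,n_pg number of control / patient exams.
#' @param format \code{"spiral"} or \code{"meander"}.
#' @param master_seed integer seed for the whole dataset.
#' @param out_dir output directory (created if missing).
#' @param template a \code{\link{template_spec}}; default matches \code{format}.
#' @param cg_args,pg_args extra arguments passed to \code{\link{subject_spec}}
#'   for each group (e.g. tremor amplitude).
#' @param scan_variation emulate scan-to-scan acquisition nuisances: per-exam
#'   ink darkness (pen brightness uniform on 0.8-1.6), paper tone (uniform on
#'   235-255) and 0.3\% impulse speckle. These vary with the sample seed and
#'   affect no ground-truth mask.
#' @param write_masks also write \code{*_template.png} / \code{*_trace.png}
#'   ground-truth masks.
#' @return the manifest as a data.frame (invisibly also written to
#'   \code{out_dir/manifest.csv}).
#' @export
generate_dataset <- function(n_cg = 72L, n_pg = 296L,
                             format = c("spiral", "meander"),
                             master_seed = 1L, out_dir,
                             template = NULL,
                             cg_args = list(), pg_args = list(),
                             scan_variation = TRUE,
                             write_masks = TRUE) {
  format <- match.arg(format)
  if (!is_count(n_cg) || !is_count(n_pg))
    stopf("n_cg and n_pg must be nonnegative integers",
          class = "scmhand_bad_param")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir,
          class = "scmhand_io_error")
  if (is.null(template)) template <- template_spec(format)
  labels <- c(rep("CG", n_cg), rep("PG", n_pg))
  n <- length(labels)
  manifest <- data.frame(file = character(n), label = labels,
                         format = rep(format, n), seed = integer(n),
                         stringsAsFactors = FALSE)
  for (i in seq_len(max(n, 0L))) {
    seed_i <- mix_seed(master_seed, i)
    args <- c(list(label = labels[i], seed = seed_i),
              if (labels[i] == "CG") cg_args else pg_args)
    scan <- if (scan_variation) {
      with_seed(mix_seed(seed_i, 104729L),
                list(pen_brightness = stats::runif(1, 0.8, 1.6),
                     paper_value = stats::runif(1, 235, 255),
                     speckle_frac = 0.003))
    } else list()
    ex <- do.call(synthesize_exam,
                  c(list(template, do.call(subject_spec, args)), scan))
    stem <- sprintf("%s_%s_%04d", format, tolower(labels[i]), i)
    write_image(ex$exam, file.path(out_dir, paste0(stem, ".png")))
    if (write_masks) {
      write_image(ex$template_mask * 255,
                  file.path(out_dir, paste0(stem, "_template.png")))
      write_image(ex$trace_mask * 255,
                  file.path(out_dir, paste0(stem, "_trace.png")))
    }
    manifest$file[i] <- paste0(stem, ".png")
    manifest$seed[i] <- seed_i
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest
}
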