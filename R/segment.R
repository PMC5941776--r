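#' Segment a handwriting exam into template and trace layers
#'
#' The exam template (ET) is recovered by smoothing with a 5x5 median filter,
#' a grayscale erosion with a 9x9 elliptical structuring element (closing any
#' discontinuity in the printed curve), an intensity threshold selecting the
#' darkest (printed) pixels, and a second erosion with the same element that
#' restores the stroke to its real size. The handwritten trace (HT) is the
#' Otsu foreground of the median-smoothed grayscale exam minus the ET
#' foreground. Both outputs are binary grayscale images (foreground 255,
#' background 0) with the same dimensions as the input, ready for
#' co-occurrence analysis.
#'
#' @param exam RGB array or grayscale matrix of the exam, intensities 0-255.
#' @param threshold intensity cut for the printed template: pixels strictly
#'   darker than this (after smoothing and erosion) are template foreground.
#'   The default 40 separates printed black (~0) from blue ink (BT.601
#'   luminance ~69) on the bundled synthetic exams; scanned collections
#'   need their own empirical value.
#' @return a binary grayscale matrix (0/255).
#' @seealso [segment_exam()] for the full exam/ET/HT triple.
#' @export
segment_template <- function(exam, threshold = 40) {
  gray <- to_grayscale(exam)
  sm <- from_eb(EBImage::medianFilter(as_eb(gray), 2)) # 5x5 window
  brush <- EBImage::makeBrush(9, shape = "disc")
  eroded <- from_eb(EBImage::erode(as_eb(sm), brush)) # grayscale: min filter
  fg <- eroded < threshold
  if (!any(fg))
    stopf("no template foreground below threshold %s", format(threshold),
          class = "scmhand_empty_segmentation")
  et <- from_eb(EBImage::erode(as_eb(fg * 255), brush))
  et <- (et > 127) * 255
  if (!any(et > 0))
    stopf("template foreground vanished after erosion",
          class = "scmhand_empty_segmentation")
  et
}

#' @rdname segment_template
#' @param et the template layer returned by \code{segment_template()} for the
#'   same exam.
#' @export
segment_trace <- function(exam, et) {
  gray <- to_grayscale(exam)
  if (!identical(dim(gray), dim(et)))
    stopf("exam and template dimensions differ", class = "scmhand_dim_mismatch")
  sm <- from_eb(EBImage::medianFilter(as_eb(gray), 2))
  t_otsu <- EBImage::otsu(as_eb(sm)) * 255
  fg <- sm < t_otsu               # dark ink/print on light page
  ht <- (fg & !(et > 0)) * 255    # set-difference with the template layer
  ht
}

#' @rdname segment_template
#' @return \code{segment_exam()} returns a list of three pixel-aligned
#'   grayscale images: \code{a} (full exam, grayscale), \code{b} (ET),
#'   \code{c} (HT).
#' @export
segment_exam <- function(exam, threshold = 40) {
  et <- segment_template(exam, threshold = threshold)
  ht <- segment_trace(exam, et)
  list(a = to_grayscale(exam), b = et, c = ht)
}
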