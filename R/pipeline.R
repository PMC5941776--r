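#' Extract feature tables from an exam manifest
#'
#' Runs the full front end for every exam listed in a manifest: segmentation
#' into template (b) and trace (c) layers, grayscale conversion, then the
#' structural co-occurrence matrix for the requested image-pair combination
#' and/or the radius-profile baseline attributes. Combinations follow the
#' exam/template/trace naming: \code{"a_c"} pairs the full exam with the
#' trace, \code{"a_b"} the exam with the template, and \code{"c_b"} the trace
#' with the template. Exams whose segmentation comes back empty are flagged,
#' skipped and reported via a warning.
#'
#' @param manifest data.frame with columns \code{file,label,format} (as
#'   written by [generate_dataset()]) or the path of such a CSV.
#' @param image_dir directory the \code{file} column is relative to; defaults
#'   to the manifest's directory when \code{manifest} is a path.
#' @param combination one of \code{"a_c"}, \code{"a_b"}, \code{"c_b"}.
#' @param features \code{"scm"}, \code{"baseline"} or \code{"both"}.
#' @param n_levels SCM quantization levels.
#' @param threshold template segmentation threshold (see
#'   [segment_template()]).
#' @param n_bins,d angular bins and MRT displacement for the baseline
#'   attributes.
#' @return data.frame with columns \code{id,label,format} followed by the
#'   feature columns (8 SCM and/or 9 baseline values per exam).
#' @export
extract_features <- function(manifest, image_dir = NULL,
                             combination = c("c_b", "a_c", "a_b"),
                             features = c("scm", "baseline", "both"),
                             n_levels = 8L, threshold = 40,
                             n_bins = 360L, d = 10L) {
  combination <- match.arg(combination)
  features <- match.arg(features)
  if (is.character(manifest) && length(manifest) == 1L) {
    if (is.null(image_dir)) image_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(image_dir)) image_dir <- "."
  rows <- vector("list", nrow(manifest))
  skipped <- character(0)
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(image_dir, manifest$file[i])
    rec <- tryCatch(
      exam_features(read_image(path), combination, features,
                    n_levels, threshold, n_bins, d),
      scmhand_error = function(e) e, error = function(e) e)
    if (inherits(rec, "condition")) {
      skipped <- c(skipped, sprintf("%s (%s)", manifest$file[i],
                                    conditionMessage(rec)))
      next
    }
    rows[[i]] <- data.frame(id = manifest$file[i], label = manifest$label[i],
                            format = manifest$format[i], t(rec),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(sprintf("skipped %d exam(s): %s", length(skipped),
                    paste(skipped, collapse = "; ")))
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' @rdname extract_features
#' @param combinations combinations to extract in one pass (each exam is
#'   segmented once and all requested SCMs are built from it).
#' @return \code{extract_feature_tables()} returns a named list of feature
#'   tables, one per combination.
#' @export
extract_feature_tables <- function(manifest, image_dir = NULL,
                                   combinations = c("a_c", "a_b", "c_b"),
                                   n_levels = 8L, threshold = 40) {
  combinations <- match.arg(combinations, several.ok = TRUE)
  if (is.character(manifest) && length(manifest) == 1L) {
    if (is.null(image_dir)) image_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(image_dir)) image_dir <- "."
  tabs <- stats::setNames(vector("list", length(combinations)), combinations)
  for (i in seq_len(nrow(manifest))) {
    seg <- segment_exam(read_image(file.path(image_dir, manifest$file[i])),
                        threshold = threshold)
    for (cb in combinations) {
      pair <- switch(cb, a_c = list(seg$a, seg$c), a_b = list(seg$a, seg$b),
                     c_b = list(seg$c, seg$b))
      fv <- scm_features(scm(pair[[1]], pair[[2]], n_levels))
      tabs[[cb]][[i]] <- data.frame(id = manifest$file[i],
                                    label = manifest$label[i],
                                    format = manifest$format[i], t(fv),
                                    stringsAsFactors = FALSE)
    }
  }
  lapply(tabs, function(x) do.call(rbind, x))
}

# features of one exam image: named numeric vector
exam_features <- function(exam, combination, features,
                          n_levels, threshold, n_bins, d) {
  seg <- segment_exam(exam, threshold = threshold)
  out <- numeric(0)
  if (features %in% c("scm", "both")) {
    pair <- switch(combination,
                   a_c = list(seg$a, seg$c),
                   a_b = list(seg$a, seg$b),
                   c_b = list(seg$c, seg$b))
    out <- c(out, scm_features(scm(pair[[1]], pair[[2]], n_levels)))
  }
  if (features %in% c("baseline", "both")) {
    p_et <- radius_profile(seg$b, n = n_bins)
    p_ht <- radius_profile(seg$c, n = n_bins, center = p_et$center)
    bl <- unlist(baseline_features(p_ht, p_et, d = d))
    names(bl) <- paste0("bl_", names(bl))
    out <- c(out, bl)
  }
  out
}

#' Evaluate classifiers with repeated stratified splits
#'
#' Monte-Carlo cross-validation: each run draws a stratified random
#' train/validation/test split (default 50/25/25), z-scores the features with
#' training-split statistics, fits each requested classifier on the training
#' split (the SVM picking its RBF hyperparameters by minimal validation
#' error), and measures plain accuracy on the test split. Results aggregate
#' as mean and sd over runs with the per-run confusion matrices retained.
#' Missing feature values (e.g. an undefined SCM correlation on a constant
#' pair) are imputed to 0 before classification.
#'
#' @param feature_table data.frame from [extract_features()].
#' @param classifiers subset of \code{c("nb", "svm", "opf")}.
#' @param n_runs number of repeated splits.
#' @param fractions train/validation/test fractions, summing to 1.
#' @param seed master seed; per-run seeds are derived from it.
#' @return an object of class \code{"scm_experiment"}: per-classifier
#'   accuracy vectors, means, sds, confusion matrices, and the configuration.
#' @export
run_experiment <- function(feature_table,
                           classifiers = c("nb", "svm", "opf"),
                           n_runs = 20L,
                           fractions = c(train = 0.5, val = 0.25, test = 0.25),
                           seed = 1L) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (abs(sum(fractions) - 1) > 1e-8)
    stopf("split fractions must sum to 1", class = "scmhand_bad_param")
  if (!is_count(n_runs, 1L))
    stopf("n_runs must be >= 1", class = "scmhand_bad_param")
  feat_cols <- setdiff(names(feature_table), c("id", "label", "format"))
  x <- as.matrix(feature_table[, feat_cols, drop = FALSE])
  x[!is.finite(x)] <- 0
  y <- as.character(feature_table$label)
  if (length(unique(y)) < 2L)
    stopf("need at least two classes", class = "scmhand_bad_param")
  acc <- matrix(NA_real_, n_runs, length(classifiers),
                dimnames = list(NULL, classifiers))
  confusions <- stats::setNames(
    rep(list(vector("list", n_runs)), length(classifiers)), classifiers)
  for (run in seq_len(n_runs)) {
    sp <- stratified_split(y, fractions, mix_seed(seed, run))
    mu <- colMeans(x[sp$train, , drop = FALSE])
    sdv <- apply(x[sp$train, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    xtr <- z[sp$train, , drop = FALSE]; ytr <- y[sp$train]
    xva <- z[sp$val, , drop = FALSE];   yva <- y[sp$val]
    xte <- z[sp$test, , drop = FALSE];  yte <- y[sp$test]
    for (cl in classifiers) {
      pred <- switch(cl,
        nb = as.character(predict(nb_fit(xtr, ytr), as.data.frame(xte))),
        svm = {
          par <- svm_select(xtr, ytr, xva, yva)
          as.character(predict(svm_fit(xtr, ytr, par$cost, par$gamma), xte))
        },
        opf = predict(opf(xtr, ytr), xte))
      acc[run, cl] <- mean(pred == yte)
      confusions[[cl]][[run]] <- table(truth = factor(yte, unique(y)),
                                       predicted = factor(pred, unique(y)))
    }
  }
  structure(list(accuracy = acc,
                 mean = colMeans(acc), sd = apply(acc, 2, stats::sd),
                 confusions = confusions,
                 config = list(classifiers = classifiers, n_runs = n_runs,
                               fractions = fractions, seed = seed,
                               n_samples = nrow(x),
                               features = feat_cols)),
            class = "scm_experiment")
}

# stratified random split; retries with derived seeds (cap 10) if any split
# portion loses a class entirely
stratified_split <- function(y, fractions, seed, retry = 0L) {
  idx <- with_seed(seed, {
    parts <- list(train = integer(0), val = integer(0), test = integer(0))
    for (cls in unique(y)) {
      ci <- sample(which(y == cls))
      nc <- length(ci)
      n_tr <- floor(fractions[[1]] * nc)
      n_va <- floor(fractions[[2]] * nc)
      parts$train <- c(parts$train, ci[seq_len(n_tr)])
      parts$val <- c(parts$val, ci[n_tr + seq_len(n_va)])
      parts$test <- c(parts$test, ci[-seq_len(n_tr + n_va)])
    }
    parts
  })
  ok <- all(vapply(idx, function(p) length(unique(y[p])) == length(unique(y)),
                   logical(1)))
  if (!ok) {
    if (retry >= 10L)
      stopf("could not stratify split after 10 retries",
            class = "scmhand_bad_param")
    return(stratified_split(y, fractions, mix_seed(seed, retry + 1L),
                            retry + 1L))
  }
  idx
}

#' @export
print.scm_experiment <- function(x, ...) {
  cat(sprintf("Repeated stratified-split evaluation (%d runs, %d samples)\n",
              x$config$n_runs, x$config$n_samples))
  for (cl in names(x$mean))
    cat(sprintf("  %-4s accuracy %.2f%% +/- %.2f%%\n",
                cl, 100 * x$mean[cl], 100 * x$sd[cl]))
  invisible(x)
}

#' Compare the three image-pair combinations
#'
#' Runs [run_experiment()] on a feature table per combination and ranks the
#' combinations by mean accuracy (ties keep the input order).
#'
#' @param tables named list of feature tables, names among
#'   \code{c("a_c", "a_b", "c_b")}, all extracted from the same manifest.
#' @param ... passed on to [run_experiment()].
#' @return data.frame ranked by decreasing mean accuracy with columns
#'   \code{combination, classifier, mean_accuracy, sd_accuracy, rank}; the
#'   full reports are attached as attribute \code{"reports"}.
#' @export
compare_combinations <- function(tables, ...) {
  stopifnot(is.list(tables), length(tables) >= 2L, !is.null(names(tables)))
  n_ids <- unique(vapply(tables, nrow, integer(1)))
  if (length(n_ids) != 1L)
    stopf("combination tables come from different manifests",
          class = "scmhand_dim_mismatch")
  reports <- lapply(tables, run_experiment, ...)
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(combination = nm, classifier = names(r$mean),
               mean_accuracy = unname(r$mean), sd_accuracy = unname(r$sd),
               stringsAsFactors = FALSE)
  }))
  best <- vapply(split(rows$mean_accuracy, rows$combination), max, numeric(1))
  rk <- rank(-best, ties.method = "min") # equal means share the better rank
  rows$rank <- unname(rk[rows$combination])
  rows <- rows[order(rows$rank, -rows$mean_accuracy), ]
  attr(rows, "reports") <- reports
  rows
}

#' Write an experiment report as JSON
#'
#' Serializes the configuration, per-run accuracies and confusion matrices.
#'
#' @param report an \code{"scm_experiment"} object.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  out <- list(config = report$config,
              accuracy = as.data.frame(report$accuracy),
              mean = as.list(report$mean), sd = as.list(report$sd),
              confusions = lapply(report$confusions, function(cl)
                lapply(cl, function(tb) as.data.frame.matrix(tb))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
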