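#' Supervised Optimum-Path Forest classifier
#'
#' Training builds the complete graph on the training samples with Euclidean
#' arc weights, computes its minimum spanning tree (Prim, ties broken by
#' lower sample index), and marks as prototypes both endpoints of every MST
#' edge joining different classes. A path-max competition (image foresting
#' transform with \eqn{f_{max}}) then assigns every sample the cost
#' \eqn{C(t) = \min_{paths} \max} arc weight from any prototype, carrying the
#' conquering prototype's label. If the training set holds a single class the
#' minimum-index sample is the lone prototype.
#'
#' @param x numeric matrix of training features (rows = samples).
#' @param y factor or character vector of class labels.
#' @return an object of class \code{"opf"}: training samples, per-sample path
#'   costs \code{cost}, assigned labels, prototype flags, and the
#'   cost-nondecreasing scan order used for early-stopping prediction.
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 5), 10))
#' y <- rep(c("A", "B"), each = 10)
#' fit <- opf(x, y)
#' predict(fit, x[1:3, , drop = FALSE])
#' @export
opf <- function(x, y) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  if (n == 0L) stopf("empty training set", class = "scmhand_bad_param")
  if (length(y) != n)
    stopf("length(y) must match nrow(x)", class = "scmhand_dim_mismatch")
  d <- as.matrix(stats::dist(x))
  proto <- opf_prototypes(d, y)
  cost <- rep(Inf, n)
  lab <- y
  cost[proto] <- 0
  done <- rep(FALSE, n)
  # IFT with f_max: O(n^2) Dijkstra-like sweep; which.min takes the lowest
  # index on ties, making conquest order deterministic
  for (k in seq_len(n)) {
    u <- which.min(replace(cost, done, Inf))
    done[u] <- TRUE
    relax <- !done & pmax(cost[u], d[u, ]) < cost
    cost[relax] <- pmax(cost[u], d[u, relax])
    lab[relax] <- lab[u]
  }
  ord <- order(cost)
  structure(list(x = x, cost = cost, labels = lab, prototypes = proto,
                 order = ord, classes = sort(unique(y))),
            class = "opf")
}

# prototypes: endpoints of inter-class MST edges; Prim with lowest-index
# tie-breaks. Single class: minimum-index sample.
opf_prototypes <- function(d, y) {
  n <- nrow(d)
  if (length(unique(y)) < 2L || n == 1L) return(1L)
  intree <- rep(FALSE, n)
  key <- rep(Inf, n); parent <- rep(NA_integer_, n)
  key[1L] <- 0
  proto <- logical(n)
  for (k in seq_len(n)) {
    u <- which.min(replace(key, intree, Inf))
    intree[u] <- TRUE
    if (!is.na(parent[u]) && y[u] != y[parent[u]]) {
      proto[u] <- TRUE
      proto[parent[u]] <- TRUE
    }
    upd <- !intree & d[u, ] < key
    key[upd] <- d[u, upd]
    parent[upd] <- u
  }
  which(proto)
}

#' @rdname opf
#' @param object a fitted \code{"opf"} model.
#' @param newdata numeric matrix (or vector for a single sample) of query
#'   features.
#' @param ... unused.
#' @return \code{predict.opf()} returns a character vector of labels: each
#'   query gets the label of the training sample minimizing
#'   \eqn{\max(C(t), d(q, t))}. Samples are scanned in nondecreasing stored
#'   cost; the scan stops once the running minimum cannot be beaten, ties
#'   resolving to the earlier sample in that order.
#' @export
predict.opf <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stopf("feature dimensionality mismatch", class = "scmhand_dim_mismatch")
  ord <- object$order
  xo <- object$x[ord, , drop = FALSE]
  co <- object$cost[ord]
  lo <- object$labels[ord]
  out <- character(nrow(newdata))
  for (q in seq_len(nrow(newdata))) {
    best <- Inf
    lab <- lo[1L]
    for (k in seq_along(co)) {
      if (co[k] >= best) break # no later sample can improve a max(C, d)
      val <- max(co[k], sqrt(sum((newdata[q, ] - xo[k, ])^2)))
      if (val < best) {
        best <- val
        lab <- lo[k]
      }
    }
    out[q] <- lab
  }
  out
}

#' @export
print.opf <- function(x, ...) {
  cat(sprintf("Optimum-path forest: %d samples, %d prototypes, classes: %s\n",
              nrow(x$x), length(x$prototypes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Gaussian Naive Bayes and RBF-SVM wrappers
#'
#' Thin wrappers around \pkg{e1071} presenting the same fit/predict contract
#' as [opf()]. The Naive Bayes fit floors every per-class feature variance at
#' \code{1e-9} so constant features cannot produce degenerate densities. The
#' SVM uses a radial-basis kernel; [svm_select()] picks \code{(cost, gamma)}
#' from a log-spaced grid by minimal error on a held-out validation split
#' (ties resolve to the first grid point).
#'
#' @param x,y training features and labels as in [opf()].
#' @return a fitted model; use \code{predict(model, newdata)}.
#' @export
nb_fit <- function(x, y) {
  fit <- e1071::naiveBayes(as.data.frame(x), factor(y))
  fit$tables <- lapply(fit$tables, function(tb) {
    tb[, 2] <- pmax(tb[, 2], sqrt(1e-9))
    tb
  })
  fit
}

#' @rdname nb_fit
#' @param cost,gamma RBF-SVM hyperparameters.
#' @export
svm_fit <- function(x, y, cost = 1, gamma = 1 / ncol(x)) {
  e1071::svm(as.matrix(x), factor(y), kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

#' @rdname nb_fit
#' @param xv,yv validation features and labels scoring each grid point.
#' @param cost_grid,gamma_grid candidate hyperparameter values.
#' @return \code{svm_select()} returns \code{list(cost, gamma, val_error)}.
#' @export
svm_select <- function(x, y, xv, yv,
                       cost_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2)) {
  best <- list(cost = cost_grid[1L], gamma = gamma_grid[1L], val_error = Inf)
  for (g in gamma_grid) for (cc in cost_grid) {
    fit <- svm_fit(x, y, cost = cc, gamma = g)
    err <- mean(as.character(predict(fit, as.matrix(xv))) != as.character(yv))
    if (err < best$val_error) best <- list(cost = cc, gamma = g, val_error = err)
  }
  best
}
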