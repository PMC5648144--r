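#' Confusion-matrix accuracy metrics
#'
#' True positive rate (sensitivity), true negative rate (specificity), and
#' the true skill statistic `TSS = TPR + TNR - 1`.
#'
#' @param obs 0/1 observed labels (both classes required).
#' @param pred_binary 0/1 (or logical) predicted labels.
#' @return list with `TPR`, `TNR`, `TSS`.
#' @export
confusion_metrics <- function(obs, pred_binary) {
  if (length(unique(obs)) < 2L) stop("both classes required in obs")
  pred_binary <- as.integer(as.logical(pred_binary))
  tpr <- sum(pred_binary == 1 & obs == 1) / sum(obs == 1)
  tnr <- sum(pred_binary == 0 & obs == 0) / sum(obs == 0)
  list(TPR = tpr, TNR = tnr, TSS = tpr + tnr - 1)
}

#' Rank-based AUC (Mann-Whitney estimator)
#'
#' Probability that a random presence outscores a random absence; ties
#' contribute one half (midranks).
#'
#' @param obs 0/1 labels.
#' @param scores predicted suitabilities.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(obs, scores) {
  if (length(unique(obs)) < 2L) stop("both classes required in obs")
  r <- rank(scores)
  np <- sum(obs == 1); nn <- sum(obs == 0)
  (sum(r[obs == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Label patches of suitable cells
#'
#' Connected components of `TRUE` cells (rook/4-neighbour adjacency by
#' default, queen/8 optionally; invalid cells count as non-suitable).
#' Each patch reports its area (cell count) and its perimeter: the number
#' of cell edges facing a non-suitable, invalid or off-map cell. The
#' perimeter is always even and at least 4.
#'
#' @param binary a `grid_layer` whose valid cells are 0/1, or a logical
#'   matrix.
#' @param connectivity 4 (default) or 8.
#' @return data.frame with one row per patch: `area`, `perimeter`.
#' @export
label_patches <- function(binary, connectivity = 4) {
  if (inherits(binary, "grid_layer")) {
    b <- binary$values == 1 & binary$valid
  } else b <- binary
  b[is.na(b)] <- FALSE
  if (!any(b)) return(data.frame(area = integer(0), perimeter = integer(0)))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(b); nc <- ncol(b)
  lab <- EBImage::bwlabel(b * 1)               # rook-adjacency components
  lab <- matrix(as.integer(round(lab)), nr, nc)
  if (connectivity == 8) {
    # merge rook components that touch diagonally (union-find on label ids)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),     # SE
      cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))     # NE
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(max(lab))
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); d <- find(pairs[r, 2])
        if (a != d) parent[max(a, d)] <- min(a, d)
      }
      roots <- vapply(seq_along(parent), find, integer(1))
      lab[lab > 0L] <- match(roots, sort(unique(roots)))[lab[lab > 0L]]
    }
  }
  cells <- which(b)
  comp <- lab[cells]
  comp <- match(comp, sort(unique(comp)))      # densify label ids
  # perimeter: 4 minus the number of suitable rook neighbours, per cell
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- b
  nbr <- pad[1:nr, 2:(nc + 1)] + pad[3:(nr + 2), 2:(nc + 1)] +
         pad[2:(nr + 1), 1:nc] + pad[2:(nr + 1), 3:(nc + 2)]
  per_cell <- 4L - nbr[cells]
  data.frame(area = as.integer(tabulate(comp)),
             perimeter = as.integer(rowsum(per_cell, comp)))
}

#' Landscape shape index
#'
#' `SI = sum over patches of 0.25 * perimeter / sqrt(area)`. A square patch
#' contributes exactly 1; irregular or fragmented maps score higher; an
#' empty map scores 0.
#'
#' @param patches data.frame from [label_patches()], or a `grid_layer` /
#'   logical matrix (labelled on the fly with rook adjacency).
#' @param connectivity used when `patches` is a map.
#' @return SI, a non-negative number.
#' @export
shape_index <- function(patches, connectivity = 4) {
  if (!is.data.frame(patches)) patches <- label_patches(patches, connectivity)
  if (nrow(patches) == 0L) return(0)
  sum(0.25 * patches$perimeter / sqrt(patches$area))
}

#' Kendall tau-b between two co-registered maps
#'
#' Tie-corrected rank correlation over the jointly valid cells, computed
#' with an O(n log n) merge-sort algorithm so whole-study-area comparisons
#' stay cheap.
#'
#' @param a,b `grid_layer`s on the same geometry.
#' @return tau-b in `[-1, 1]`.
#' @export
kendall_map_tau <- function(a, b) {
  stopifnot(inherits(a, "grid_layer"), inherits(b, "grid_layer"))
  if (!identical(dim(a$values), dim(b$values)))
    stop("maps are not co-registered")
  jv <- a$valid & b$valid
  if (sum(jv) < 2L) stop("fewer than 2 jointly valid cells")
  x <- a$values[jv]; y <- b$values[jv]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("tau undefined: a map is constant over the joint cells")
  kendall_tau_b_cpp(x, y)
}

#' Two-fold spatial cross-validated evaluation of one treatment
#'
#' For each fold, fits the algorithm on one checkerboard bin, selects the
#' max(sensitivity + specificity) threshold on the training fold, and
#' scores the held-out fold: TPR and TSS at that threshold, rank AUC, plus
#' the shape index of the whole-study-area prediction binarized at the
#' training threshold. The returned record averages the two folds
#' (bin1->bin2 and bin2->bin1), so it is invariant to fold order; the
#' returned suitability map is the cell-wise mean of the two fold
#' predictions.
#'
#' The maximum-entropy algorithm is presence-background: it fits on the
#' training-fold presences against `background` and is thresholded on the
#' training presences plus training pseudo-absences, like the other
#' algorithms.
#'
#' @param ts a `training_set`.
#' @param algorithm `"GAM"`, `"MElq"`, `"RF"` or `"SVM"`.
#' @param scores `grid_stack` the training set was extracted from.
#' @param seed integer.
#' @param background optional list from [sample_background()] (required for
#'   `"MElq"`; sampled on the fly when omitted).
#' @param connectivity patch adjacency for the shape index.
#' @return list with `record` (one-row data.frame: TSS, TPR, AUC, SI,
#'   threshold, n_train, n_test, chosen_resolution) and `suitability`
#'   (a `grid_layer`).
#' @export
evaluate_treatment <- function(ts, algorithm, scores, seed,
                               background = NULL, connectivity = 4) {
  stopifnot(inherits(ts, "training_set"))
  pts <- ts$points
  if (algorithm == "MElq" && is.null(background))
    background <- sample_background(scores, seed)
  fold <- function(train_bin) {
    tr <- pts$bin == train_bin
    te <- !tr
    model <- switch(algorithm,
      GAM = fit_gam(ts$X[tr, , drop = FALSE], pts$label[tr]),
      RF = fit_rf(ts$X[tr, , drop = FALSE], pts$label[tr], seed = seed),
      SVM = fit_svm(ts$X[tr, , drop = FALSE], pts$label[tr], seed = seed),
      MElq = fit_maxent_lq(ts$X[tr & pts$label == 1L, , drop = FALSE],
                           background$X),
      stop("unknown algorithm: ", algorithm))
    thr <- select_threshold(pts$label[tr],
                            predict_points(model, ts$X[tr, , drop = FALSE]))
    pred_te <- predict_points(model, ts$X[te, , drop = FALSE])
    cm <- confusion_metrics(pts$label[te], pred_te >= thr)
    suit <- predict_raster(model, scores)
    bin_map <- suit
    bin_map$values <- ifelse(suit$valid, as.numeric(suit$values >= thr), NA)
    list(TSS = cm$TSS, TPR = cm$TPR,
         AUC = auc_rank(pts$label[te], pred_te),
         SI = shape_index(bin_map, connectivity),
         threshold = thr, n_train = sum(tr), n_test = sum(te),
         suit = suit)
  }
  f1 <- fold(1L); f2 <- fold(2L)
  mean_suit <- f1$suit
  mean_suit$values <- (f1$suit$values + f2$suit$values) / 2
  rec <- data.frame(
    species = ts$species_id, algorithm = algorithm,
    TSS = (f1$TSS + f2$TSS) / 2, TPR = (f1$TPR + f2$TPR) / 2,
    AUC = (f1$AUC + f2$AUC) / 2, SI = (f1$SI + f2$SI) / 2,
    threshold = (f1$threshold + f2$threshold) / 2,
    n_train = f1$n_train, n_test = f1$n_test,
    chosen_resolution = ts$chosen_resolution)
  list(record = rec, suitability = mean_suit)
}
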