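#' Build connection and nodal feature matrices for classification
#'
#' Connection features are the upper-triangle vectorization of each
#' subject's weight matrix in fixed row-major pair order — `N(N-1)/2`
#' features (4005 for 90 regions). Nodal features are three blocks of `N`
#' in fixed order: strength, nodal global efficiency, nodal local
#' efficiency (270 for 90 regions).
#'
#' @param networks list of `fn_network`, one per subject.
#' @param nodal list of `fn_nodal_metrics` aligned with `networks`.
#' @param labels factor/character of group labels (`"A"`/`"B"`) aligned
#'   with `networks`.
#' @return object of class `fn_features`: list with `connection`
#'   (subjects x pairs matrix), `nodal` (subjects x 3N matrix), `labels`
#'   (factor with levels A, B), `feature_names` per family.
#' @export
build_features <- function(networks, nodal, labels) {
  ns <- length(networks)
  if (length(nodal) != ns || length(labels) != ns) {
    stopf("networks, nodal metrics and labels must be aligned (one per subject)")
  }
  region_labels <- networks[[1]]$region_labels
  for (g in networks) {
    if (!identical(g$region_labels, region_labels)) {
      stopf("all networks must share the same region ordering")
    }
  }
  for (nm in nodal) {
    if (!identical(nm$region, region_labels)) {
      stopf("nodal metrics region order must match the networks")
    }
  }
  conn <- t(vapply(networks, function(g) vec_upper(g$weights),
                   numeric(length(region_labels) * (length(region_labels) - 1) / 2)))
  nod <- t(vapply(nodal, function(nm) {
    c(nm$strength, nm$global_efficiency, nm$local_efficiency)
  }, numeric(3 * length(region_labels))))
  p <- upper_pairs(length(region_labels))
  conn_names <- paste0(region_labels[p[, 1]], "--", region_labels[p[, 2]])
  nod_names <- c(paste0("strength.", region_labels),
                 paste0("eglob.", region_labels),
                 paste0("eloc.", region_labels))
  colnames(conn) <- conn_names
  colnames(nod) <- nod_names
  labels <- factor(as.character(labels), levels = c("A", "B"))
  if (anyNA(labels)) stopf("group labels must be 'A' or 'B'")
  structure(list(connection = conn, nodal = nod, labels = labels,
                 feature_names = list(connection = conn_names,
                                      nodal = nod_names)),
            class = "fn_features")
}

#' Select features by two-sample t-test on training subjects
#'
#' Keeps features whose two-sample (pooled) t-test p-value between the two
#' training classes is below `alpha`. Constant features are never
#' selected. If no feature passes, the single smallest-p feature is kept
#' so downstream classification always has an input (the fallback is
#' flagged in the attributes).
#'
#' @param x training feature matrix (subjects x features).
#' @param y training labels (factor with both classes present).
#' @param alpha selection threshold (default 0.001).
#' @return logical mask over features with attributes `p_values` and
#'   `fallback`.
#' @export
select_features <- function(x, y, alpha = 0.001) {
  y <- factor(y)
  if (nlevels(droplevels(y)) != 2) {
    stopf("feature selection needs both classes in the training labels")
  }
  p <- feature_t_pvalues(x, y)
  mask <- !is.na(p) & p < alpha
  fallback <- FALSE
  if (!any(mask)) {
    fallback <- TRUE
    best <- which.min(p)
    if (!length(best)) best <- 1L
    mask[best] <- TRUE
  }
  structure(mask, p_values = p, fallback = fallback)
}

# vectorized pooled two-sample t-test p-values per feature column
feature_t_pvalues <- function(x, y) {
  lv <- levels(factor(y))
  ia <- which(y == lv[1]); ib <- which(y == lv[2])
  na <- length(ia); nb <- length(ib)
  xa <- x[ia, , drop = FALSE]; xb <- x[ib, , drop = FALSE]
  ma <- colMeans(xa); mb <- colMeans(xb)
  ssa <- colSums(xa^2) - na * ma^2
  ssb <- colSums(xb^2) - nb * mb^2
  df <- na + nb - 2
  se <- sqrt((ssa + ssb) / df * (1 / na + 1 / nb))
  d <- ma - mb
  tt <- ifelse(se > 0, d / se, ifelse(d == 0, NA_real_, Inf))
  p <- 2 * stats::pt(-abs(tt), df)
  p[is.infinite(tt)] <- 0
  p
}

#' Confusion-matrix metrics with group B as the positive class
#'
#' Accuracy `(TP+TN)/(TP+TN+FN+FP)`, sensitivity `TP/(TP+FN)` (proportion
#' of group-B subjects correctly predicted) and specificity `TN/(FP+TN)`
#' (proportion of group-A subjects correctly predicted).
#'
#' @param predictions,labels aligned factors/characters with values
#'   `"A"`/`"B"`.
#' @return list with `tp`, `tn`, `fp`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity` (metrics `NA` when the relevant class is absent).
#' @export
confusion_metrics <- function(predictions, labels) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels)) stopf("inputs must be aligned")
  tp <- sum(predictions == "B" & labels == "B")
  tn <- sum(predictions == "A" & labels == "A")
  fp <- sum(predictions == "B" & labels == "A")
  fn <- sum(predictions == "A" & labels == "B")
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (fp + tn) else NA_real_)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps thresholds over the unique scores (predict positive when the
#' score is at or above the threshold), records (1 - specificity,
#' sensitivity) points and integrates by the trapezoid rule — with score
#' ties handled by the sweep itself this equals the rank (concordance)
#' AUC with tied pairs counted 1/2.
#'
#' @param scores numeric decision scores, larger = more group-B-like.
#' @param labels aligned labels `"A"`/`"B"`; B is positive.
#' @return list with `roc_points` (data frame `fpr`, `tpr`, `threshold`)
#'   and `auc`; constant scores give `auc = 0.5` with `degenerate = TRUE`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stopf("inputs must be aligned")
  pos <- labels == "B"
  if (!any(pos) || all(pos)) stopf("both classes must be present")
  if (length(unique(scores)) == 1) {
    pts <- data.frame(fpr = c(0, 1), tpr = c(0, 1),
                      threshold = c(Inf, unique(scores)))
    return(list(roc_points = pts, auc = 0.5, degenerate = TRUE))
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    data.frame(fpr = sum(pred & !pos) / sum(!pos),
               tpr = sum(pred & pos) / sum(pos),
               threshold = t)
  }))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(roc_points = pts, auc = auc, degenerate = FALSE)
}

#' Multiple-kernel SVM with leave-one-out cross-validation
#'
#' For every left-out subject: z-score each feature family on the training
#' subjects, select features family-wise by two-sample t-test on the
#' training subjects only, form one linear kernel per family and combine
#' them as `K = beta1 K1 + beta2 K2` with `beta` on the simplex, train a
#' soft-margin SVM and predict the held-out subject. `beta` is chosen by a
#' simplex grid search (step 0.1) with stratified inner k-fold validation
#' on the training set; linear kernels make the combination equivalent to
#' concatenating the feature blocks scaled by `sqrt(beta)`, which is how
#' it is realized. Selection placement is fold-wise by default; a
#' whole-sample mode (`selection = "pooled"`) selects once on all subjects
#' before cross-validation.
#'
#' @param features `fn_features`.
#' @param families which feature families to use (default both;
#'   a single family gives the single-kernel classifier).
#' @param selection_alpha t-test selection threshold (default 0.001).
#' @param beta fixed kernel weights (numeric over `families`, summing
#'   to 1), or `NULL` (default) to choose by inner validation.
#' @param cost soft-margin cost C (default 1).
#' @param inner_folds inner validation folds for the beta search
#'   (default 5).
#' @param selection `"fold"` (default, selection inside each training
#'   fold) or `"pooled"` (selection once on the full sample).
#' @param seed seed for inner fold assignment.
#' @return object of class `fn_classification`: per-fold predictions and
#'   decision scores, confusion counts, `accuracy`, `sensitivity`,
#'   `specificity`, `roc` (points + `auc`), `kernel_weights` (mean beta
#'   across folds), `selected_frequency` per family, `config` echo.
#' @export
mkl_svm_loocv <- function(features, families = c("connection", "nodal"),
                          selection_alpha = 0.001, beta = NULL, cost = 1,
                          inner_folds = 5, selection = c("fold", "pooled"),
                          seed = 1) {
  stopifnot(inherits(features, "fn_features"))
  selection <- match.arg(selection)
  families <- match.arg(families, c("connection", "nodal"),
                        several.ok = TRUE)
  y <- features$labels
  n <- length(y)
  if (n < 4 || min(table(y)) < 2) {
    stopf("need at least 4 subjects with both classes represented twice")
  }
  fam_x <- lapply(families, function(f) features[[f]])
  names(fam_x) <- families
  if (!is.null(beta)) {
    if (length(beta) != length(families) || any(beta < 0) ||
        abs(sum(beta) - 1) > 1e-8) {
      stopf("beta must be nonnegative over the families and sum to 1")
    }
  }
  pooled_masks <- NULL
  if (selection == "pooled") {
    pooled_masks <- lapply(fam_x, function(x) select_features(x, y, selection_alpha))
  }

  grid <- if (length(families) == 1) {
    matrix(1, 1, 1)
  } else {
    b1 <- seq(0, 1, by = 0.1)
    cbind(b1, 1 - b1)
  }

  preds <- character(n)
  scores <- numeric(n)
  fold_betas <- matrix(NA_real_, n, length(families),
                       dimnames = list(NULL, families))
  sel_count <- lapply(fam_x, function(x) numeric(ncol(x)))

  with_seed(seed, {
    for (s in seq_len(n)) {
      tr <- setdiff(seq_len(n), s)
      prep <- prepare_fold(fam_x, y, tr, selection_alpha, pooled_masks)
      for (f in seq_along(families)) {
        sel_count[[f]][prep$masks[[f]]] <- sel_count[[f]][prep$masks[[f]]] + 1
      }
      b <- beta
      if (is.null(b) && nrow(grid) > 1) {
        acc <- inner_beta_search(prep$xtr, y[tr], grid, cost, inner_folds,
                                 fam_x, tr, selection_alpha, pooled_masks,
                                 selection)
        b <- grid[which.max(acc), ]
      } else if (is.null(b)) {
        b <- 1
      }
      fold_betas[s, ] <- b
      fit <- svm_fit(fuse_blocks(prep$xtr, b), y[tr], cost)
      sc <- svm_score_b(fit, fuse_blocks(prep$apply(s), b))
      scores[s] <- sc
      preds[s] <- if (sc >= 0) "B" else "A"
    }
  })

  cm <- confusion_metrics(preds, y)
  roc <- roc_auc(scores, y)
  structure(list(
    fold_predictions = data.frame(subject = seq_len(n),
                                  label = as.character(y),
                                  prediction = preds, score = scores,
                                  stringsAsFactors = FALSE),
    confusion = cm[c("tp", "tn", "fp", "fn")],
    accuracy = cm$accuracy, sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    roc = roc, auc = roc$auc,
    kernel_weights = colMeans(fold_betas),
    selected_frequency = lapply(sel_count, function(v) v / n),
    config = list(families = families, selection_alpha = selection_alpha,
                  beta = beta, cost = cost, inner_folds = inner_folds,
                  selection = selection, seed = seed)
  ), class = "fn_classification")
}

# z-score + select each family on training subjects; returns training
# blocks and a closure applying the same transform to other subjects
prepare_fold <- function(fam_x, y, tr, alpha, pooled_masks) {
  stats_f <- lapply(fam_x, function(x) {
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    list(mu = mu, sd = sdv)
  })
  masks <- lapply(seq_along(fam_x), function(f) {
    if (!is.null(pooled_masks)) {
      as.logical(pooled_masks[[f]])
    } else {
      xs <- sweep_scale(fam_x[[f]][tr, , drop = FALSE], stats_f[[f]])
      as.logical(select_features(xs, y[tr], alpha))
    }
  })
  xtr <- lapply(seq_along(fam_x), function(f) {
    xs <- sweep_scale(fam_x[[f]][tr, , drop = FALSE], stats_f[[f]])
    xs[, masks[[f]], drop = FALSE]
  })
  list(
    xtr = xtr, masks = masks,
    apply = function(idx) {
      lapply(seq_along(fam_x), function(f) {
        xs <- sweep_scale(fam_x[[f]][idx, , drop = FALSE], stats_f[[f]])
        xs[, masks[[f]], drop = FALSE]
      })
    }
  )
}

sweep_scale <- function(x, st) {
  sweep(sweep(x, 2, st$mu, "-"), 2, st$sd, "/")
}

# concatenate family blocks scaled by sqrt(beta): the linear-kernel Gram
# matrix of the result is exactly beta1 K1 + beta2 K2
fuse_blocks <- function(blocks, beta) {
  do.call(cbind, lapply(seq_along(blocks), function(f) {
    sqrt(beta[f]) * blocks[[f]]
  }))
}

svm_fit <- function(x, y, cost) {
  e1071::svm(x = x, y = factor(y, levels = c("A", "B")), kernel = "linear",
             cost = cost, scale = FALSE)
}

# decision scores oriented so that positive = class B (one per row of xnew)
svm_score_b <- function(fit, xnew) {
  dv <- attr(stats::predict(fit, xnew, decision.values = TRUE),
             "decision.values")
  sc <- as.numeric(dv[, 1])
  if (grepl("^B/", colnames(dv)[1])) sc else -sc
}

# stratified inner k-fold accuracy for each beta row of the grid
inner_beta_search <- function(xtr_outer, ytr, grid, cost, k,
                              fam_x, tr, alpha, pooled_masks, selection) {
  n <- length(ytr)
  folds <- integer(n)
  for (lv in levels(factor(ytr))) {
    idx <- which(ytr == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  acc <- numeric(nrow(grid))
  y_all <- y_all_cache(fam_x, tr, ytr)
  for (fold in seq_len(k)) {
    hold <- which(folds == fold)
    if (!length(hold) || nlevels(droplevels(factor(ytr[-hold]))) < 2) next
    prep <- prepare_fold(fam_x, y_all, tr[-hold], alpha,
                         if (selection == "pooled") pooled_masks else NULL)
    xin <- prep$xtr
    xho <- prep$apply(tr[hold])
    for (g in seq_len(nrow(grid))) {
      fit <- svm_fit(fuse_blocks(xin, grid[g, ]), ytr[-hold], cost)
      sc <- svm_score_b(fit, fuse_blocks(xho, grid[g, ]))
      ph <- ifelse(sc >= 0, "B", "A")
      acc[g] <- acc[g] + sum(ph == as.character(ytr[hold]))
    }
  }
  acc
}

# reconstruct the full label vector for prepare_fold's y argument
y_all_cache <- function(fam_x, tr, ytr) {
  n_all <- nrow(fam_x[[1]])
  y_all <- factor(rep("A", n_all), levels = c("A", "B"))
  y_all[tr] <- ytr
  y_all
}

#' @export
print.fn_classification <- function(x, ...) {
  cat(sprintf("MKL-SVM LOOCV (%s): accuracy %.4f, sensitivity %.4f, specificity %.4f, AUC %.4f\n",
              paste(x$config$families, collapse = " + "),
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("  confusion TP %d, TN %d, FP %d, FN %d; mean kernel weights: %s\n",
              x$confusion$tp, x$confusion$tn, x$confusion$fp, x$confusion$fn,
              paste(sprintf("%s %.2f", names(x$kernel_weights),
                            x$kernel_weights), collapse = ", ")))
  invisible(x)
}
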