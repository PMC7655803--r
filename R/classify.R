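#' Z-score feature table for a cohort
#'
#' Computes, for every component of every network, the metric battery
#' and motif census normalized against connected-random-graph null
#' ensembles, in wide format (one row per component, one column per
#' Z-scored feature). Ensembles are cached per (nodes, links) pair:
#' ensemble membership depends only on those two counts, so components
#' with equal counts share a null.
#'
#' @param networks A `synthetic_cohort`, list of [mito_network()]s, or
#'   one network.
#' @param n_random Null ensemble size per (n, l).
#' @param seed Base seed for the ensembles.
#' @param min_size Smallest component size given Z-scores (smaller
#'   components are skipped; size-1 components carry no pairwise
#'   metrics).
#' @return data.frame: provenance columns, `size`, `links`, raw metric
#'   columns, and `<metric>_z` / `<motif>_z` columns (`NA` where the
#'   null SD is zero).
#' @export
zscores_table <- function(networks, n_random = 100, seed = 1L,
                          min_size = 3) {
  nets <- as_network_list(networks)
  cache <- new.env(hash = TRUE)
  rows <- list()
  for (net in nets) {
    comps <- extract_components(net)
    for (ci in seq_along(comps)) {
      cc <- comps[[ci]]
      n <- igraph::vcount(cc); l <- igraph::ecount(cc)
      if (n < min_size) next
      key <- paste(n, l)
      if (!exists(key, envir = cache)) {
        assign(key, build_null(cc, n_random,
                               seed = seed + n * 1000L + l,
                               keep_graphs = FALSE), envir = cache)
      }
      null <- get(key, envir = cache)
      cid <- paste0(net$network_id, "_c", ci)
      zs <- component_zscores(cc, null, component_id = cid)
      mz <- motif_zscores(motif_census(cc), null)
      row <- data.frame(subject_id = net$subject_id, side = net$side,
                        network_id = net$network_id, component_id = cid,
                        size = n, links = l)
      for (i in seq_len(nrow(zs))) {
        row[[zs$metric[i]]] <- zs$M[i]
        row[[paste0(zs$metric[i], "_z")]] <- zs$z[i]
      }
      for (i in seq_len(nrow(mz))) row[[mz$metric[i]]] <- mz$z[i]
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Build classifier feature instances
#'
#' One instance per component passing the side and size filters, with
#' the selected feature columns. Instances with more than half of their
#' features undefined are dropped; remaining missing values are left for
#' training-fold imputation inside the cross-validation.
#'
#' @param ztbl A [zscores_table()] (must carry `subject_id`, `side`,
#'   `size` and a `label` column, or a cohort to derive labels from).
#' @param labels Named character vector subject_id -> class label.
#' @param side_filter Optional `"left"` or `"right"`.
#' @param size_filter Optional inclusive `c(min, max)` (a single number
#'   is a lower bound).
#' @param feature_subset Character vector of feature columns; default
#'   all `_z` columns.
#' @return data.frame of instances: `subject_id`, `label`, `side`,
#'   `size`, then feature columns (attribute `features` lists them).
#' @export
build_feature_table <- function(ztbl, labels, side_filter = NULL,
                                size_filter = NULL, feature_subset = NULL) {
  tbl <- ztbl
  if (!is.null(side_filter)) tbl <- tbl[tbl$side == side_filter, ]
  if (!is.null(size_filter)) {
    if (length(size_filter) == 1) size_filter <- c(size_filter, Inf)
    if (size_filter[1] > size_filter[2])
      stop_invalid("size_filter bounds are inverted")
    tbl <- tbl[tbl$size >= size_filter[1] & tbl$size <= size_filter[2], ]
  }
  if (is.null(feature_subset))
    feature_subset <- grep("_z$", names(tbl), value = TRUE)
  missing_cols <- setdiff(feature_subset, names(tbl))
  if (length(missing_cols))
    stop_invalid("unknown features: %s", paste(missing_cols, collapse = ", "))
  keep <- rowMeans(is.na(tbl[, feature_subset, drop = FALSE])) <= 0.5
  tbl <- tbl[keep, , drop = FALSE]
  if (!nrow(tbl)) stop_invalid("no instances remain after filtering")
  out <- data.frame(subject_id = tbl$subject_id,
                    label = unname(labels[tbl$subject_id]),
                    side = tbl$side, size = tbl$size,
                    tbl[, feature_subset, drop = FALSE])
  attr(out, "features") <- feature_subset
  out
}

#' Labels of a synthetic cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return Named character vector subject_id -> group label.
#' @export
cohort_labels <- function(cohort) {
  setNames(vapply(cohort$subjects, `[[`, "", "group"),
           vapply(cohort$subjects, `[[`, "", "subject_id"))
}

#' Multilayer perceptron specification
#'
#' @param hidden Hidden units of the single hidden layer.
#' @param decay Weight decay.
#' @param maxit Maximum training epochs.
#' @return List of class `mlp_spec`.
#' @export
mlp_spec <- function(hidden = 16, decay = 0.01, maxit = 500) {
  structure(list(hidden = hidden, decay = decay, maxit = maxit),
            class = "mlp_spec")
}

.instance_features <- function(instances) {
  attr(instances, "features") %||%
    setdiff(names(instances), c("subject_id", "label", "side", "size",
                                "component_id"))
}

#' Leave-one-subject-out cross-validated classification
#'
#' For each subject, a multilayer perceptron is trained on all other
#' subjects' instances and scores the held-out subject's instances;
#' pooled scores give one ROC curve and AUC. Features are standardized
#' and missing values imputed with the training fold's statistics only.
#' An audit log records the training subjects of every fold, asserting
#' that no fold ever saw its test subject.
#'
#' @param instances [build_feature_table()] output.
#' @param model_spec An [mlp_spec()].
#' @param seed Seed for weight initialization (per-fold offsets applied).
#' @param positive Positive class label (default `"PD"` when present).
#' @return Object of class `cv_result`: `scores` (per-instance
#'   data.frame), `roc`, `auc`, `folds` (audit log), `settings`.
#' @export
leave_one_subject_out_cv <- function(instances, model_spec = mlp_spec(),
                                     seed = 1L, positive = NULL) {
  feats <- .instance_features(instances)
  labs <- instances$label
  classes <- sort(unique(labs))
  if (length(classes) != 2) stop_invalid("need exactly 2 classes")
  if (is.null(positive)) positive <- if ("PD" %in% classes) "PD" else classes[2]
  subj <- unique(instances$subject_id)
  per_class_subj <- table(unique(instances[, c("subject_id", "label")])$label)
  if (any(per_class_subj < 2))
    stop_invalid("need at least 2 subjects per class")
  scores <- rep(NA_real_, nrow(instances))
  folds <- list()
  for (fi in seq_along(subj)) {
    test_id <- subj[fi]
    tr <- instances$subject_id != test_id
    if (length(unique(labs[tr])) < 2)
      stop_invalid("training fold for subject %s has a single class", test_id)
    X <- as.matrix(instances[, feats, drop = FALSE])
    Xtr <- X[tr, , drop = FALSE]
    med <- apply(Xtr, 2, median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (j in seq_along(feats)) {
      Xtr[is.na(Xtr[, j]), j] <- med[j]
    }
    mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd)
    sg[sg == 0 | is.na(sg)] <- 1
    Xtr <- scale(Xtr, center = mu, scale = sg)
    Xte <- X[!tr, , drop = FALSE]
    for (j in seq_along(feats)) Xte[is.na(Xte[, j]), j] <- med[j]
    Xte <- scale(Xte, center = mu, scale = sg)
    ytr <- as.numeric(labs[tr] == positive)
    fit <- local_seed(seed + fi, {
      nnet::nnet(x = Xtr, y = ytr, size = model_spec$hidden,
                 decay = model_spec$decay, maxit = model_spec$maxit,
                 entropy = TRUE, trace = FALSE)
    })
    scores[!tr] <- as.numeric(predict(fit, Xte))
    folds[[fi]] <- list(test_subject = test_id,
                        train_subjects = setdiff(subj, test_id))
    stopifnot(!test_id %in% folds[[fi]]$train_subjects)
  }
  ra <- roc_auc(scores, labs == positive)
  structure(list(
    scores = data.frame(subject_id = instances$subject_id,
                        label = labs, score = scores),
    roc = ra$roc, auc = ra$auc, folds = folds,
    settings = list(model_spec = model_spec, positive = positive,
                    features = feats, seed = seed)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: AUC = %.3f over %d instances, %d folds>\n",
              x$auc, nrow(x$scores), length(x$folds)))
  invisible(x)
}

#' Label-reshuffling control for the classifier
#'
#' Permutes the class labels at the subject level (all of a subject's
#' instances receive the same permuted label, class counts preserved)
#' and reruns the full leave-one-subject-out CV for each permutation.
#'
#' @param instances [build_feature_table()] output.
#' @param model_spec An [mlp_spec()].
#' @param n_reshuffles Number of permutations (50 by default).
#' @param seed Seed for the permutations.
#' @return Numeric vector of null AUCs, one per reshuffle.
#' @export
reshuffle_control <- function(instances, model_spec = mlp_spec(),
                              n_reshuffles = 50, seed = 1L) {
  map <- unique(instances[, c("subject_id", "label")])
  local_seed(seed, {
    vapply(seq_len(n_reshuffles), function(r) {
      perm <- setNames(sample(map$label), map$subject_id)
      inst2 <- instances
      inst2$label <- unname(perm[inst2$subject_id])
      attr(inst2, "features") <- .instance_features(instances)
      leave_one_subject_out_cv(inst2, model_spec,
                               seed = seed + 7919L * r)$auc
    }, 1)
  })
}

#' ROC curve and AUC
#'
#' Empirical ROC over all distinct score thresholds; AUC by the
#' trapezoidal rule, which handles tied scores by the midrank
#' convention (identical to the normalized Mann-Whitney U statistic).
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical (TRUE = positive) or two-level factor/character
#'   with positive class given by `positive`.
#' @param positive Positive class when `labels` is not logical.
#' @return List: `roc` (data.frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels)) {
    if (is.null(positive)) positive <- sort(unique(labels))[2]
    labels <- labels == positive
  }
  if (!any(labels) || all(labels))
    stop_invalid("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # one ROC point per distinct threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}
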