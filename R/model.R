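#' Training labels from HRR classification
#'
#' Builds the classifier's label set: samples with a biallelic BRCA1 or
#' BRCA2 alteration are true positives, HRR-wildtype samples true negatives,
#' and everything else (biallelic non-BRCA genes, monoallelic or
#' zygosity-unknown alterations, biallelic PALB2, ...) is excluded from
#' training. The partition is exhaustive and mutually exclusive.
#'
#' @param sample_classes tibble from [call_zygosity()]`$samples` (`sample`,
#'   `hrr_class`, `brca12_biallelic`)
#' @return tibble `sample`, `label` (positive / negative / excluded),
#'   `reason`
#' @export
build_training_labels <- function(sample_classes) {
  sample_classes |>
    transmute(
      sample = .data$sample,
      label = case_when(
        .data$brca12_biallelic ~ "positive",
        .data$hrr_class == "HRRwt" ~ "negative",
        TRUE ~ "excluded"
      ),
      reason = case_when(
        .data$brca12_biallelic ~ "biallelic-BRCA1/2",
        .data$hrr_class == "HRRwt" ~ "HRRwt",
        TRUE ~ "other"
      )
    )
}

#' Train the HRD scar classifier
#'
#' Fits a gradient-boosted tree ensemble (xgboost, binary logistic) on the
#' scar feature vectors of labelled samples, with seeded stratified 5-fold
#' cross-validation to produce out-of-fold scores for every labelled sample.
#' Excluded samples never enter any training fold. The decision threshold is
#' set from the out-of-fold scores of the negatives at the requested
#' specificity (or by matching a target call prevalence).
#'
#' @param features tibble from [extract_features()] (`sample` + feature
#'   columns)
#' @param labels tibble from [build_training_labels()]
#' @param hyperparams named list; defaults: `max_depth = 3`, `eta = 0.1`,
#'   `nrounds = 150`, `subsample = 0.9`, `colsample_bytree = 0.9`. The study
#'   that introduced the signature specifies none, so these are ordinary
#'   small-data boosting settings.
#' @param seed integer seed controlling fold assignment and boosting
#' @param nfold number of CV folds
#' @param threshold_mode `"specificity"` (default) or `"prevalence"`
#' @param target_specificity specificity on held-out negatives used when
#'   `threshold_mode = "specificity"`
#' @param target_prevalence call prevalence used when
#'   `threshold_mode = "prevalence"`
#' @return object of class `hrdsig_model`: list with `fit` (xgb.Booster),
#'   `feature_names`, `threshold`, `threshold_mode`, `cv` (tibble sample,
#'   label, fold, oof_score), `metrics` (out-of-fold AUROC etc.),
#'   `hyperparams`, `seed`
#' @export
train_classifier <- function(features, labels,
                             hyperparams = list(), seed = 1L,
                             nfold = 5L,
                             threshold_mode = c("specificity", "prevalence"),
                             target_specificity = 0.95,
                             target_prevalence = 0.09) {
  threshold_mode <- match.arg(threshold_mode)
  hp <- utils::modifyList(
    list(max_depth = 3, eta = 0.1, nrounds = 150,
         subsample = 0.9, colsample_bytree = 0.9),
    hyperparams
  )
  dat <- inner_join(features, labels, by = "sample") |>
    filter(.data$label %in% c("positive", "negative"))
  n_pos <- sum(dat$label == "positive")
  n_neg <- sum(dat$label == "negative")
  if (n_pos < 20 || n_neg < 20) {
    abort(sprintf(
      "need at least 20 samples per class to train (have %d positive, %d negative)",
      n_pos, n_neg))
  }
  fn <- scar_feature_names()
  miss <- setdiff(fn, names(dat))
  if (length(miss)) {
    abort(paste0("features missing columns: ", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(dat[, fn])
  y <- as.integer(dat$label == "positive")

  withr::with_seed(seed, {
    fold <- integer(nrow(dat))
    for (cl in c(0L, 1L)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(nfold), length(idx)))
    }
    oof <- numeric(nrow(dat))
    for (f in seq_len(nfold)) {
      tr <- fold != f
      bst <- xgb_fit(x[tr, , drop = FALSE], y[tr], hp)
      oof[!tr] <- xgb_score(bst, x[!tr, , drop = FALSE])
    }
    fit <- xgb_fit(x, y, hp)
  })

  cv <- tibble(sample = dat$sample, label = dat$label, fold = fold,
               oof_score = oof)
  auc <- auroc(oof, y)
  threshold <- if (threshold_mode == "specificity") {
    select_threshold(oof[y == 0L], target_specificity)
  } else {
    as.numeric(quantile(oof, 1 - target_prevalence, type = 1))
  }
  structure(
    list(fit = fit, feature_names = fn, threshold = threshold,
         threshold_mode = threshold_mode, cv = cv,
         metrics = list(oof_auroc = auc, n_pos = n_pos, n_neg = n_neg),
         hyperparams = hp, seed = seed),
    class = "hrdsig_model"
  )
}

xgb_fit <- function(x, y, hp) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  eta = hp$eta, subsample = hp$subsample,
                  colsample_bytree = hp$colsample_bytree, nthread = 1,
                  seed = sample.int(.Machine$integer.max, 1)),
    data = dtrain, nrounds = hp$nrounds, verbose = 0
  )
}

xgb_score <- function(fit, x) {
  predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUROC with ties handled by midranks.
#'
#' @param score numeric scores
#' @param truth 0/1 (or logical) class labels
#' @return AUROC in \[0,1\]
#' @export
auroc <- function(score, truth) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) abort("auroc needs both classes")
  r <- rank(score)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Decision threshold at a target specificity
#'
#' Returns the smallest score threshold achieving at least the target
#' specificity on a held-out set of negative scores, under the convention
#' that a score greater than or equal to the threshold is called positive.
#' With `target_specificity = 0` this is the minimum observed score; when no
#' observed score suffices (e.g. target 1 with ties at the maximum) a value
#' just above the largest negative score is returned.
#'
#' @param heldout_negatives numeric vector of scores of known negatives
#' @param target_specificity required fraction of negatives called negative
#' @return numeric threshold
#' @export
select_threshold <- function(heldout_negatives, target_specificity = 0.95) {
  s <- heldout_negatives[!is.na(heldout_negatives)]
  if (length(s) == 0L) abort("empty held-out negative score set")
  if (target_specificity < 0 || target_specificity > 1) {
    abort("target_specificity must be in [0,1]")
  }
  cand <- c(sort(unique(s)), max(s) + 1e-9)
  spec <- vapply(cand, function(th) mean(s < th), numeric(1))
  cand[which(spec >= target_specificity)[1]]
}

#' Apply the classifier
#'
#' Scores feature vectors with a trained [train_classifier()] bundle and
#' calls HRD signature status; a score exactly at the threshold is called
#' positive.
#'
#' @param bundle an `hrdsig_model`
#' @param features feature tibble (`sample` + the bundle's feature columns)
#' @return tibble `sample`, `score`, `call` ("positive"/"negative"),
#'   `threshold_used`
#' @export
predict_hrdsig <- function(bundle, features) {
  stopifnot(inherits(bundle, "hrdsig_model"))
  if (nrow(features) == 0L) {
    return(tibble(sample = character(), score = double(), call = character(),
                  threshold_used = double()))
  }
  miss <- setdiff(bundle$feature_names, names(features))
  if (length(miss)) {
    abort(paste0("features missing columns: ", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(features[, bundle$feature_names])
  score <- xgb_score(bundle$fit, x)
  tibble(
    sample = features$sample,
    score = score,
    call = ifelse(score >= bundle$threshold, "positive", "negative"),
    threshold_used = bundle$threshold
  )
}

#' @export
print.hrdsig_model <- function(x, ...) {
  cat("<hrdsig_model>\n")
  cat(sprintf("  trained on %d positive / %d negative samples\n",
              x$metrics$n_pos, x$metrics$n_neg))
  cat(sprintf("  out-of-fold AUROC: %.3f; threshold %.4f (%s mode)\n",
              x$metrics$oof_auroc, x$threshold, x$threshold_mode))
  invisible(x)
}

#' @rdname train_classifier
#' @param x,object an `hrdsig_model`
#' @param ... unused
#' @export
tidy.hrdsig_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$fit)
  tibble(feature = imp$Feature, gain = imp$Gain, cover = imp$Cover,
         frequency = imp$Frequency)
}

#' @rdname train_classifier
#' @export
glance.hrdsig_model <- function(x, ...) {
  tibble(oof_auroc = x$metrics$oof_auroc, n_pos = x$metrics$n_pos,
         n_neg = x$metrics$n_neg, threshold = x$threshold,
         threshold_mode = x$threshold_mode, nrounds = x$hyperparams$nrounds)
}

#' @rdname train_classifier
#' @export
autoplot.hrdsig_model <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(.data$oof_score, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "out-of-fold score", y = "samples",
                  fill = "training label",
                  title = sprintf("out-of-fold AUROC %.3f, threshold %.3f",
                                  object$metrics$oof_auroc, object$threshold))
}

#' Serialize / restore a trained model bundle
#'
#' The boosted ensemble is written with xgboost's native serialisation and
#' the bundle metadata (feature list, threshold, CV table, hyperparameters,
#' seed) as a JSON sidecar.
#'
#' @param bundle an `hrdsig_model`
#' @param path file stem; writes `<path>.ubj` and `<path>.json`
#' @return `save_model()`: paths invisibly; `load_model()`: the bundle
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "hrdsig_model"))
  model_path <- paste0(path, ".ubj")
  meta_path <- paste0(path, ".json")
  xgboost::xgb.save(bundle$fit, model_path)
  meta <- bundle[setdiff(names(bundle), "fit")]
  meta$cv <- as.data.frame(meta$cv)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(model = model_path, meta = meta_path))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(fit = xgboost::xgb.load(paste0(path, ".ubj")),
         feature_names = meta$feature_names,
         threshold = meta$threshold, threshold_mode = meta$threshold_mode,
         cv = as_tibble(meta$cv), metrics = as.list(meta$metrics),
         hyperparams = as.list(meta$hyperparams), seed = meta$seed),
    class = "hrdsig_model"
  )
}
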