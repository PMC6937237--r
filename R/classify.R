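#' Patient-grouped, stratified fold plan
#'
#' Partitions the patient set into `k` outer folds so that no patient
#' appears in both the training and the test side of any split (all 72
#' augmented samples of a patient travel together). With
#' `stratified = TRUE`, each class's patients are dealt cyclically across
#' folds; a class with fewer members than folds triggers a warning and a
#' non-strict assignment. The same fold plan is reused across the four
#' feature sets of a task so accuracies are paired.
#'
#' @param patient_ids Character vector of distinct patient ids.
#' @param labels Class label per patient (same length/order as
#'   `patient_ids`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return A `fold_plan`: list with `folds` (list of `k` test-patient-id
#'   vectors), `k`, `seed`, `stratified`.
#' @export
make_folds <- function(patient_ids, labels, k = 10L, seed = 1L,
                       stratified = TRUE) {
  n <- length(patient_ids)
  if (anyDuplicated(patient_ids)) stopf("`patient_ids` must be distinct")
  if (length(labels) != n) stopf("`labels` must match `patient_ids`")
  if (k > n) stopf("k = %d exceeds the %d patients", k, n)
  fold_of <- integer(n)
  with_seed(seed, {
    if (stratified) {
      small <- names(which(table(labels) < k))
      if (length(small)) {
        warnf("class(es) %s have fewer than %d members; stratification is non-strict",
              paste(small, collapse = ", "), k)
      }
      start <- sample.int(k, 1L) - 1L
      for (cl in unique(labels)) {
        members <- sample(which(labels == cl))
        fold_of[members] <- (start + seq_along(members) - 1L) %% k + 1L
        start <- start + length(members)
      }
    } else {
      fold_of[sample.int(n)] <- (seq_len(n) - 1L) %% k + 1L
    }
  })
  structure(
    list(
      folds = lapply(seq_len(k), function(i) patient_ids[fold_of == i]),
      k = as.integer(k),
      seed = as.integer(seed),
      stratified = stratified
    ),
    class = "fold_plan"
  )
}

#' One-way ANOVA F-statistic per feature
#'
#' The univariate screening statistic: for each column of `x`,
#' `F = (SSB / (g - 1)) / (SSW / (n - g))` across the label groups.
#' Features with zero within-group and zero between-group variance get
#' `F = 0`; zero within-group but positive between-group variance gives
#' `Inf` (such features sort first).
#'
#' @param x Numeric matrix, samples in rows.
#' @param labels Group label per row; at least two groups.
#' @return Numeric vector of per-feature F values.
#' @export
f_statistic <- function(x, labels) {
  x <- as.matrix(x)
  g <- factor(labels)
  ng <- nlevels(g)
  if (ng < 2L) stopf("need at least two classes")
  n <- nrow(x)
  counts <- as.vector(table(g))
  gm <- rowsum(x, g) / counts                 # group means, ng x p
  grand <- colMeans(x)
  ssb <- colSums(counts * (gm - rep(grand, each = ng))^2)
  sst <- colSums((x - rep(grand, each = n))^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (ng - 1)) / (ssw / (n - ng))
  f[ssw == 0 & ssb <= 1e-12 * pmax(sst, 1)] <- 0
  f[ssw == 0 & ssb > 1e-12 * pmax(sst, 1)] <- Inf
  unname(f)
}

# Top-m feature indices by F, ties broken by (stable) feature index.
top_m_indices <- function(f, m) {
  m <- min(m, length(f))
  sort(order(-f)[seq_len(m)])
}

#' Balanced accuracy from a confusion matrix
#'
#' Mean over classes of the per-class recall (rows = true classes,
#' columns = predicted), so the measure is not affected by an imbalanced
#' number of samples among classes. With balanced classes it coincides
#' with plain accuracy.
#'
#' @param confusion Square count matrix, true classes in rows.
#' @return Fraction in `[0, 1]`.
#' @export
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  rs <- rowSums(confusion)
  if (any(rs == 0)) stopf("every true class needs at least one test sample")
  mean(diag(confusion) / rs)
}

#' Area under the precision-recall curve
#'
#' Average-precision form: precision is accumulated at each recall
#' increment while sweeping a threshold down the scores (here: signed
#' distances to the SVM separating hyperplane). Ties in the scores are
#' handled by evaluating only at distinct thresholds.
#'
#' @param scores Numeric score per sample (larger = more positive).
#' @param positives Logical per sample; at least one must be `TRUE`.
#' @return Fraction in `(0, 1]`.
#' @export
auprc <- function(scores, positives) {
  positives <- as.logical(positives)
  if (length(scores) != length(positives)) stopf("length mismatch")
  npos <- sum(positives)
  if (npos == 0) stopf("AUPRC undefined without positive samples")
  o <- order(-scores)
  s <- scores[o]
  tp <- cumsum(positives[o])
  last <- cumsum(rle(s)$lengths)       # last index at each distinct score
  prec <- tp[last] / last
  rec <- tp[last] / npos
  sum(diff(c(0, rec)) * prec)
}

#' Mean one-vs-rest AUPRC for a multi-class fold
#'
#' For the three-subtype task the AUPRC is computed per class from the
#' distances to the hyperplane separating that class from the rest, then
#' averaged over the classes within the same test fold.
#'
#' @param decision Matrix of signed hyperplane distances, one column per
#'   class (column names = class labels).
#' @param labels True class per row.
#' @return Mean of the per-class AUPRCs.
#' @export
auprc_multiclass <- function(decision, labels) {
  classes <- colnames(decision)
  mean(vapply(classes, function(cl) {
    auprc(decision[, cl], labels == cl)
  }, numeric(1)))
}

# --- linear SVM helpers (e1071 / libsvm backend) ---------------------------

# Fit one-vs-rest linear SVMs; for 2 classes a single machine oriented
# toward the second factor level. Returns an object with predict() giving
# class labels and a decision matrix (one column per class).
fit_linear_svm <- function(x, y, cost) {
  lv <- levels(y)
  if (length(lv) < 2L) stopf("training fold has a single class")
  if (length(lv) == 2L) {
    m <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    structure(list(kind = "binary", model = m, levels = lv),
              class = "linear_svm_set")
  } else {
    models <- lapply(lv, function(cl) {
      yb <- factor(ifelse(y == cl, "pos", "rest"), levels = c("rest", "pos"))
      e1071::svm(x, yb, kernel = "linear", cost = cost, scale = FALSE)
    })
    names(models) <- lv
    structure(list(kind = "ovr", models = models, levels = lv),
              class = "linear_svm_set")
  }
}

# decision values oriented so larger = `positive` label
oriented_decision <- function(model, x, positive) {
  pr <- predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first == positive) dv[, 1] else -dv[, 1]
}

predict_svm_set <- function(fit, x) {
  lv <- fit$levels
  if (fit$kind == "binary") {
    dv <- oriented_decision(fit$model, x, lv[2])
    decision <- cbind(-dv, dv)
    colnames(decision) <- lv
    pred <- factor(ifelse(dv > 0, lv[2], lv[1]), levels = lv)
  } else {
    decision <- vapply(lv, function(cl) {
      oriented_decision(fit$models[[cl]], x, "pos")
    }, numeric(nrow(x)))
    colnames(decision) <- lv
    pred <- factor(lv[max.col(decision, ties.method = "first")],
                   levels = lv)
  }
  list(pred = pred, decision = decision)
}

# Extract primal weights/offsets of every machine in a fit (fingerprint for
# leakage tests).
svm_weights <- function(fit) {
  one <- function(m) {
    w <- t(m$coefs) %*% m$SV
    list(w = as.numeric(w), rho = m$rho)
  }
  if (fit$kind == "binary") list(one(fit$model)) else lapply(fit$models, one)
}

#' Patient-grouped nested cross-validation with a linear SVM
#'
#' For every outer fold: features are screened to the `m_select` highest
#' F-statistics computed on the training side only; an inner,
#' patient-grouped cross-validation picks the SVM cost from `cost_grid` by
#' balanced accuracy; the final linear SVM is trained on the full outer
#' training set (all augmented samples of its patients, when present); and
#' the held-out patients are scored using only their `is_center` sample —
#' the crop with neither shift, rotation nor flip — yielding the fold's
#' balanced accuracy and AUPRC (mean one-vs-rest for 3 or more classes,
#' positive-class for 2). Feature standardization (z-score) is fit on the
#' training side when `standardize = TRUE`. Nothing about the test patients
#' influences screening, scaling, cost choice or the trained machine.
#'
#' @param x Feature matrix: one row per sample (a patient contributes 72
#'   augmented rows for CNN features, or a single row for age/radiomic
#'   features).
#' @param y Class label per row (constant within patient). For binary
#'   tasks, the second factor level is the AUPRC-positive class.
#' @param patient Patient id per row.
#' @param plan A [make_folds()] plan over the patients.
#' @param is_center Logical per row marking the centre sample used for
#'   scoring; default: every row (the single-vector-per-patient case).
#' @param m_select Number of features kept by the F-statistic screen
#'   (default 4000; `Inf` disables screening).
#' @param cost_grid SVM cost candidates (default `10^(-3:3)`).
#' @param inner_k Inner folds for cost tuning (default 5).
#' @param standardize Z-score features on the training side (default
#'   `TRUE`).
#' @param seed Seed for the inner fold plans.
#' @param return_models Also return the per-fold fitted machines.
#' @return A `classification_result`: `per_fold` (list with
#'   `balanced_accuracy`, `auprc`, `chosen_cost`, `selected_features`,
#'   `weights`), `fold_accuracy`, `mean_accuracy`, `ci95_halfwidth`,
#'   `mean_auprc`.
#' @export
nested_cv <- function(x, y, patient, plan, is_center = NULL,
                      m_select = 4000L, cost_grid = 10^seq(-3, 3),
                      inner_k = 5L, standardize = TRUE, seed = 1L,
                      return_models = FALSE) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stopf("feature matrix must be finite")
  y <- factor(y)
  patient <- as.character(patient)
  if (is.null(is_center)) is_center <- rep(TRUE, nrow(x))
  stopifnot(nrow(x) == length(y), nrow(x) == length(patient),
            nrow(x) == length(is_center))
  all_pat <- unique(patient)
  pat_label <- y[match(all_pat, patient)]

  per_fold <- vector("list", plan$k)
  for (i in seq_len(plan$k)) {
    test_pat <- plan$folds[[i]]
    tr <- !(patient %in% test_pat)
    te <- (patient %in% test_pat) & is_center
    if (!any(te)) stopf("fold %d has no centre test samples", i)
    ytr <- droplevels(y[tr])
    if (nlevels(ytr) < 2L) stopf("fold %d training side has a single class", i)
    if (nlevels(ytr) < nlevels(y)) {
      stopf("fold %d training side is missing a class", i)
    }

    sel <- if (is.finite(m_select) && ncol(x) > m_select) {
      top_m_indices(f_statistic(x[tr, , drop = FALSE], y[tr]), m_select)
    } else {
      seq_len(ncol(x))
    }
    xs <- x[, sel, drop = FALSE]
    if (standardize) {
      mu <- colMeans(xs[tr, , drop = FALSE])
      sdv <- apply(xs[tr, , drop = FALSE], 2, sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      xs <- sweep(sweep(xs, 2, mu), 2, sdv, `/`)
    }

    # inner patient-grouped cost tuning
    chosen_cost <- cost_grid[1]
    if (length(cost_grid) > 1L) {
      tr_pat <- all_pat[!(all_pat %in% test_pat)]
      tr_lab <- as.character(pat_label[match(tr_pat, all_pat)])
      ki <- min(inner_k, length(tr_pat))
      inner_plan <- suppressWarnings(
        make_folds(tr_pat, tr_lab, k = ki,
                   seed = derive_seed(seed, i), stratified = TRUE)
      )
      score <- vapply(cost_grid, function(cost) {
        accs <- c()
        for (j in seq_len(inner_plan$k)) {
          ip <- inner_plan$folds[[j]]
          itr <- tr & !(patient %in% ip)
          ite <- (patient %in% ip) & is_center
          yitr <- y[itr]
          if (length(unique(yitr)) < nlevels(y)) next
          fit <- fit_linear_svm(xs[itr, , drop = FALSE],
                                factor(yitr, levels = levels(y)), cost)
          pr <- predict_svm_set(fit, xs[ite, , drop = FALSE])
          cm <- table(factor(y[ite], levels = levels(y)), pr$pred)
          ok <- rowSums(cm) > 0
          accs <- c(accs, balanced_accuracy(cm[ok, , drop = FALSE]))
        }
        if (length(accs)) mean(accs) else NA_real_
      }, numeric(1))
      if (all(is.na(score))) {
        chosen_cost <- cost_grid[1]
      } else {
        chosen_cost <- cost_grid[which.max(score)]  # ties: smallest cost
      }
    }

    fit <- fit_linear_svm(xs[tr, , drop = FALSE],
                          factor(y[tr], levels = levels(y)), chosen_cost)
    pr <- predict_svm_set(fit, xs[te, , drop = FALSE])
    yte <- factor(y[te], levels = levels(y))
    cm <- table(yte, pr$pred)
    ok <- rowSums(cm) > 0
    acc <- balanced_accuracy(cm[ok, , drop = FALSE])
    fold_auprc <- if (nlevels(y) == 2L) {
      auprc(pr$decision[, levels(y)[2]], yte == levels(y)[2])
    } else {
      present <- levels(y)[levels(y) %in% yte]
      auprc_multiclass(pr$decision[, present, drop = FALSE],
                       as.character(yte))
    }
    per_fold[[i]] <- list(
      balanced_accuracy = acc,
      auprc = fold_auprc,
      chosen_cost = chosen_cost,
      selected_features = sel,
      weights = svm_weights(fit),
      model = if (return_models) fit else NULL
    )
  }
  fold_acc <- vapply(per_fold, `[[`, 0, "balanced_accuracy")
  structure(
    list(
      per_fold = per_fold,
      fold_accuracy = fold_acc,
      mean_accuracy = mean(fold_acc),
      ci95_halfwidth = ci95(fold_acc),
      mean_auprc = mean(vapply(per_fold, `[[`, 0, "auprc"))
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result: %d folds, balanced accuracy %.3f +/- %.3f (95%% CI), AUPRC %.3f>\n",
    length(x$per_fold), x$mean_accuracy, x$ci95_halfwidth, x$mean_auprc
  ))
  invisible(x)
}

#' Shuffled-label chance runs
#'
#' Estimates the chance level of a classification task by rerunning the
#' nested cross-validation on the age feature with genotype labels permuted
#' at the patient level. The default single permutation matches the
#' emulated study's design (a 10-fold chance run compared to the real run
#' by a one-tailed Welch test); more repeats give a fuller permutation
#' distribution.
#'
#' @param x Feature matrix (typically the one-column age matrix), one row
#'   per patient.
#' @param y Label per row.
#' @param patient Patient id per row.
#' @param plan A [make_folds()] plan; its `k`, `seed` and stratification
#'   setting are mirrored. By default each permutation gets folds
#'   re-stratified on its permuted labels, exactly as the real analysis
#'   stratifies on the true labels — otherwise the permuted classes are
#'   unbalanced across the reused folds and the chance estimate is biased
#'   downward.
#' @param n_repeats Number of label permutations (default 1).
#' @param seed Seed for the permutations.
#' @param restratify Rebuild the fold plan from each permutation's labels
#'   (default `TRUE`); `FALSE` reuses `plan` unchanged.
#' @param ... Passed on to [nested_cv()].
#' @return List with `accuracy` (`n_repeats x k` matrix of fold balanced
#'   accuracies), `fold_accuracy` (first repeat, for Welch tests) and
#'   `mean_accuracy`.
#' @export
chance_run <- function(x, y, patient, plan, n_repeats = 1L, seed = 1L,
                       restratify = TRUE, ...) {
  x <- as.matrix(x)
  y <- factor(y)
  patient <- as.character(patient)
  pats <- unique(patient)
  y_pat <- y[match(pats, patient)]
  perms <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) sample(as.character(y_pat)))
  })
  acc <- matrix(NA_real_, n_repeats, plan$k)
  for (r in seq_len(n_repeats)) {
    y_new <- factor(perms[[r]][match(patient, pats)], levels = levels(y))
    plan_r <- if (restratify) {
      suppressWarnings(make_folds(pats, perms[[r]], k = plan$k,
                                  seed = derive_seed(seed, 500L + r),
                                  stratified = plan$stratified))
    } else {
      plan
    }
    cv <- nested_cv(x, y_new, patient, plan_r,
                    seed = derive_seed(seed, r), ...)
    acc[r, ] <- cv$fold_accuracy
  }
  list(accuracy = acc, fold_accuracy = acc[1, ], mean_accuracy = mean(acc))
}
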