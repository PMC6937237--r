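#' Fixed random subsample of a layer's neurons
#'
#' Selects `k` distinct neuron indices from one layer of an extractor.
#' The sample is drawn once per analysis and reused for every patient and
#' every member of a train/test split, so feature columns line up across
#' the whole experiment.
#'
#' @param layer Layer name.
#' @param layer_dim Number of neurons in that layer.
#' @param k Number of neurons to keep (default 1000, the per-layer sample
#'   size of the emulated study).
#' @param seed Integer seed.
#' @return A `neuron_sample`: list with `layer`, `indices` (sorted, unique)
#'   and `seed`.
#' @export
neuron_sample <- function(layer, layer_dim, k = 1000L, seed = 1L) {
  if (k > layer_dim) {
    stopf("cannot sample %d neurons from layer '%s' with %d neurons",
          k, layer, layer_dim)
  }
  idx <- with_seed(seed, sort(sample.int(layer_dim, k)))
  structure(list(layer = layer, indices = idx, seed = as.integer(seed)),
            class = "neuron_sample")
}

#' Concatenate subsampled CNN features across the four MR sequences
#'
#' Applies the neuron subsample to each sequence's activation vector and
#' concatenates in the fixed order T1W, T2W, GdT1W, FLAIR, so `k` neurons
#' per sequence yield a `4k`-long feature vector (4000 at the default
#' sample size).
#'
#' @param per_sequence Named list with numeric activation vectors for
#'   `"T1W"`, `"T2W"`, `"GdT1W"`, `"FLAIR"`.
#' @param sample A [neuron_sample()].
#' @param sequences Sequences to concatenate, in order (default: the four
#'   acquired sequences; a single name gives the single-sequence variant of
#'   length `k`).
#' @return Named numeric vector of length
#'   `length(sequences) * length(sample$indices)`.
#' @export
concat_sequences <- function(per_sequence, sample,
                             sequences = MR_SEQUENCES) {
  stopifnot(inherits(sample, "neuron_sample"))
  missing_seq <- setdiff(sequences, names(per_sequence))
  if (length(missing_seq)) {
    stopf("missing sequence(s): %s", paste(missing_seq, collapse = ", "))
  }
  out <- unlist(lapply(sequences, function(s) {
    v <- per_sequence[[s]]
    if (length(v) < max(sample$indices)) {
      stopf("activation vector for %s shorter than sampled indices", s)
    }
    setNames(v[sample$indices],
             sprintf("%s_%s_n%04d", s, sample$layer, sample$indices))
  }))
  out
}

# Cut + normalize + augment the lesion (or normal) image of one patient for
# one sequence; returns list of augmented_image objects.
patient_sequence_images <- function(patient, sequence, voi,
                                    augmented = TRUE, size = 243L) {
  vol <- normalize_volume(patient$volumes[[sequence]],
                          norm_params("cnn_percentile"))
  li <- cut_lesion_image(vol, voi, size)
  if (augmented) augment(li) else list(center_crop(li))
}

#' CNN texture-feature matrix for a cohort
#'
#' For every patient: each sequence is percentile-normalized, the lesion
#' image is cut from the centre slice of the VOI, augmented (72 crops /
#' rotations / flips) or reduced to the centre crop only, passed through
#' the extractor, subsampled to `k` neurons of `layer`, and concatenated
#' across the four sequences. Rows are samples (72 per patient when
#' augmented, 1 otherwise); the neuron sample is drawn once and shared by
#' all patients.
#'
#' @param cohort A `glioma_cohort`.
#' @param extractor A [feature_extractor].
#' @param layer Layer to read out (default `"conv5"`, the layer selected by
#'   the lesion-vs-normal experiment in the emulated study).
#' @param k Neurons per sequence (default 1000).
#' @param seed Seed for the neuron sample.
#' @param augmented Use all 72 augmented samples per patient (`TRUE`) or
#'   the centre crop only.
#' @param voi_role `"lesion"` (default) or `"normal"` (mirrored VOI;
#'   patients without one are skipped).
#' @return List with `x` (feature matrix), `patient` (row patient ids),
#'   `is_center` (logical per row) and `sample` (the [neuron_sample()]).
#' @export
cohort_cnn_features <- function(cohort, extractor, layer = "conv5",
                                k = 1000L, seed = 1L, augmented = TRUE,
                                voi_role = c("lesion", "normal")) {
  voi_role <- match.arg(voi_role)
  samp <- neuron_sample(layer, extractor$layer_dims[[layer]], k, seed)
  rows <- list()
  pat <- character(0)
  ctr <- logical(0)
  for (p in cohort) {
    voi <- if (voi_role == "lesion") p$lesion_voi else p$normal_voi
    if (is.null(voi)) next
    imgs <- lapply(MR_SEQUENCES, function(s) {
      patient_sequence_images(p, s, voi, augmented)
    })
    names(imgs) <- MR_SEQUENCES
    n_samp <- length(imgs[[1]])
    acts <- lapply(imgs, function(il) {
      lapply(il, function(im) extract_features(im, extractor, layer))
    })
    for (j in seq_len(n_samp)) {
      rows[[length(rows) + 1L]] <- concat_sequences(
        lapply(acts, `[[`, j), samp
      )
      pat <- c(pat, p$patient_id)
      ctr <- c(ctr, imgs[[1]][[j]]$is_center)
    }
  }
  x <- do.call(rbind, rows)
  list(x = x, patient = pat, is_center = ctr, sample = samp)
}

#' Select the extractor layer by the lesion-vs-normal experiment
#'
#' For each exposed layer, classifies lesion versus mirrored normal-tissue
#' images (patients with a valid normal VOI only) with the full
#' patient-grouped nested cross-validation on subsampled, concatenated
#' features, and returns the layer with the highest mean balanced accuracy
#' together with the per-layer accuracies and 95% confidence intervals.
#'
#' @param cohort A `glioma_cohort`.
#' @param extractor A [feature_extractor].
#' @param layers Layers to evaluate (default: all exposed layers).
#' @param k Neurons per sequence.
#' @param seed Seed for folds and neuron samples.
#' @param outer_k,inner_k,cost_grid,m_select Passed to [nested_cv()].
#' @param augmented Use all 72 augmented samples per patient in training.
#' @return List with `best_layer` and `summary` (data frame: layer, mean
#'   accuracy, 95% CI half-width, mean AUPRC).
#' @export
select_layer <- function(cohort, extractor, layers = extractor$layer_names,
                         k = 1000L, seed = 1L, outer_k = 10L, inner_k = 5L,
                         cost_grid = 10^seq(-3, 3), m_select = Inf,
                         augmented = FALSE) {
  keep <- !vapply(cohort, `[[`, FALSE, "excluded_from_normal_analysis")
  sub <- structure(cohort[keep], class = "glioma_cohort")
  if (length(sub) < 2L) stopf("need at least 2 patients with normal VOIs")
  res <- lapply(layers, function(ly) {
    les <- cohort_cnn_features(sub, extractor, ly, k,
                               seed = derive_seed(seed, 1L),
                               augmented = augmented, voi_role = "lesion")
    nor <- cohort_cnn_features(sub, extractor, ly, k,
                               seed = derive_seed(seed, 1L),
                               augmented = augmented, voi_role = "normal")
    x <- rbind(les$x, nor$x)
    y <- factor(rep(c("lesion", "normal"), c(nrow(les$x), nrow(nor$x))),
                levels = c("normal", "lesion"))
    patient <- c(les$patient, nor$patient)
    is_center <- c(les$is_center, nor$is_center)
    # both classes of one patient stay in the same fold
    plan <- make_folds(unique(patient),
                       rep("both", length(unique(patient))),
                       k = outer_k, seed = derive_seed(seed, 2L),
                       stratified = FALSE)
    cv <- nested_cv(x, y, patient, plan, is_center = is_center,
                    m_select = m_select, cost_grid = cost_grid,
                    inner_k = inner_k, seed = derive_seed(seed, 3L))
    c(accuracy = cv$mean_accuracy, ci = cv$ci95_halfwidth,
      auprc = mean(vapply(cv$per_fold, `[[`, 0, "auprc")))
  })
  summary <- data.frame(
    layer = layers,
    accuracy = vapply(res, `[[`, 0, "accuracy"),
    ci95 = vapply(res, `[[`, 0, "ci"),
    auprc = vapply(res, `[[`, 0, "auprc"),
    stringsAsFactors = FALSE
  )
  list(best_layer = summary$layer[which.max(summary$accuracy)],
       summary = summary)
}
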