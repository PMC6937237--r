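#' Task specifications for genotype classification
#'
#' Three tasks mirror the emulated study: the three molecular subtypes
#' (all patients), IDH mutation vs wild type (all patients), and pTERT
#' mutation vs wild type within the IDH-mutant patients only. For binary
#' tasks the mutation-positive class is the last factor level (the
#' AUPRC-positive class).
#'
#' @param name `"three_subtype"`, `"idh"` or `"ptert_in_idh_mut"`.
#' @return A `task_spec`: list with `name`, `filter(genotype)` and
#'   `label(genotype)` returning a factor.
#' @export
task_spec <- function(name = c("three_subtype", "idh", "ptert_in_idh_mut")) {
  name <- match.arg(name)
  spec <- switch(name,
    three_subtype = list(
      filter = function(genotype) rep(TRUE, length(genotype)),
      label = function(genotype) factor(genotype, levels = GENOTYPES)
    ),
    idh = list(
      filter = function(genotype) rep(TRUE, length(genotype)),
      label = function(genotype) {
        factor(ifelse(genotype == "IDHwt", "IDHwt", "IDHmut"),
               levels = c("IDHwt", "IDHmut"))
      }
    ),
    ptert_in_idh_mut = list(
      filter = function(genotype) genotype != "IDHwt",
      label = function(genotype) {
        factor(ifelse(genotype == "IDHmut_pTERTmut", "pTERTmut", "pTERTwt"),
               levels = c("pTERTwt", "pTERTmut"))
      }
    )
  )
  structure(c(list(name = name), spec), class = "task_spec")
}

#' Configuration for a full experiment run
#'
#' Bundles the cohort source and every tunable of the pipeline. The
#' defaults are the emulated study's settings (1000 neurons per sequence
#' from conv5, F-screen to 4000 features, 10 outer / 5 inner folds, cost
#' grid 10^-3..10^3, training on all 72 augmented samples); pass smaller
#' values for desk-scale runs.
#'
#' @param cohort A `glioma_cohort`, a [synthetic_config()], or a directory
#'   written by [write_cohort()].
#' @param extractor A [feature_extractor]; default
#'   `random_conv_extractor()`.
#' @param layer Extractor layer for the texture features.
#' @param k_neurons Neurons sampled per sequence.
#' @param m_select F-statistic screen size.
#' @param cost_grid SVM cost candidates.
#' @param outer_k,inner_k Fold counts.
#' @param augmented_training Train on all augmented samples (`TRUE`) or on
#'   centre crops only.
#' @param feature_sets Subset of `c("age", "radiomics", "cnn", "all")`.
#' @param tasks Subset of
#'   `c("three_subtype", "idh", "ptert_in_idh_mut")`.
#' @param chance_repeats Label permutations per task for the chance run.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort = synthetic_config(),
                              extractor = random_conv_extractor(),
                              layer = "conv5",
                              k_neurons = 1000L,
                              m_select = 4000L,
                              cost_grid = 10^seq(-3, 3),
                              outer_k = 10L,
                              inner_k = 5L,
                              augmented_training = TRUE,
                              feature_sets = c("age", "radiomics", "cnn",
                                               "all"),
                              tasks = c("three_subtype", "idh",
                                        "ptert_in_idh_mut"),
                              chance_repeats = 1L,
                              seed = 1L) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  tasks <- match.arg(tasks, several.ok = TRUE)
  structure(
    list(cohort = cohort, extractor = extractor, layer = layer,
         k_neurons = as.integer(k_neurons), m_select = m_select,
         cost_grid = cost_grid, outer_k = as.integer(outer_k),
         inner_k = as.integer(inner_k),
         augmented_training = isTRUE(augmented_training),
         feature_sets = feature_sets, tasks = tasks,
         chance_repeats = as.integer(chance_repeats),
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

validate_cohort <- function(cohort) {
  for (p in cohort) {
    missing_seq <- setdiff(MR_SEQUENCES, names(p$volumes))
    if (length(missing_seq)) {
      stopf("patient %s is missing sequence(s): %s", p$patient_id,
            paste(missing_seq, collapse = ", "))
    }
    if (is.null(p$lesion_voi) || !any(p$lesion_voi$mask)) {
      stopf("patient %s has no lesion VOI", p$patient_id)
    }
  }
  invisible(TRUE)
}

#' Run the full experiment grid
#'
#' Executes preprocessing, feature extraction, classification and
#' statistics for every task x feature-set cell: the fold plan is built
#' once per task and shared by the feature sets; each cell runs the
#' patient-grouped nested cross-validation; the chance level comes from a
#' shuffled-label run on the age feature; and the statistics layer
#' compares fold accuracies across feature sets (one-way ANOVA with
#' Tukey-Kramer post hoc, Bonferroni-corrected over the tasks) and against
#' chance (one-tailed Welch). Deterministic under the config seed.
#'
#' @param config An [experiment_config()].
#' @return An `experiment_report`: `per_task` (each with `feature_sets`
#'   mapping to [nested_cv()] results, `chance`, `anova`,
#'   `welch_vs_chance`), and `provenance`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- config$cohort
  if (inherits(cohort, "synthetic_config")) cohort <- generate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)

  clin <- clinical_table(cohort)
  age_x <- matrix(clin$age, ncol = 1,
                  dimnames = list(clin$patient_id, "age"))
  need_rad <- any(c("radiomics", "all") %in% config$feature_sets)
  need_cnn <- any(c("cnn", "all") %in% config$feature_sets)
  rad_x <- if (need_rad) cohort_radiomic_features(cohort) else NULL
  cnn <- if (need_cnn) {
    cohort_cnn_features(cohort, config$extractor, config$layer,
                        k = config$k_neurons,
                        seed = derive_seed(config$seed, 1L),
                        augmented = config$augmented_training)
  } else {
    NULL
  }

  per_task <- lapply(seq_along(config$tasks), function(ti) {
    task <- task_spec(config$tasks[ti])
    keep <- task$filter(clin$genotype)
    pats <- clin$patient_id[keep]
    labels <- task$label(clin$genotype[keep])
    plan <- make_folds(pats, as.character(labels), k = config$outer_k,
                       seed = derive_seed(config$seed, 10L + ti))

    cells <- lapply(config$feature_sets, function(fs) {
      if (fs %in% c("age", "radiomics")) {
        x <- switch(fs, age = age_x[keep, , drop = FALSE],
                    radiomics = rad_x[keep, , drop = FALSE])
        nested_cv(x, labels, pats, plan,
                  m_select = config$m_select,
                  cost_grid = config$cost_grid, inner_k = config$inner_k,
                  seed = derive_seed(config$seed, 100L + ti))
      } else {
        in_task <- cnn$patient %in% pats
        xc <- cnn$x[in_task, , drop = FALSE]
        pr <- cnn$patient[in_task]
        ic <- cnn$is_center[in_task]
        yr <- labels[match(pr, pats)]
        if (fs == "all") {
          xc <- cbind(
            xc,
            age_x[match(pr, clin$patient_id), , drop = FALSE],
            rad_x[match(pr, clin$patient_id), , drop = FALSE]
          )
        }
        nested_cv(xc, yr, pr, plan,
                  m_select = config$m_select,
                  cost_grid = config$cost_grid, inner_k = config$inner_k,
                  seed = derive_seed(config$seed, 100L + ti))
      }
    })
    names(cells) <- config$feature_sets

    chance <- chance_run(age_x[keep, , drop = FALSE], labels, pats, plan,
                         n_repeats = config$chance_repeats,
                         seed = derive_seed(config$seed, 200L + ti),
                         cost_grid = config$cost_grid,
                         inner_k = config$inner_k)
    welch <- lapply(cells, function(cv) {
      welch_one_tailed(cv$fold_accuracy, chance$fold_accuracy)
    })
    anova <- if (length(cells) >= 2L) {
      anova_tukey(lapply(cells, `[[`, "fold_accuracy"),
                  bonferroni_m = length(config$tasks))
    } else {
      NULL
    }
    list(task = task$name, plan = plan, feature_sets = cells,
         chance = chance, welch_vs_chance = welch, anova = anova)
  })
  names(per_task) <- config$tasks

  structure(
    list(
      per_task = per_task,
      provenance = list(
        seed = config$seed,
        n_patients = length(cohort),
        feature_sets = config$feature_sets,
        tasks = config$tasks,
        layer = config$layer,
        k_neurons = config$k_neurons,
        augmented_training = config$augmented_training,
        package_version = as.character(utils::packageVersion("rgpipe")),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  for (tk in names(x$per_task)) {
    t <- x$per_task[[tk]]
    cat(sprintf("  %s (chance %.3f):\n", tk, t$chance$mean_accuracy))
    for (fs in names(t$feature_sets)) {
      cv <- t$feature_sets[[fs]]
      cat(sprintf(
        "    %-9s accuracy %.3f +/- %.3f  AUPRC %.3f  (Welch vs chance p = %.3g)\n",
        fs, cv$mean_accuracy, cv$ci95_halfwidth, cv$mean_auprc,
        t$welch_vs_chance[[fs]]$p_value
      ))
    }
    if (!is.null(t$anova)) {
      cat(sprintf("    ANOVA F(%d,%d) = %.4f, Bonferroni p = %.4g\n",
                  t$anova$df[1], t$anova$df[2], t$anova$statistic,
                  t$anova$adjusted_p))
    }
  }
  invisible(x)
}
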