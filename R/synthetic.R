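#' Configuration for the synthetic glioma cohort generator
#'
#' Defines the study conditions the generator emulates: a three-class
#' molecular-subtype cohort (IDH wild type, IDH+pTERT co-mutated, IDH mutant
#' with pTERT wild type) with class-dependent lesion texture and age. The
#' defaults mirror the published cohort composition (164 patients split
#' 56/54/54, about 55% of scans at 1.5 T) on a desk-scale 64x64x40 grid at
#' 2 mm isotropic spacing.
#'
#' @param n_patients Number of patients.
#' @param class_proportions Length-3 probabilities for the subtypes
#'   (IDHwt, IDHmut_pTERTmut, IDHmut_pTERTwt); must sum to 1.
#' @param texture_effect Non-negative scalar scaling the between-class
#'   separation of the lesion texture parameters (mean offset, contrast and
#'   correlation length of the Gaussian random field). 0 gives the null
#'   cohort in which lesion appearance carries no class information.
#' @param age_effect Between-class mean-age shift in years (IDH wild type is
#'   shifted older, IDH mutant/pTERT wild type younger). 0 removes the age
#'   signal.
#' @param volume_shape Grid size (3 positive integers).
#' @param voxel_spacing Voxel pitch in mm (length 3).
#' @param lesion_radius_range Range (mm) for the lesion ellipsoid radius.
#' @param noise_sd SD of additive Gaussian acquisition noise.
#' @param scanner_class_assoc If `TRUE`, field strength is made dependent on
#'   subtype (for exercising the chi-squared homogeneity test); the default
#'   `FALSE` assigns scanners independently so the cohort test is null.
#' @param seed Integer seed; the same config yields a bitwise-identical
#'   cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 164,
                             class_proportions = c(56, 54, 54) / 164,
                             texture_effect = 1,
                             age_effect = 8,
                             volume_shape = c(64, 64, 40),
                             voxel_spacing = c(2, 2, 2),
                             lesion_radius_range = c(8, 20),
                             noise_sd = 0.05,
                             scanner_class_assoc = FALSE,
                             seed = 1L) {
  if (n_patients < 0) stopf("`n_patients` must be >= 0")
  if (length(class_proportions) != 3L ||
      abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0)) {
    stopf("`class_proportions` must be 3 non-negative values summing to 1")
  }
  if (texture_effect < 0 || age_effect < 0) {
    stopf("effect sizes must be non-negative")
  }
  if (length(volume_shape) != 3L || any(volume_shape < 8)) {
    stopf("`volume_shape` must be 3 integers >= 8")
  }
  if (any(voxel_spacing <= 0)) stopf("`voxel_spacing` must be positive")
  if (length(lesion_radius_range) != 2L ||
      lesion_radius_range[1] > lesion_radius_range[2] ||
      lesion_radius_range[1] <= 0) {
    stopf("`lesion_radius_range` must be an increasing positive pair (mm)")
  }
  if (noise_sd < 0) stopf("`noise_sd` must be non-negative")
  structure(
    list(
      n_patients = as.integer(n_patients),
      class_proportions = as.numeric(class_proportions),
      texture_effect = texture_effect,
      age_effect = age_effect,
      volume_shape = as.integer(volume_shape),
      voxel_spacing = as.numeric(voxel_spacing),
      lesion_radius_range = as.numeric(lesion_radius_range),
      noise_sd = noise_sd,
      scanner_class_assoc = isTRUE(scanner_class_assoc),
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Class direction of the texture/age shifts: IDH wild type up, co-mutated
# neutral, IDH mutant / pTERT wild type down.
class_delta <- c(IDHwt = 1, IDHmut_pTERTmut = 0, IDHmut_pTERTwt = -1)

# Per-sequence background level and lesion signal gain (arbitrary units):
# lesions are hyperintense on T2W/FLAIR, hypointense on T1W, mildly
# enhancing on GdT1W.
seq_background <- c(T1W = 1.00, T2W = 0.80, GdT1W = 1.05, FLAIR = 0.90)
seq_lesion_gain <- c(T1W = -0.30, T2W = 0.55, GdT1W = -0.15, FLAIR = 0.45)

# Separable Gaussian smoothing of a 3-D array (zero-padded borders).
gauss_smooth3d <- function(arr, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- array(0, dim(arr))
    n <- dim(arr)[ax]
    for (t in -r:r) {
      src <- seq_len(n) + t
      ok <- src >= 1 & src <= n
      idx_dst <- which(ok)
      idx_src <- src[ok]
      w <- k[t + r + 1]
      if (ax == 1) {
        out[idx_dst, , ] <- out[idx_dst, , ] + w * arr[idx_src, , ]
      } else if (ax == 2) {
        out[, idx_dst, ] <- out[, idx_dst, ] + w * arr[, idx_src, ]
      } else {
        out[, , idx_dst] <- out[, , idx_dst] + w * arr[, , idx_src]
      }
    }
    arr <- out
  }
  arr
}

ellipsoid_mask <- function(shape, center, semi_axes_vox) {
  dx <- (seq_len(shape[1]) - center[1]) / semi_axes_vox[1]
  dy <- (seq_len(shape[2]) - center[2]) / semi_axes_vox[2]
  dz <- (seq_len(shape[3]) - center[3]) / semi_axes_vox[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
}

#' Generate a synthetic multi-sequence MR cohort
#'
#' Draws a cohort of patients with genotype-dependent lesion texture and age.
#' Each patient gets four pre-aligned sequences (T1W, T2W, GdT1W, FLAIR): a
#' brain ellipsoid background plus an ellipsoidal lesion whose interior is a
#' smoothed Gaussian random field. The field's mean offset, contrast and
#' correlation length shift with the molecular subtype in proportion to
#' `texture_effect`; patient age shifts by `age_effect`. The lesion VOI is
#' mirrored across the sagittal midline to define a normal-tissue control
#' VOI; patients whose mirrored VOI overlaps the lesion are flagged
#' `excluded_from_normal_analysis` (as happened for 37/164 patients in the
#' emulated study).
#'
#' @param config A [synthetic_config()].
#' @return A list of patient records (class `glioma_cohort`). Each record
#'   has `patient_id`, `age`, `genotype`, `scanner`, `volumes` (named list
#'   of [mr_volume()]), `lesion_voi`, `normal_voi` (or `NULL`) and
#'   `excluded_from_normal_analysis`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  if (n == 0L) {
    return(structure(list(), class = "glioma_cohort", config = config))
  }
  shape <- config$volume_shape
  sp <- config$voxel_spacing
  eff <- config$texture_effect

  cohort <- with_seed(config$seed, {
    genotypes <- sample(GENOTYPES, n, replace = TRUE,
                        prob = config$class_proportions)
    lapply(seq_len(n), function(i) {
      g <- genotypes[i]
      d <- class_delta[[g]]
      age <- min(90, max(20, rnorm(1, 45 + d * config$age_effect, 10)))
      p15 <- if (config$scanner_class_assoc) {
        c(IDHwt = 0.8, IDHmut_pTERTmut = 0.5, IDHmut_pTERTwt = 0.25)[[g]]
      } else {
        90 / 164
      }
      scanner <- if (runif(1) < p15) "1.5T" else "3.0T"

      # lesion geometry: one hemisphere (axis 1 = left-right), with the
      # offset distribution allowing occasional midline crossing
      side <- sample(c(-1, 1), 1)
      midline <- (shape[1] + 1) / 2
      cx <- midline + side * runif(1, 0.05, 0.35) * shape[1]
      cy <- runif(1, 0.3, 0.7) * shape[2]
      cz <- runif(1, 0.3, 0.7) * shape[3]
      r_mm <- runif(1, config$lesion_radius_range[1],
                    config$lesion_radius_range[2])
      semi_mm <- r_mm * runif(3, 0.75, 1.25)
      lesion <- ellipsoid_mask(shape, c(cx, cy, cz), semi_mm / sp)
      if (!any(lesion)) {  # degenerate draw: force a single voxel
        lesion[round(cx), round(cy), round(cz)] <- TRUE
      }

      # brain background ellipsoid
      brain <- ellipsoid_mask(shape, (shape + 1) / 2, 0.45 * shape)

      # class-dependent Gaussian random field inside the lesion
      contrast <- 0.25 * exp(0.4 * d * eff)
      corr_mm <- 3 * exp(0.25 * d * eff)
      mu <- 0.12 * d * eff
      wn <- array(rnorm(prod(shape)), shape)
      field <- gauss_smooth3d(wn, corr_mm / sp)
      fsd <- sd(field[lesion])
      if (!is.finite(fsd) || fsd == 0) fsd <- 1
      field <- mu + contrast * (field - mean(field[lesion])) / fsd

      volumes <- lapply(MR_SEQUENCES, function(s) {
        v <- seq_background[[s]] * brain
        v[lesion] <- seq_background[[s]] +
          seq_lesion_gain[[s]] * (0.6 + field[lesion])
        if (config$noise_sd > 0) {
          v <- v + array(rnorm(prod(shape), 0, config$noise_sd), shape)
        }
        mr_volume(v, sp, s)
      })
      names(volumes) <- MR_SEQUENCES

      lesion_voi <- voi_mask(lesion, "lesion")
      normal_voi <- mirror_voi(lesion_voi, midline_axis = 1L)
      list(
        patient_id = sprintf("P%03d", i),
        age = age,
        genotype = g,
        scanner = scanner,
        volumes = volumes,
        lesion_voi = lesion_voi,
        normal_voi = normal_voi,
        excluded_from_normal_analysis = is.null(normal_voi)
      )
    })
  })
  structure(cohort, class = "glioma_cohort", config = config)
}

#' @export
print.glioma_cohort <- function(x, ...) {
  cat(sprintf(
    "<glioma_cohort: %d patients (%s); %d excluded from normal-tissue analysis>\n",
    length(x),
    paste(sprintf("%s=%d", GENOTYPES, tabulate(
      factor(vapply(x, `[[`, "", "genotype"), GENOTYPES), 3L
    )), collapse = ", "),
    sum(vapply(x, `[[`, FALSE, "excluded_from_normal_analysis"))
  ))
  invisible(x)
}

#' Mirror a lesion VOI across the sagittal midline
#'
#' Reflects the lesion mask in the sagittal plane to define a contralateral
#' normal-tissue VOI. If the mirrored mask overlaps the lesion by one or
#' more voxels (a midline-crossing lesion), no control region can be
#' allocated and `NULL` is returned; callers flag such patients as excluded
#' from the lesion-vs-normal analysis.
#'
#' @param lesion_voi A non-empty [voi_mask()] with role `"lesion"`.
#' @param midline_axis Axis index (1-3) perpendicular to the mirror plane;
#'   axis 1 is the left-right direction.
#' @return A [voi_mask()] with role `"normal"`, or `NULL` on overlap.
#' @export
mirror_voi <- function(lesion_voi, midline_axis = 1L) {
  stopifnot(inherits(lesion_voi, "voi_mask"))
  if (!any(lesion_voi$mask)) stopf("lesion VOI must be non-empty")
  if (!midline_axis %in% 1:3) stopf("`midline_axis` must be 1, 2 or 3")
  m <- lesion_voi$mask
  n <- dim(m)[midline_axis]
  rev_idx <- rev(seq_len(n))
  mirrored <- switch(midline_axis,
    m[rev_idx, , , drop = FALSE],
    m[, rev_idx, , drop = FALSE],
    m[, , rev_idx, drop = FALSE]
  )
  if (any(mirrored & m)) {
    return(NULL)
  }
  voi_mask(mirrored, "normal")
}

#' Clinical table of a cohort
#'
#' @param cohort A `glioma_cohort`.
#' @return A data frame with patient_id, age, genotype, scanner and the
#'   normal-tissue exclusion flag.
#' @export
clinical_table <- function(cohort) {
  data.frame(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    age = vapply(cohort, `[[`, 0, "age"),
    genotype = vapply(cohort, `[[`, "", "genotype"),
    scanner = vapply(cohort, `[[`, "", "scanner"),
    excluded_from_normal_analysis =
      vapply(cohort, `[[`, FALSE, "excluded_from_normal_analysis"),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort to disk as NIfTI volumes plus a clinical CSV
#'
#' Layout: `dir/<patient>/<sequence>.nii.gz`, `dir/<patient>/lesion.nii.gz`
#' (and `normal.nii.gz` when present), `dir/clinical.csv`, `dir/config.json`.
#'
#' @param cohort A `glioma_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    pdir <- file.path(dir, p$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    for (s in names(p$volumes)) {
      v <- p$volumes[[s]]
      RNifti::writeNifti(
        RNifti::asNifti(v$intensities, pixdim = v$spacing),
        file.path(pdir, paste0(s, ".nii.gz"))
      )
    }
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(p$lesion_voi$mask),
                            dim(p$lesion_voi$mask)),
                      pixdim = p$volumes[[1]]$spacing),
      file.path(pdir, "lesion.nii.gz")
    )
    if (!is.null(p$normal_voi)) {
      RNifti::writeNifti(
        RNifti::asNifti(array(as.integer(p$normal_voi$mask),
                              dim(p$normal_voi$mask)),
                        pixdim = p$volumes[[1]]$spacing),
        file.path(pdir, "normal.nii.gz")
      )
    }
  }
  utils::write.csv(clinical_table(cohort), file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `glioma_cohort`.
#' @export
read_cohort <- function(dir) {
  clin <- utils::read.csv(file.path(dir, "clinical.csv"),
                          stringsAsFactors = FALSE)
  cohort <- lapply(seq_len(nrow(clin)), function(i) {
    pdir <- file.path(dir, clin$patient_id[i])
    volumes <- lapply(MR_SEQUENCES, function(s) {
      img <- RNifti::readNifti(file.path(pdir, paste0(s, ".nii.gz")))
      mr_volume(array(as.numeric(img), dim(img)),
                RNifti::pixdim(img)[1:3], s)
    })
    names(volumes) <- MR_SEQUENCES
    read_mask <- function(path, role) {
      if (!file.exists(path)) return(NULL)
      img <- RNifti::readNifti(path)
      voi_mask(array(as.numeric(img) > 0.5, dim(img)), role)
    }
    list(
      patient_id = clin$patient_id[i],
      age = clin$age[i],
      genotype = clin$genotype[i],
      scanner = clin$scanner[i],
      volumes = volumes,
      lesion_voi = read_mask(file.path(pdir, "lesion.nii.gz"), "lesion"),
      normal_voi = read_mask(file.path(pdir, "normal.nii.gz"), "normal"),
      excluded_from_normal_analysis = clin$excluded_from_normal_analysis[i]
    )
  })
  structure(cohort, class = "glioma_cohort")
}
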