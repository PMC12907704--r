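#' Specification for synthetic methylation fixtures
#'
#' Describes a synthetic 450K-style dataset: a probe universe with planted
#' tumor-specific probes (differential between tumor tissue and both healthy
#' populations), planted tissue-specific probes (differential between normal
#' tissue and plasma, to exercise the tumor-specificity exclusion rule) and
#' background probes shared across populations. Per-probe values are drawn
#' from Beta distributions in a mean/concentration parameterization
#' (`shape1 = mean * kappa`, `shape2 = (1 - mean) * kappa`), which respects
#' the `[0, 1]` support of beta-values.
#'
#' @param n_probes total number of probes. Default 2000.
#' @param n_dmp planted tumor-specific probes. Default 550.
#' @param n_tissue_dmp planted tissue-specific probes. Default 100.
#' @param n_tumor_tissue,n_normal_tissue,n_plasma group sizes. Defaults
#'   50, 50, 60.
#' @param mean_hyper,mean_hypo,mean_mid stratum means for hypermethylated,
#'   hypomethylated and intermediate levels. Defaults 0.8, 0.2, 0.5.
#' @param background_range background probes draw their (shared) per-probe
#'   mean uniformly from this interval. Default `c(0.3, 0.7)`.
#' @param kappa Beta concentration; larger is less noisy. Default 50.
#' @param seed integer seed. Default 1.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_probes = 2000, n_dmp = 550, n_tissue_dmp = 100,
                         n_tumor_tissue = 50, n_normal_tissue = 50,
                         n_plasma = 60, mean_hyper = 0.8, mean_hypo = 0.2,
                         mean_mid = 0.5, background_range = c(0.3, 0.7),
                         kappa = 50, seed = 1) {
  if (n_dmp + n_tissue_dmp > n_probes) {
    stop2("n_dmp + n_tissue_dmp must not exceed n_probes")
  }
  means <- c(mean_hyper, mean_hypo, mean_mid, background_range)
  if (any(means <= 0 | means >= 1)) stop2("all stratum means must lie strictly in (0, 1)")
  if (kappa <= 0) stop2("kappa must be positive")
  structure(as.list(environment()), class = "fixture_spec")
}

# Beta draws in mean/concentration form; mu may be a length-n_probes vector,
# recycled down the rows of an n_probes x n_samples matrix.
rbeta_mk <- function(n_probes, n_samples, mu, kappa) {
  matrix(stats::rbeta(n_probes * n_samples, mu * kappa, (1 - mu) * kappa),
         nrow = n_probes, ncol = n_samples)
}

# planted probe means: half hyper-in-tumor, half hypo-in-tumor
planted_means <- function(n, hyper, hypo) {
  up <- rep_len(c(TRUE, FALSE), n)
  list(tumor = ifelse(up, hyper, hypo), other = ifelse(up, hypo, hyper))
}

#' Generate a two-population reference fixture
#'
#' Builds a tumor-tissue / healthy-plasma reference matrix with `tumor_*` and
#' `plasma_*` columns, the true per-probe population means, and the planted
#' differential probe list. Background probes share a per-probe mean drawn
#' from `background_range`; planted probes alternate hyper/hypo in tumor at
#' the configured stratum means (|mean difference| = `mean_hyper - mean_hypo`).
#'
#' @param spec a [fixture_spec()]; `n_tumor_tissue` and `n_plasma` set the
#'   column counts.
#' @return A list with `ref` (probe-by-sample beta matrix), `means`
#'   (probes-by-2 matrix, columns `healthy`, `tumor`) and `dmp` (planted probe
#'   IDs).
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    probes <- sprintf("cg%06d", seq_len(spec$n_probes))
    dmp_idx <- sort(sample.int(spec$n_probes, spec$n_dmp))
    base <- stats::runif(spec$n_probes, spec$background_range[1], spec$background_range[2])
    mu_t <- base
    mu_h <- base
    if (spec$n_dmp > 0) {
      pm <- planted_means(spec$n_dmp, spec$mean_hyper, spec$mean_hypo)
      mu_t[dmp_idx] <- pm$tumor
      mu_h[dmp_idx] <- pm$other
    }
    tumor <- rbeta_mk(spec$n_probes, spec$n_tumor_tissue, mu_t, spec$kappa)
    plasma <- rbeta_mk(spec$n_probes, spec$n_plasma, mu_h, spec$kappa)
    ref <- cbind(tumor, plasma)
    dimnames(ref) <- list(probes,
                          c(paste0("tumor_", seq_len(spec$n_tumor_tissue)),
                            paste0("plasma_", seq_len(spec$n_plasma))))
    means <- cbind(healthy = mu_h, tumor = mu_t)
    rownames(means) <- probes
    list(ref = ref, means = means, dmp = probes[dmp_idx])
  })
}

#' Generate a three-group tissue fixture for DMP analysis
#'
#' Builds tumor-tissue, adjacent-normal-tissue and healthy-plasma groups.
#' Planted tumor-specific probes are differential in tumor only (both healthy
#' populations share the opposite stratum mean). Planted tissue-specific
#' probes form a gradient (plasma at one extreme, normal tissue intermediate,
#' tumor at the other extreme), so they pass the tumor-versus-normal contrast
#' but must be removed by the tissue-specificity exclusion rule.
#'
#' @param spec a [fixture_spec()].
#' @return A list with `beta` (probe-by-sample matrix), `design`
#'   (a [group_design()] over groups `tumor_tissue`, `normal_tissue`,
#'   `normal_plasma`), `tumor_dmp` and `tissue_dmp` (planted probe IDs).
#' @export
make_tissue_groups <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    probes <- sprintf("cg%06d", seq_len(spec$n_probes))
    planted <- sample.int(spec$n_probes, spec$n_dmp + spec$n_tissue_dmp)
    dmp_idx <- sort(planted[seq_len(spec$n_dmp)])
    tis_idx <- sort(planted[spec$n_dmp + seq_len(spec$n_tissue_dmp)])
    base <- stats::runif(spec$n_probes, spec$background_range[1], spec$background_range[2])
    mu <- cbind(tumor_tissue = base, normal_tissue = base, normal_plasma = base)
    if (spec$n_dmp > 0) {
      pm <- planted_means(spec$n_dmp, spec$mean_hyper, spec$mean_hypo)
      mu[dmp_idx, "tumor_tissue"] <- pm$tumor
      mu[dmp_idx, "normal_tissue"] <- pm$other
      mu[dmp_idx, "normal_plasma"] <- pm$other
    }
    if (spec$n_tissue_dmp > 0) {
      pm <- planted_means(spec$n_tissue_dmp, spec$mean_hyper, spec$mean_hypo)
      mu[tis_idx, "tumor_tissue"] <- pm$tumor
      mu[tis_idx, "normal_tissue"] <- spec$mean_mid
      mu[tis_idx, "normal_plasma"] <- pm$other
    }
    sizes <- c(tumor_tissue = spec$n_tumor_tissue,
               normal_tissue = spec$n_normal_tissue,
               normal_plasma = spec$n_plasma)
    beta <- cbind(rbeta_mk(spec$n_probes, sizes[1], mu[, 1], spec$kappa),
                  rbeta_mk(spec$n_probes, sizes[2], mu[, 2], spec$kappa),
                  rbeta_mk(spec$n_probes, sizes[3], mu[, 3], spec$kappa))
    sample_ids <- unlist(lapply(names(sizes), function(g) paste0(g, "_", seq_len(sizes[g]))))
    dimnames(beta) <- list(probes, sample_ids)
    design <- group_design(sample_ids, rep(names(sizes), times = sizes))
    list(beta = beta, design = design,
         tumor_dmp = probes[dmp_idx], tissue_dmp = probes[tis_idx])
  })
}

#' Specification for a synthetic longitudinal cfDNA cohort
#'
#' Emulates a treatment-monitoring arm: each patient has a baseline tumor
#' fraction and follow-up visits whose fraction follows the arm's dynamics —
#' `sensitive` patients drop to a small multiple of the previous visit
#' (`follow-up = previous * U(mult)`), `resistant` patients random-walk with
#' small Gaussian steps truncated to `[0, 1]`.
#'
#' @param n_patients patients in the arm. Default 12.
#' @param timepoints visits per patient (baseline = timepoint 0). Default 2.
#' @param arm `"sensitive"` or `"resistant"`.
#' @param baseline_range uniform range of baseline tumor fractions.
#'   Default `c(0.2, 0.6)`.
#' @param sensitive_mult follow-up multiplier range for the sensitive arm.
#'   Default `c(0, 0.3)`.
#' @param resistant_sd Gaussian step SD for the resistant arm. Default 0.05.
#' @param kappa Beta concentration of per-probe measurement noise. Default 200.
#' @param seed integer seed. Default 1.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 12, timepoints = 2,
                        arm = c("sensitive", "resistant"),
                        baseline_range = c(0.2, 0.6),
                        sensitive_mult = c(0, 0.3), resistant_sd = 0.05,
                        kappa = 200, seed = 1) {
  arm <- match.arg(arm)
  if (n_patients < 1 || timepoints < 1) stop2("need >= 1 patient and timepoint")
  if (any(baseline_range < 0 | baseline_range > 1)) {
    stop2("baseline_range must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a longitudinal cfDNA cohort with known tumor fractions
#'
#' Each sample is a convex blend of the healthy and tumor population mean
#' profiles at the patient's true tumor fraction for that visit, observed with
#' Beta-distributed per-probe noise of concentration `kappa`.
#'
#' @param atlas_means probes-by-2 matrix of population mean beta-values
#'   (columns `healthy`, `tumor`), e.g. [make_reference()]'s `means`.
#' @param spec a [cohort_spec()].
#' @return A list with `beta` (probe-by-sample matrix), `meta` (metadata
#'   data.frame: sample_id, patient_id, phenotype, timepoint) and `truth`
#'   (data.frame with the true tumor fraction per sample).
#' @export
make_cohort <- function(atlas_means, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.matrix(atlas_means) || ncol(atlas_means) != 2 || is.null(rownames(atlas_means))) {
    stop2("atlas_means must be a probes-by-2 matrix with probe rownames")
  }
  with_seed(spec$seed, {
    n_samp <- spec$n_patients * spec$timepoints
    frac <- matrix(0, spec$n_patients, spec$timepoints)
    frac[, 1] <- stats::runif(spec$n_patients, spec$baseline_range[1], spec$baseline_range[2])
    if (spec$timepoints > 1) {
      for (tp in 2:spec$timepoints) {
        frac[, tp] <- if (spec$arm == "sensitive") {
          frac[, tp - 1] * stats::runif(spec$n_patients, spec$sensitive_mult[1],
                                        spec$sensitive_mult[2])
        } else {
          pmin(pmax(frac[, tp - 1] + stats::rnorm(spec$n_patients, 0, spec$resistant_sd), 0), 1)
        }
      }
    }
    meta <- data.frame(
      sample_id = sprintf("%s_p%02d_t%d", spec$arm,
                          rep(seq_len(spec$n_patients), each = spec$timepoints),
                          rep(seq_len(spec$timepoints) - 1L, spec$n_patients)),
      patient_id = sprintf("p%02d", rep(seq_len(spec$n_patients), each = spec$timepoints)),
      phenotype = spec$arm,
      timepoint = rep(seq_len(spec$timepoints) - 1L, spec$n_patients),
      stringsAsFactors = FALSE
    )
    truth <- cbind(meta[, c("sample_id", "patient_id", "timepoint")],
                   tumor_fraction = as.vector(t(frac)))
    n_probes <- nrow(atlas_means)
    beta <- matrix(0, n_probes, n_samp,
                   dimnames = list(rownames(atlas_means), meta$sample_id))
    for (i in seq_len(n_samp)) {
      f <- truth$tumor_fraction[i]
      mu <- pmin(pmax((1 - f) * atlas_means[, 1] + f * atlas_means[, 2], 1e-3), 1 - 1e-3)
      beta[, i] <- stats::rbeta(n_probes, mu * spec$kappa, (1 - mu) * spec$kappa)
    }
    list(beta = beta, meta = meta, truth = truth)
  })
}
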