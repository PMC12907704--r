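#' Build a cell-means group design
#'
#' Constructs a no-intercept indicator design (`~ 0 + group`) for a set of
#' samples, the parameterization under which each fitted coefficient is a
#' group mean.
#'
#' @param sample_ids character vector of sample IDs, in matrix column order.
#' @param group_labels factor or character vector of group memberships, one
#'   per sample (e.g. `tumor_tissue`, `normal_tissue`, `normal_plasma`).
#' @return An object of class `group_design`: a list with `sample_ids`,
#'   `groups` (factor) and `design` (sample-by-group indicator matrix).
#' @export
group_design <- function(sample_ids, group_labels) {
  if (length(sample_ids) != length(group_labels)) {
    stop2("sample_ids and group_labels must have the same length")
  }
  if (anyDuplicated(sample_ids)) stop2("sample_ids must be unique")
  groups <- if (is.factor(group_labels)) droplevels(group_labels) else factor(group_labels)
  if (anyNA(groups)) stop2("every sample needs a group label")
  if (nlevels(groups) < 2) stop2("at least two groups are required")
  design <- stats::model.matrix(~ 0 + groups)
  colnames(design) <- levels(groups)
  rownames(design) <- sample_ids
  structure(list(sample_ids = sample_ids, groups = groups, design = design),
            class = "group_design")
}

#' Fit per-probe group-means linear models to an M-value matrix
#'
#' Under the cell-means design each coefficient is the within-group mean
#' M-value; the residual variance is the pooled within-group variance with
#' `n - k` degrees of freedom. This is the per-probe linear-model fit that
#' feeds the moderated-t machinery.
#'
#' @param m probe-by-sample M-value matrix.
#' @param design a [group_design()].
#' @return An object of class `probe_fit`: list with `coef` (probe-by-group
#'   means), `sigma2` (residual variances), `df_resid`, `xtx_inv`
#'   (the `(X'X)^-1` of the design) and `design`.
#' @export
fit_group_means <- function(m, design) {
  check_matrix(m, "m")
  if (!inherits(design, "group_design")) stop2("design must be a group_design")
  if (ncol(m) != nrow(design$design) ||
      !identical(colnames(m), design$sample_ids)) {
    stop2("matrix columns and design sample_ids must match exactly")
  }
  if (anyNA(m)) stop2("M-value matrix must be complete (see drop_incomplete_probes)")
  X <- design$design
  n <- nrow(X)
  k <- ncol(X)
  if (any(colSums(X) < 1)) stop2("every group needs at least one sample")
  df_resid <- n - k
  if (df_resid < 1) stop2("residual degrees of freedom must be >= 1 (need n_samples > n_groups)")
  group_n <- colSums(X)
  coef <- (m %*% X) %*% diag(1 / group_n, k)  # per-group means
  colnames(coef) <- colnames(X)
  fitted <- coef %*% t(X)
  resid <- m - fitted
  sigma2 <- rowSums(resid^2) / df_resid
  structure(list(coef = coef, sigma2 = sigma2, df_resid = df_resid,
                 xtx_inv = diag(1 / group_n, k, k), design = design),
            class = "probe_fit")
}

#' Estimate the empirical-Bayes variance prior
#'
#' Fits a scaled inverse-chi-square prior to the per-probe residual variances
#' by method of moments on the log scale: the mean and variance of
#' `log(sigma2)` are matched to their digamma/trigamma expressions under the
#' hierarchical model. When the observed spread of log-variances does not
#' exceed the sampling spread `trigamma(df/2)`, the prior degrees of freedom
#' are infinite and all variances shrink to a common value.
#'
#' @param fit a [fit_group_means()] result.
#' @param min_var variances at or below this are excluded from estimation
#'   (they carry no log-scale information). Default 1e-12.
#' @return A list of class `moderated_prior` with `d0` (prior degrees of
#'   freedom, possibly `Inf`) and `s0_sq` (prior variance).
#' @export
estimate_prior <- function(fit, min_var = 1e-12) {
  if (!inherits(fit, "probe_fit")) stop2("fit must be a probe_fit")
  s2 <- fit$sigma2[fit$sigma2 > min_var]
  if (length(s2) < 2) {
    stop2("need >= 2 probes with positive residual variance; input looks degenerate")
  }
  df <- fit$df_resid
  # e_g = log s2_g - E[log s2 | sigma2] offset; under the model
  # E[e] = log s0^2 + digamma(d0/2) - log(d0/2), Var[e] = trigamma(d0/2) + trigamma(df/2)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  e_mean <- mean(e)
  e_var <- sum((e - e_mean)^2) / (length(e) - 1)
  excess <- e_var - trigamma(df / 2)
  if (excess <= 0) {
    # no excess spread: infinite prior df, pooled mean variance as the scale
    d0 <- Inf
    s0_sq <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(e_mean + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderated_prior")
}

# Newton solve of trigamma(y) = x; monotone decreasing, standard iteration.
trigamma_inverse <- function(x) {
  if (x <= 0) stop2("trigamma_inverse needs a positive argument")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Moderated-t contrast test
#'
#' Tests a linear contrast of group means for every probe using the
#' empirical-Bayes posterior variance
#' `s2_post = (d0 * s0_sq + df * sigma2) / (d0 + df)`. The moderated t is the
#' contrast estimate divided by `sqrt(s2_post * c' (X'X)^-1 c)` and is referred
#' to a t distribution with `d0 + df` degrees of freedom (normal when
#' `d0 = Inf`; with `d0 = 0` the ordinary linear-model t is recovered).
#' P-values are two-sided and adjusted by Benjamini-Hochberg across probes.
#'
#' @param fit a [fit_group_means()] result.
#' @param prior a [estimate_prior()] result, or a list with `d0` and `s0_sq`
#'   (`d0 = 0` gives the unmoderated test).
#' @param contrast numeric vector of group weights, one per design group
#'   (named vectors are matched to group names).
#' @return A data.frame of class `dmp_result` with columns `probe_id`,
#'   `logFC` (contrast estimate on the M scale), `t`, `P.Value`, `adj.P.Val`,
#'   in the input probe order.
#' @export
moderated_contrast <- function(fit, prior, contrast) {
  if (!inherits(fit, "probe_fit")) stop2("fit must be a probe_fit")
  groups <- colnames(fit$coef)
  if (!is.null(names(contrast))) {
    if (!setequal(names(contrast), groups)) {
      stop2("named contrast must cover exactly the design groups: ",
            paste(groups, collapse = ", "))
    }
    contrast <- contrast[groups]
  }
  if (length(contrast) != length(groups)) {
    stop2("contrast length (", length(contrast), ") must equal the number of groups (",
          length(groups), ")")
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  if (is.null(d0) || is.null(s0_sq) || d0 < 0 || (d0 > 0 && s0_sq <= 0)) {
    stop2("prior must supply d0 >= 0 and s0_sq > 0")
  }
  df <- fit$df_resid
  logFC <- drop(fit$coef %*% contrast)
  su <- sqrt(drop(t(contrast) %*% fit$xtx_inv %*% contrast))  # stdev unscaled
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(logFC))
  } else {
    (d0 * s0_sq + df * fit$sigma2) / (d0 + df)
  }
  denom <- su * sqrt(s2_post)
  t_mod <- ifelse(denom > 0, logFC / denom,
                  ifelse(logFC == 0, 0, sign(logFC) * Inf))
  df_total <- d0 + df
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }
  p[t_mod == 0] <- 1
  out <- data.frame(probe_id = rownames(fit$coef), logFC = logFC, t = t_mod,
                    P.Value = p, adj.P.Val = bh_adjust(p),
                    row.names = rownames(fit$coef), stringsAsFactors = FALSE)
  class(out) <- c("dmp_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p)) stop2("p must be numeric without missing values")
  if (length(p) && (min(p) < 0 || max(p) > 1)) stop2("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select tumor-specific differentially methylated positions
#'
#' Applies the two-contrast tumor-specificity rule: a probe is kept when it is
#' strongly differential between tumor and adjacent normal tissue
#' (`adj.P.Val < p_tumor` and `|logFC| > lfc_tumor`) but *not* tissue-specific,
#' i.e. the tissue-versus-plasma contrast is non-significant or negligible
#' (`adj.P.Val >= p_tissue` or `|logFC| < lfc_tissue`). Survivors are ranked by
#' decreasing tumor `|logFC|` (probe ID breaks ties for reproducibility) and
#' capped at `top_n`.
#'
#' @param tumor [moderated_contrast()] table for the tumor-vs-normal-tissue
#'   contrast.
#' @param tissue [moderated_contrast()] table for the
#'   normal-tissue-vs-plasma contrast, over the same probe universe.
#' @param p_tumor,lfc_tumor significance and effect-size thresholds for the
#'   tumor contrast. Defaults 0.01 and 0.2.
#' @param p_tissue,lfc_tissue non-specificity thresholds for the tissue
#'   contrast. Defaults 0.05 and 0.01.
#' @param top_n maximum number of probes returned. Default 500.
#' @return Character vector of selected probe IDs, ranked by `|logFC|`
#'   descending; empty (with a warning) when nothing passes.
#' @export
select_tumor_specific <- function(tumor, tissue, p_tumor = 0.01,
                                  lfc_tumor = 0.2, p_tissue = 0.05,
                                  lfc_tissue = 0.01, top_n = 500) {
  if (!setequal(tumor$probe_id, tissue$probe_id)) {
    stop2("tumor and tissue tables must share the same probe universe")
  }
  tissue <- tissue[match(tumor$probe_id, tissue$probe_id), ]
  not_tissue_specific <- tissue$adj.P.Val >= p_tissue | abs(tissue$logFC) < lfc_tissue
  pass <- tumor$adj.P.Val < p_tumor & abs(tumor$logFC) > lfc_tumor & not_tissue_specific
  hits <- tumor[pass, , drop = FALSE]
  if (nrow(hits) == 0) {
    warn2("no probe passes the tumor-specific DMP filters")
    return(character(0))
  }
  ord <- order(-abs(hits$logFC), hits$probe_id)
  utils::head(hits$probe_id[ord], top_n)
}

#' Write a DMP result table
#'
#' @param dmp a [moderated_contrast()] result.
#' @param path output path (tab-separated, columns probe_id, logFC, t,
#'   P.Value, adj.P.Val).
#' @return `path`, invisibly.
#' @export
write_dmp_table <- function(dmp, path) {
  utils::write.table(dmp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
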