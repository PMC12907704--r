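#' Compute methylation beta-values from raw array intensities
#'
#' Converts methylated/unmethylated signal intensities to beta-values with the
#' standard regularizing offset: `beta = M / (M + U + offset)`. The offset
#' (typically 100) stabilizes the ratio when both channel intensities are low.
#'
#' @param meth probe-by-sample matrix of methylated intensities (non-negative).
#' @param unmeth probe-by-sample matrix of unmethylated intensities, aligned
#'   with `meth`.
#' @param offset non-negative scalar added to the denominator. Default 100.
#' @return A probe-by-sample beta-value matrix; all entries lie in `[0, 1)`
#'   whenever `offset > 0`.
#' @examples
#' m <- matrix(c(100, 900), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
#' u <- matrix(0, 2, 1, dimnames = dimnames(m))
#' beta_from_signals(m, u) # 0.5, 0.9
#' @export
beta_from_signals <- function(meth, unmeth, offset = 100) {
  check_matrix(meth, "meth")
  check_matrix(unmeth, "unmeth")
  check_aligned(meth, unmeth, "meth", "unmeth")
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0) {
    stop2("offset must be a non-negative scalar")
  }
  if (anyNA(meth) || anyNA(unmeth)) stop2("intensities must not be missing")
  if (min(meth) < 0 || min(unmeth) < 0) stop2("intensities must be >= 0")
  denom <- meth + unmeth + offset
  if (any(denom == 0)) {
    stop2("offset = 0 with zero total intensity gives an undefined beta-value")
  }
  meth / denom
}

#' Drop probes with unreliable detection p-values
#'
#' A probe whose detection p-value is at or above `threshold` in *any* sample
#' cannot be distinguished from background noise in that sample and is removed
#' from the whole matrix. The comparison is inclusive (`p >= threshold`
#' discards). Probe order among survivors is preserved and values are untouched.
#'
#' @param beta probe-by-sample beta-value matrix.
#' @param detect_p probe-by-sample detection p-value matrix aligned with `beta`.
#' @param threshold detection p-value cutoff. Default 0.01.
#' @return `beta` restricted to probes detected (`p < threshold`) in every
#'   sample.
#' @export
detection_filter <- function(beta, detect_p, threshold = 0.01) {
  check_matrix(beta, "beta", range = c(0, 1))
  check_matrix(detect_p, "detect_p", range = c(0, 1))
  check_aligned(beta, detect_p, "beta", "detect_p")
  keep <- rowSums(detect_p >= threshold) == 0
  if (!any(keep)) {
    stop2("no probes survive the detection p-value filter at threshold ",
          threshold)
  }
  beta[keep, , drop = FALSE]
}

#' Restrict matrices to probes complete in every matrix
#'
#' Keeps only probes that are present and non-missing in all samples of all
#' supplied matrices, so that downstream analyses see a shared complete probe
#' universe. Probe order follows the first matrix.
#'
#' @param matrices a list of probe-by-sample matrices.
#' @return A list of matrices (same length and names as the input), each
#'   restricted to the common complete probes in the same order.
#' @export
drop_incomplete_probes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1) {
    stop2("matrices must be a non-empty list")
  }
  for (i in seq_along(matrices)) check_matrix(matrices[[i]], paste0("matrices[[", i, "]]"))
  complete <- lapply(matrices, function(x) rownames(x)[rowSums(is.na(x)) == 0])
  keep <- Reduce(intersect, complete)
  if (length(keep) == 0) {
    stop2("empty intersection: no probe is complete in every matrix")
  }
  # preserve the first matrix's probe order
  keep <- rownames(matrices[[1]])[rownames(matrices[[1]]) %in% keep]
  lapply(matrices, function(x) x[keep, , drop = FALSE])
}

#' Transform beta-values to M-values
#'
#' Beta-values are clipped to `[eps, 1 - eps]` and logit-transformed on the
#' log2 scale: `M = log2(beta / (1 - beta))`. M-values are approximately
#' homoscedastic and preferred for differential testing.
#'
#' @param beta probe-by-sample beta-value matrix (values in `[0, 1]`,
#'   missing entries allowed and propagated).
#' @param eps clipping constant in `(0, 0.5)`. Default `1e-6`.
#' @return A probe-by-sample M-value matrix.
#' @examples
#' b <- matrix(c(0.5, 0.8), 2, 1, dimnames = list(c("cg1", "cg2"), "s1"))
#' beta_to_m(b) # 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  check_matrix(beta, "beta", range = c(0, 1))
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 0.5) {
    stop2("eps must lie strictly between 0 and 0.5")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Transform M-values back to beta-values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`. Round-trips
#' [beta_to_m()] to within 1e-9 for beta in `[eps, 1 - eps]`.
#'
#' @param m probe-by-sample M-value matrix.
#' @return A probe-by-sample beta-value matrix in `(0, 1)`.
#' @export
m_to_beta <- function(m) {
  check_matrix(m, "m")
  # plogis on the natural-log scale == 2^m/(1+2^m) on the log2 scale
  stats::plogis(m * log(2))
}

#' Read a probe-by-sample matrix from a tab-separated file
#'
#' Expects probe IDs in the first column and sample IDs in the header row.
#' Both common header dialects are accepted: a header with a leading label for
#' the ID column, or (as `write.table(..., row.names = TRUE)` produces) a
#' header with one field per sample only. Cells equal to `NA` or empty are
#' read as missing.
#'
#' @param path path to a tab-separated text file.
#' @return A numeric probe-by-sample matrix with probe rownames and sample
#'   colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2) stop2("matrix file needs a header and at least one probe row: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  width <- length(rows[[1]])
  bad <- which(vapply(rows, length, 1L) != width)
  if (length(bad)) {
    stop2("ragged row at line ", bad[1] + 1L, " of ", path,
          ": expected ", width, " fields, found ", length(rows[[bad[1]]]))
  }
  if (length(header) == width - 1L) {
    samples <- header
  } else if (length(header) == width) {
    samples <- header[-1]
  } else {
    stop2("header has ", length(header), " fields but data rows have ", width)
  }
  probes <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(probes)) {
    dups <- unique(probes[duplicated(probes)])
    stop2("duplicated probe IDs in ", path, ": ", paste(dups, collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    dups <- unique(samples[duplicated(samples)])
    stop2("duplicated sample IDs in ", path, ": ", paste(dups, collapse = ", "))
  }
  cells <- unlist(lapply(rows, `[`, -1L), use.names = FALSE)
  cells[cells == "" | cells == "NA"] <- NA_character_
  vals <- suppressWarnings(as.numeric(cells))
  bad_cell <- which(is.na(vals) & !is.na(cells))
  if (length(bad_cell)) {
    stop2("non-numeric cell '", cells[bad_cell[1]], "' at line ",
          (bad_cell[1] - 1L) %/% (width - 1L) + 2L, " of ", path)
  }
  x <- matrix(vals, nrow = length(rows), ncol = width - 1L, byrow = TRUE,
              dimnames = list(probes, samples))
  x
}

#' Write a probe-by-sample matrix to a tab-separated file
#'
#' The header carries sample IDs (with a leading `probe_id` field), rows carry
#' probe IDs, missing values are written as `NA`, and values are written at 15
#' significant digits so that [read_matrix()] round-trips them losslessly.
#'
#' @param x numeric probe-by-sample matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  check_matrix(x, "x")
  fmt <- matrix(vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, ""), nrow = nrow(x))
  lines <- c(
    paste(c("probe_id", colnames(x)), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], fmt[i, ]), collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a tab-separated metadata table with columns `sample_id`,
#' `patient_id`, `phenotype` and `timepoint` (numeric visit index).
#'
#' @param path path to a tab-separated metadata file with a header.
#' @return A data.frame with the four required columns; `timepoint` numeric.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(meta)
}

#' Write sample metadata
#'
#' @param meta metadata data.frame (see [read_metadata()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(meta) {
  need <- c("sample_id", "patient_id", "phenotype", "timepoint")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop2("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop2("metadata sample_id values must be unique")
  }
  meta$timepoint <- as.numeric(meta$timepoint)
  if (anyNA(meta$timepoint) || anyNA(meta$patient_id)) {
    stop2("every sample needs a patient_id and a numeric timepoint")
  }
  meta
}
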