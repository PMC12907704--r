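#' Generate simulated cfDNA mixtures with known fraction labels
#'
#' Fabricates a training set for the deconvolution model by blending reference
#' tumor-tissue and healthy-plasma methylation profiles at known proportions.
#' For each simulated sample a fraction pair `(w_healthy, w_tumor)` is drawn —
#' from a Dirichlet distribution with the given prior, or, with
#' `method = "uniform"`, `w_tumor ~ U(0, 1)` — then a per-population profile is
#' built as the per-probe mean of `k` reference columns drawn with replacement
#' from that population, and the sample is the convex blend of the two
#' profiles.
#'
#' Reference columns are assigned to populations by their name prefixes:
#' columns matching `tumor` belong to the tumor-tissue population and columns
#' matching `plasma` to the healthy-plasma population (e.g. `tumor_1 ...
#' tumor_n`, `plasma_1 ... plasma_n`).
#'
#' @param ref probe-by-sample reference beta matrix with `tumor_*` and
#'   `plasma_*` columns and no missing values, or a path to such a file (read
#'   via [read_matrix()]).
#' @param prior length-2 positive Dirichlet prior over (healthy, tumor).
#'   Default `c(0.8, 0.2)`, giving mean tumor fraction 0.2.
#' @param samplenum number of simulated samples. Default 5000.
#' @param random_state integer seed; identical inputs and seed give
#'   bit-identical output. Default 1.
#' @param method `"dirichlet"` (default) or `"uniform"`.
#' @param k number of reference columns averaged per population per sample.
#'   Default 5; `k = 1` blends single donors.
#' @return A list of class `simulated_set` with
#'   `x` (samplenum-by-probes beta matrix), `y` (samplenum-by-2 fraction
#'   labels, column 1 healthy, column 2 tumor), `probe_ids`, `method`, `seed`.
#' @examples
#' ref <- matrix(runif(40), 10, 4,
#'               dimnames = list(paste0("cg", 1:10),
#'                               c("plasma_1", "plasma_2", "tumor_1", "tumor_2")))
#' sim <- generate_simulated_data(ref, samplenum = 3, random_state = 7)
#' rowSums(sim$y) # all 1
#' @export
generate_simulated_data <- function(ref, prior = c(0.8, 0.2), samplenum = 5000,
                                    random_state = 1, method = c("dirichlet", "uniform"),
                                    k = 5) {
  if (is.character(ref) && length(ref) == 1) ref <- read_matrix(ref)
  check_matrix(ref, "ref", range = c(0, 1))
  if (anyNA(ref)) stop2("reference matrix must not contain missing values")
  method <- match.arg(tolower(method[1]), c("dirichlet", "uniform"))
  if (length(prior) != 2 || any(prior <= 0)) {
    stop2("prior must be two positive Dirichlet weights (healthy, tumor)")
  }
  if (samplenum < 1) stop2("samplenum must be >= 1")
  if (k < 1) stop2("k must be >= 1")
  tumor_cols <- grep("tumor", colnames(ref))
  plasma_cols <- grep("plasma", colnames(ref))
  if (length(tumor_cols) == 0 || length(plasma_cols) == 0) {
    stop2("could not identify reference populations: column names must carry ",
          "'tumor' and 'plasma' prefixes (tumor_1 ... tumor_n, plasma_1 ... plasma_n)")
  }

  with_seed(random_state, {
    y <- if (method == "dirichlet") {
      g <- matrix(stats::rgamma(samplenum * 2, shape = rep(prior, each = samplenum)),
                  nrow = samplenum)
      g / rowSums(g)
    } else {
      wt <- stats::runif(samplenum)
      cbind(1 - wt, wt)
    }
    colnames(y) <- c("healthy", "tumor")
    x <- matrix(0, nrow = samplenum, ncol = nrow(ref),
                dimnames = list(paste0("sim_", seq_len(samplenum)), rownames(ref)))
    for (i in seq_len(samplenum)) {
      ph <- rowMeans(ref[, sample(plasma_cols, k, replace = TRUE), drop = FALSE])
      pt <- rowMeans(ref[, sample(tumor_cols, k, replace = TRUE), drop = FALSE])
      x[i, ] <- y[i, 1] * ph + y[i, 2] * pt
    }
    rownames(y) <- rownames(x)
    structure(list(x = x, y = y, probe_ids = rownames(ref),
                   method = method, seed = as.integer(random_state)),
              class = "simulated_set")
  })
}
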