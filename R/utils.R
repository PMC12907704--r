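#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Single-string stop/warning without call noise
stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)

#' Validate a probe-by-sample matrix
#'
#' @param x numeric matrix with probe rownames and sample colnames.
#' @param what label used in error messages.
#' @param range optional length-2 numeric; non-missing values must fall inside.
#' @return `x`, invisibly, after validation.
#' @keywords internal
check_matrix <- function(x, what = "matrix", range = NULL) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop2(what, " must be a numeric matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop2(what, " must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    dups <- unique(rownames(x)[duplicated(rownames(x))])
    stop2(what, " has duplicated probe IDs: ", paste(dups, collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    dups <- unique(colnames(x)[duplicated(colnames(x))])
    stop2(what, " has duplicated sample IDs: ", paste(dups, collapse = ", "))
  }
  if (!is.null(range)) {
    v <- x[!is.na(x)]
    if (length(v) && (min(v) < range[1] || max(v) > range[2])) {
      stop2(what, " has values outside [", range[1], ", ", range[2], "]")
    }
  }
  invisible(x)
}

# check two matrices share exactly the same dimnames
check_aligned <- function(a, b, what_a, what_b) {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    stop2(what_a, " and ", what_b,
          " are not aligned: identical probe and sample indices required")
  }
  invisible(NULL)
}
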