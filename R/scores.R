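#' Score scheme for a categorical margin
#'
#' A score scheme decides how one margin of a stratified contingency table is
#' weighted inside the generalized Cochran-Mantel-Haenszel statistic.  A
#' `"nominal"` scheme treats the levels as unordered and contributes an
#' \eqn{(L-1) \times L} contrast matrix; an `"ordinal"` scheme assigns a
#' strictly increasing numeric score to each level and contributes a single
#' score row.  The combination of the two margins' kinds selects the test:
#' nominal/nominal gives the general association test, one ordinal margin
#' gives a mean-score test, and ordinal/ordinal gives the correlation test.
#'
#' @param kind `"nominal"` or `"ordinal"`.
#' @param scores numeric vector of strictly increasing level scores; required
#'   for (and only allowed with) `kind = "ordinal"`.  Its length must match
#'   the number of levels of the margin it is later applied to.
#' @return An object of class `"score_scheme"`.
#' @examples
#' score_scheme("nominal")
#' score_scheme("ordinal", scores = 0:2)   # additive genotype coding
#' @seealso [score_matrix()], [cmh_test()]
#' @export
score_scheme <- function(kind = c("nominal", "ordinal"), scores = NULL) {
  kind <- match.arg(kind)
  if (kind == "ordinal") {
    if (is.null(scores)) {
      stop("an ordinal score scheme requires 'scores'")
    }
    scores <- as.numeric(scores)
    ## ties are allowed (dominant (0,1,1) / recessive (0,0,1) genotype
    ## codings are mean-score tests with tied scores) but the scores must
    ## be monotone and not all equal
    if (anyNA(scores) || any(!is.finite(scores)) || any(diff(scores) < 0) ||
        length(unique(scores)) < 2L) {
      stop("ordinal scores must be finite, non-decreasing and not all equal")
    }
  } else if (!is.null(scores)) {
    stop("'scores' only applies to ordinal schemes")
  }
  structure(list(kind = kind, scores = scores), class = "score_scheme")
}

#' @export
print.score_scheme <- function(x, ...) {
  if (x$kind == "nominal") {
    cat("Nominal score scheme (identity-contrast weighting)\n")
  } else {
    cat("Ordinal score scheme, scores:", paste(x$scores, collapse = " "), "\n")
  }
  invisible(x)
}

## Accept "nominal"/"ordinal" strings or numeric score vectors where a
## score_scheme is expected, so callers rarely need the constructor.
as_score_scheme <- function(x) {
  if (inherits(x, "score_scheme")) return(x)
  if (is.character(x) && length(x) == 1L) return(score_scheme(x))
  if (is.numeric(x)) return(score_scheme("ordinal", scores = x))
  stop("cannot interpret ", deparse(substitute(x)), " as a score scheme")
}

#' Score matrix for one margin
#'
#' Realizes a [score_scheme()] at a given number of levels.  Nominal schemes
#' yield the \eqn{(L-1) \times L} block `(I | -1)`: row r has 1 in column r,
#' -1 in the last column and 0 elsewhere.  Ordinal schemes yield the
#' \eqn{1 \times L} row of scores.
#'
#' @param n_levels number of levels `L` of the margin (at least 2).
#' @param scheme a [score_scheme()], or `"nominal"`/`"ordinal"` shorthand, or
#'   a numeric score vector (taken as ordinal).
#' @return A numeric matrix with `n_levels` columns.
#' @examples
#' score_matrix(3, "nominal")            # rbind(c(1,0,-1), c(0,1,-1))
#' score_matrix(3, score_scheme("ordinal", 0:2))
#' @export
score_matrix <- function(n_levels, scheme) {
  scheme <- as_score_scheme(scheme)
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L) {
    stop("'n_levels' must be an integer >= 2")
  }
  if (scheme$kind == "nominal") {
    cbind(diag(n_levels - 1L), -1)
  } else {
    if (length(scheme$scores) != n_levels) {
      stop("ordinal scores have length ", length(scheme$scores),
           " but the margin has ", n_levels, " levels")
    }
    matrix(scheme$scores, nrow = 1L)
  }
}
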