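#' The canonical amino acid alphabet
#'
#' The 20 proteinogenic amino acids as IUPAC single-letter codes, in fixed
#' alphabetical order. All profiles, count tables and recipes in this package
#' are indexed by this alphabet; the fixed order makes serialised output
#' deterministic.
#'
#' @return A character vector of length 20.
#' @seealso [aa_essential()]
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Essential amino acids of Drosophila
#'
#' The ten amino acids the fly cannot synthesise de novo. Only essential
#' amino acids can be limiting in a diet comparison; the set can be
#' overridden in [aa_coverage()] for other consumers.
#'
#' @return A character vector of length 10, a subset of [aa_alphabet()].
#' @export
#' @examples
#' aa_essential()
aa_essential <- function() {
  c("F", "H", "I", "K", "L", "M", "R", "T", "V", "W")
}

# Coerce a named numeric vector, or a data frame with `aa` and a value
# column, to a full named vector over the 20-letter alphabet (missing
# letters -> 0). Errors on names outside the alphabet.
aa_vector <- function(x, value_col = "proportion", what = "profile") {
  alpha <- aa_alphabet()
  if (is.data.frame(x)) {
    if (!"aa" %in% names(x)) {
      rlang::abort(sprintf("%s data frame must have an `aa` column", what))
    }
    vc <- if (value_col %in% names(x)) value_col else {
      num <- names(x)[vapply(x, is.numeric, logical(1))]
      if (length(num) == 0) rlang::abort(sprintf("no numeric column found in %s", what))
      num[[1]]
    }
    v <- stats::setNames(x[[vc]], x$aa)
  } else if (is.numeric(x)) {
    v <- x
  } else {
    rlang::abort(sprintf("cannot interpret object of class <%s> as an amino acid %s",
                         paste(class(x), collapse = "/"), what))
  }
  if (is.null(names(v)) || any(names(v) == "")) {
    rlang::abort(sprintf("%s values must be named by amino acid letter", what))
  }
  bad <- setdiff(names(v), alpha)
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown amino acid symbol(s) in %s: %s",
                         what, paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(names(v))) {
    rlang::abort(sprintf("duplicated amino acid symbol in %s", what))
  }
  out <- stats::setNames(numeric(20L), alpha)
  out[names(v)] <- as.numeric(v)
  out
}

#' Construct an amino acid profile
#'
#' An AA profile is a molar-fraction vector over the 20 canonical amino
#' acids: all entries non-negative and summing to one. Input proportions are
#' validated but not rescaled; use [normalize_counts()] to build a profile
#' from raw counts or from a vector that does not yet sum to one.
#'
#' @param x A named numeric vector (names in [aa_alphabet()]; missing
#'   letters are taken as zero), or a data frame with columns `aa` and
#'   `proportion`.
#' @param label Optional free-text label (e.g. `"FLYAA"`).
#' @param tol Tolerance on the sum-to-one check. The default `1e-6`
#'   accommodates profiles that have been through arithmetic; freshly
#'   normalised profiles satisfy `1e-9`.
#' @return A tibble of class `aa_profile` with columns `aa` (ordered as
#'   [aa_alphabet()]) and `proportion`, carrying the label as an attribute.
#' @export
#' @examples
#' aa_profile(c(M = 0.5, W = 0.5), label = "toy")
aa_profile <- function(x, label = NULL, tol = 1e-6) {
  v <- aa_vector(x, "proportion", "profile")
  if (any(v < 0)) {
    rlang::abort("profile proportions must be non-negative")
  }
  s <- sum(v)
  if (abs(s - 1) > tol) {
    rlang::abort(sprintf(
      "profile proportions must sum to 1 (got %.9g); use normalize_counts() to rescale", s))
  }
  new_aa_profile(v, label)
}

new_aa_profile <- function(v, label = NULL) {
  out <- tibble::tibble(aa = aa_alphabet(), proportion = unname(v[aa_alphabet()]))
  class(out) <- c("aa_profile", class(out))
  attr(out, "label") <- label
  out
}

#' @export
print.aa_profile <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("<aa_profile%s>\n", if (is.null(lbl)) "" else paste0(": ", lbl)))
  NextMethod()
}

# keep class/label through dplyr verbs only where we control the call sites;
# generic subsetting returns a plain tibble, which is fine for piping.

#' Profile label
#' @param p An `aa_profile`.
#' @return The label attribute, or `NULL`.
#' @export
profile_label <- function(p) attr(p, "label")

#' Normalise an amino acid count vector to a profile
#'
#' Divides each count by the total so the result sums to one. Counts may be
#' raw residue counts or expression-weighted counts; any non-negative vector
#' with a positive total is acceptable.
#'
#' @param counts Named numeric vector or data frame (`aa`, `count`).
#' @param label Optional label for the resulting profile.
#' @return An [aa_profile()].
#' @export
#' @examples
#' normalize_counts(c(A = 3, G = 1))
normalize_counts <- function(counts, label = NULL) {
  v <- aa_vector(counts, "count", "count vector")
  if (any(v < 0)) rlang::abort("counts must be non-negative")
  total <- sum(v)
  if (total <= 0) {
    rlang::abort(sprintf("cannot normalise an all-zero count vector%s",
                         if (is.null(label)) "" else paste0(" (", label, ")")))
  }
  new_aa_profile(v / total, label)
}

#' Euclidean distance between two amino acid profiles
#'
#' The straight-line distance between two 20-dimensional proportion vectors,
#' the divergence measure used to place observed profiles within the
#' permutation null. For two normalised profiles the distance is bounded by
#' `sqrt(2)`.
#'
#' @param p,q Profiles: `aa_profile` objects, named numeric vectors over the
#'   alphabet, or `aa`/`proportion` data frames. Both must cover the same
#'   20 symbols.
#' @return A non-negative scalar.
#' @export
#' @examples
#' profile_distance(c(A = 1), c(C = 1)) # sqrt(2)
profile_distance <- function(p, q) {
  pv <- aa_vector(p)
  qv <- aa_vector(q)
  sqrt(sum((pv - qv)^2))
}

#' Per-amino-acid median of a set of profiles
#'
#' Computes the median proportion of each amino acid across a collection of
#' profiles. The result is deliberately NOT renormalised: the component-wise
#' median of unit-sum vectors does not itself sum to one, and null-distance
#' calculations measure distances to this raw median.
#'
#' @param profiles A list of profiles, or a numeric matrix with one row per
#'   profile and 20 columns named by [aa_alphabet()].
#' @return A named numeric vector over the alphabet.
#' @export
median_profile <- function(profiles) {
  m <- profile_matrix(profiles)
  if (nrow(m) == 0) rlang::abort("median_profile() needs at least one profile")
  apply(m, 2, stats::median)
}

# list-of-profiles (or matrix) -> n x 20 matrix in alphabet order
profile_matrix <- function(profiles) {
  alpha <- aa_alphabet()
  if (is.matrix(profiles)) {
    if (is.null(colnames(profiles)) || !all(alpha %in% colnames(profiles))) {
      rlang::abort("profile matrix must have the 20 amino acids as column names")
    }
    return(profiles[, alpha, drop = FALSE])
  }
  if (!is.list(profiles)) rlang::abort("expected a list of profiles or a matrix")
  if (length(profiles) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = 20, dimnames = list(NULL, alpha)))
  }
  do.call(rbind, lapply(profiles, aa_vector))
}
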