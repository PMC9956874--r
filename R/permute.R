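#' Permutation null for transcriptome-weighted amino acid profiles
#'
#' Builds a null distribution of expression-weighted amino acid profiles by
#' randomly reassigning the observed expression values among genes (or
#' isoforms), recomputing the weighted profile for each permutation, and
#' measuring each permuted profile's Euclidean distance to the per-amino-acid
#' median of all permuted profiles. An observed profile far out in this
#' distance distribution represents an extreme pattern of amino acid usage
#' relative to biologically realistic reshuffles of the same expression
#' values.
#'
#' At `level = "gene"` every gene keeps its internal isoform-usage weights
#' (each isoform's share of the gene's total FPKM) and the permutation
#' shuffles the gene totals across genes, so all isoforms of a gene move
#' together; for single-isoform genes this reduces to isoform-level
#' permutation. At `level = "isoform"` isoform FPKM values are shuffled
#' directly. Either way the multiset of expression values at the chosen
#' level is preserved exactly — values are reassigned, never resampled.
#'
#' @param counts An `aa_counts` tibble from [count_aa()].
#' @param expression Expression tibble or named vector (see
#'   [weighted_profile()]). Replicate columns are averaged unless
#'   `replicate` selects one.
#' @param n_perm Number of permutations (the reference analysis uses
#'   20,000). Ignored when `exhaustive = TRUE`.
#' @param seed Integer seed; required, so every null is reproducible.
#' @param level `"gene"` (default) or `"isoform"`.
#' @param replicate Optional replicate column name.
#' @param exhaustive Enumerate all `n!` assignments instead of sampling
#'   (only for 8 or fewer entities).
#' @return An object of class `permutation_null`: a list with `distances`
#'   (one per permutation), `median_profile` (named vector, not
#'   renormalised), `profiles` (20 x n_perm matrix of permuted proportions),
#'   `n_perm`, `seed`, `level`, and `observed` (an empty tibble, filled by
#'   [null_percentile()]).
#' @seealso [null_percentile()], [null_summary()]
#' @export
permute_null <- function(counts, expression, n_perm = 20000, seed = NULL,
                         level = c("gene", "isoform"), replicate = NULL,
                         exhaustive = FALSE) {
  level <- match.arg(level)
  if (!exhaustive) {
    if (is.null(seed)) rlang::abort("permute_null() requires an explicit seed")
    if (!is.numeric(n_perm) || n_perm < 1) rlang::abort("n_perm must be at least 1")
    n_perm <- as.integer(n_perm)
  }

  e <- expression_weights(expression, counts$isoform_id, replicate)
  if (all(e == 0)) rlang::abort("all expression values are zero")

  ent <- entity_composition(counts, e, level)
  n_ent <- length(ent$expr)
  if (n_ent < 2) {
    rlang::abort(sprintf("only one %s present; permutation would be the identity", level))
  }

  if (exhaustive) {
    if (n_ent > 8) rlang::abort("exhaustive enumeration is limited to 8 entities")
    perms <- all_permutations(n_ent)
    n_perm <- nrow(perms)
  } else {
    perms <- with_perm_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) sample.int(n_ent), integer(n_ent)))
    })
  }

  # weighted counts for all permutations in one product:
  # comp is n_ent x 20; E_perm is n_ent x n_perm; profiles 20 x n_perm
  e_perm <- matrix(ent$expr[t(perms)], nrow = n_ent)
  raw <- crossprod(ent$comp, e_perm)
  profiles <- sweep(raw, 2, colSums(raw), "/")
  rownames(profiles) <- aa_alphabet()

  med <- apply(profiles, 1, stats::median)
  distances <- sqrt(colSums((profiles - med)^2))

  structure(list(
    n_perm = n_perm,
    seed = if (exhaustive) NA_integer_ else as.integer(seed),
    level = level,
    exhaustive = exhaustive,
    distances = unname(distances),
    median_profile = med,
    profiles = profiles,
    observed = tibble::tibble(label = character(), distance = numeric(),
                              percentile = numeric())
  ), class = "permutation_null")
}

# per-entity composition matrix and expression vector at the chosen level
entity_composition <- function(counts, e, level) {
  m <- count_matrix(counts)
  if (level == "isoform") {
    return(list(comp = m, expr = unname(e)))
  }
  genes <- counts$gene_id
  gtot <- tapply(e, genes, sum)
  w <- e / gtot[genes]
  # genes with zero total expression: equal weights across their isoforms
  zero <- !is.finite(w) | gtot[genes] == 0
  if (any(zero)) {
    gsize <- tapply(rep(1, length(genes)), genes, sum)
    w[zero] <- 1 / gsize[genes[zero]]
  }
  comp <- rowsum(m * as.numeric(w), group = genes)
  gl <- rownames(comp)
  list(comp = comp, expr = as.numeric(gtot[gl]))
}

# all n! permutations as an (n!) x n matrix, n small
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
  unname(out)
}

# run code with a private, restored RNG state
with_perm_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Locate an observed profile within a permutation null
#'
#' Measures the Euclidean distance from an observed profile to the null's
#' median permuted profile and reports the percentage of permuted profiles
#' that lie strictly closer: `100 * #\{d_perm < d_obs\} / n_perm`. Ties count
#' as not exceeded, matching the "more distant than N% of the permutations"
#' reading.
#'
#' @param null A `permutation_null` from [permute_null()].
#' @param profile The observed profile.
#' @param label Label for the profile (defaults to its own label).
#' @return The input `null` with the profile appended to its `observed`
#'   tibble (`label`, `distance`, `percentile`).
#' @export
null_percentile <- function(null, profile, label = NULL) {
  stopifnot(inherits(null, "permutation_null"))
  if (is.null(label)) label <- label_or(profile, sprintf("observed%d", nrow(null$observed) + 1))
  d <- profile_distance(aa_vector(profile), null$median_profile)
  pct <- 100 * sum(null$distances < d) / null$n_perm
  null$observed <- dplyr::bind_rows(
    null$observed,
    tibble::tibble(label = label, distance = d, percentile = pct)
  )
  null
}

#' Per-amino-acid summary of a permutation null
#'
#' Box-plot statistics of the permuted proportions of each amino acid:
#' median, quartiles, and Tukey fences at 1.5 times the interquartile range,
#' with any observed profiles appended in long format for overplotting.
#'
#' @param null A `permutation_null`.
#' @param observed Optional named list of observed profiles to include as
#'   extra long-format rows (`source != "null"`).
#' @return A tibble with one row per amino acid: `aa`, `median`, `q1`, `q3`,
#'   `lower_fence`, `upper_fence`, plus `observed_<label>` columns for each
#'   observed profile.
#' @export
null_summary <- function(null, observed = NULL) {
  stopifnot(inherits(null, "permutation_null"))
  q <- apply(null$profiles, 1, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3, ] - q[1, ]
  out <- tibble::tibble(
    aa = aa_alphabet(),
    median = unname(q[2, ]),
    q1 = unname(q[1, ]),
    q3 = unname(q[3, ]),
    lower_fence = unname(q[1, ] - 1.5 * iqr),
    upper_fence = unname(q[3, ] + 1.5 * iqr)
  )
  if (!is.null(observed)) {
    observed <- name_if_unnamed(observed, "observed")
    for (nm in names(observed)) {
      out[[paste0("observed_", nm)]] <- unname(aa_vector(observed[[nm]]))
    }
  }
  out
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d permutations at %s level%s\n",
              x$n_perm, x$level,
              if (x$exhaustive) " (exhaustive)" else sprintf(" (seed %d)", x$seed)))
  cat(sprintf("  distances: median %.4g, max %.4g\n",
              stats::median(x$distances), max(x$distances)))
  if (nrow(x$observed) > 0) {
    cat("  observed profiles:\n")
    for (i in seq_len(nrow(x$observed))) {
      cat(sprintf("    %s: distance %.4g, percentile %.1f\n",
                  x$observed$label[i], x$observed$distance[i], x$observed$percentile[i]))
    }
  }
  invisible(x)
}

#' @rdname permute_null
#' @param x A `permutation_null`.
#' @param ... Unused.
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm), distance = x$distances)
}

#' @rdname permute_null
#' @export
glance.permutation_null <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm,
    level = x$level,
    seed = x$seed,
    median_distance = stats::median(x$distances),
    max_distance = max(x$distances),
    n_observed = nrow(x$observed)
  )
}
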