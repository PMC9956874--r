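#' Count amino acid instances per protein isoform
#'
#' Tabulates, for every isoform, the number of instances of each canonical
#' amino acid in its sequence. These per-isoform counts are the raw material
#' of every profile builder: summed directly (pooled), normalised per protein
#' and averaged (protein-average), or weighted by transcript abundance.
#'
#' @param proteins A data frame with columns `isoform_id`, `sequence`, and
#'   optionally `gene_id` (defaults to `isoform_id`), e.g. from
#'   [read_proteome()].
#' @return A tibble of class `aa_counts`: `isoform_id`, `gene_id`, `length`,
#'   then one integer column per amino acid in alphabet order. `length`
#'   always equals the row sum of the count columns. Isoforms with zero
#'   canonical residues are excluded with a warning.
#' @export
#' @examples
#' count_aa(tibble::tibble(isoform_id = "i1", sequence = "MW"))
count_aa <- function(proteins) {
  if (!all(c("isoform_id", "sequence") %in% names(proteins))) {
    rlang::abort("count_aa() needs columns `isoform_id` and `sequence`")
  }
  if (nrow(proteins) == 0) rlang::abort("count_aa() needs at least one protein record")
  gene <- if ("gene_id" %in% names(proteins)) proteins$gene_id else proteins$isoform_id

  seqs <- Biostrings::AAStringSet(toupper(proteins$sequence))
  m <- Biostrings::letterFrequency(seqs, letters = aa_alphabet())
  colnames(m) <- aa_alphabet()
  len <- rowSums(m)

  empty <- len == 0
  if (any(empty)) {
    warning(sprintf("excluding %d isoform(s) with no canonical residues: %s",
                    sum(empty), paste(proteins$isoform_id[empty], collapse = ", ")))
  }
  out <- dplyr::bind_cols(
    tibble::tibble(isoform_id = as.character(proteins$isoform_id),
                   gene_id = as.character(gene),
                   length = unname(len)),
    tibble::as_tibble(m)
  )[!empty, , drop = FALSE]
  if (nrow(out) == 0) rlang::abort("no isoform has any canonical residues")
  class(out) <- c("aa_counts", class(out))
  out
}

# n x 20 numeric count matrix from an aa_counts tibble
count_matrix <- function(counts) {
  m <- as.matrix(counts[, aa_alphabet(), drop = FALSE])
  rownames(m) <- counts$isoform_id
  m
}

#' Exome-matched amino acid profile (unweighted)
#'
#' Builds a whole-exome amino acid usage profile from per-isoform counts,
#' without expression weighting. Two conventions exist and give different
#' answers for length-heterogeneous proteomes, so the choice is explicit:
#'
#' * `"protein_average"` — the original exome match: each protein's
#'   composition is normalised to proportions first, then the proportions
#'   are averaged with equal weight per protein (protein length does not
#'   weight the average);
#' * `"pooled"` — all residue counts are summed across isoforms and the
#'   total is normalised once. This is the expression-weighted calculation
#'   with every weight equal, so it isolates the effect of weighting.
#'
#' @param counts An `aa_counts` tibble from [count_aa()].
#' @param method `"protein_average"` or `"pooled"`.
#' @param label Optional label for the profile.
#' @return An [aa_profile()].
#' @export
#' @examples
#' cts <- count_aa(tibble::tibble(isoform_id = c("a", "b"),
#'                                sequence = c("MW", "MMMW")))
#' exome_profile(cts, "protein_average") # M = (0.5 + 0.75)/2
#' exome_profile(cts, "pooled")          # M = 4/6
exome_profile <- function(counts, method = c("protein_average", "pooled"), label = NULL) {
  method <- match.arg(method)
  m <- count_matrix(counts)
  if (method == "protein_average") {
    props <- m / rowSums(m)
    normalize_counts(colMeans(props), label = label)
  } else {
    normalize_counts(colSums(m), label = label)
  }
}

#' Transcriptome-weighted amino acid profile
#'
#' Weights each isoform's amino acid counts by its transcript abundance and
#' normalises the weighted totals: `AA_i = sum_j AA_ij * E_j`, then
#' `P(AA_i) = AA_i / sum_i AA_i`. Isoforms with zero expression contribute
#' nothing; isoforms absent from the expression table are treated as
#' unexpressed (a message reports how many).
#'
#' @param counts An `aa_counts` tibble from [count_aa()].
#' @param expression An expression tibble (`isoform_id` plus replicate
#'   columns) from [read_expression()], or a named numeric vector of
#'   per-isoform weights.
#' @param replicate Which replicate column to use. `NULL` (default) averages
#'   the FPKM values across all replicate columns first; see
#'   [average_profiles()] for the per-replicate-profile route.
#' @param label Optional label.
#' @return An [aa_profile()].
#' @export
weighted_profile <- function(counts, expression, replicate = NULL, label = NULL) {
  m <- count_matrix(counts)
  e <- expression_weights(expression, counts$isoform_id, replicate)
  if (all(e == 0)) {
    rlang::abort("all isoforms have zero expression; cannot build a weighted profile")
  }
  normalize_counts(drop(crossprod(m, e)), label = label)
}

# resolve an expression table / vector to weights aligned with isoform ids
expression_weights <- function(expression, isoform_ids, replicate = NULL) {
  if (is.numeric(expression)) {
    v <- expression
    if (is.null(names(v))) {
      if (length(v) != length(isoform_ids)) {
        rlang::abort("unnamed expression vector must match the number of isoforms")
      }
      names(v) <- isoform_ids
    }
  } else {
    reps <- setdiff(names(expression), "isoform_id")
    if (!is.null(replicate)) {
      if (!replicate %in% reps) {
        rlang::abort(sprintf("replicate '%s' not found (have: %s)", replicate, paste(reps, collapse = ", ")))
      }
      vals <- expression[[replicate]]
    } else {
      vals <- rowMeans(as.matrix(expression[, reps, drop = FALSE]))
    }
    v <- stats::setNames(vals, expression$isoform_id)
  }
  if (any(v < 0)) rlang::abort("expression weights must be non-negative")
  extra <- setdiff(names(v), isoform_ids)
  if (length(extra) > 0) {
    message(sprintf("ignoring %d expression entr%s without a matching isoform",
                    length(extra), if (length(extra) == 1) "y" else "ies"))
  }
  missing <- setdiff(isoform_ids, names(v))
  if (length(missing) > 0) {
    warning(sprintf("%d isoform(s) missing from the expression table; treated as unexpressed",
                    length(missing)))
  }
  out <- stats::setNames(numeric(length(isoform_ids)), isoform_ids)
  hit <- intersect(names(v), isoform_ids)
  out[hit] <- v[hit]
  out
}

#' Average a set of amino acid profiles
#'
#' Element-wise arithmetic mean across profiles (e.g. one weighted profile
#' per replicate transcriptome), renormalised to sum to one, with the
#' per-amino-acid standard deviation across the inputs retained for
#' error-bar plotting.
#'
#' @param profiles A list of profiles (see [profile_distance()] for accepted
#'   forms) or a profile matrix.
#' @param label Optional label for the mean profile.
#' @return An [aa_profile()] with an extra `sd` column (standard deviation of
#'   the raw, pre-renormalisation proportions across inputs).
#' @export
average_profiles <- function(profiles, label = NULL) {
  m <- profile_matrix(profiles)
  if (nrow(m) == 0) rlang::abort("average_profiles() needs at least one profile")
  p <- normalize_counts(colMeans(m), label = label)
  p$sd <- if (nrow(m) == 1) rep(0, ncol(m)) else unname(apply(m, 2, stats::sd))
  p
}
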