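# shared helpers for building tiny in-code fixtures

# named vector over the full alphabet with the given entries set
aa_vec <- function(...) {
  v <- stats::setNames(numeric(20), aa_alphabet())
  vals <- c(...)
  v[names(vals)] <- vals
  v
}

# profile tibble -> named vector for comparisons
pvec <- function(p) stats::setNames(p$proportion, p$aa)

# a random normalised profile
random_profile <- function() {
  v <- stats::runif(20)
  stats::setNames(v / sum(v), aa_alphabet())
}

# tiny proteins table
proteins_tbl <- function(seqs, genes = NULL) {
  ids <- sprintf("i%d", seq_along(seqs))
  tibble::tibble(
    isoform_id = ids,
    gene_id = if (is.null(genes)) ids else genes,
    sequence = seqs
  )
}

# single-replicate expression table
expr_tbl <- function(ids, values) {
  tibble::tibble(isoform_id = ids, rep1 = values)
}

# independent brute-force weighted profile: per-sequence table() counts,
# scaled by expression, normalised — no package profile code involved
brute_weighted <- function(seqs, e) {
  tot <- stats::setNames(numeric(20), aa_alphabet())
  for (i in seq_along(seqs)) {
    cnt <- table(factor(strsplit(seqs[[i]], "")[[1]], levels = aa_alphabet()))
    tot <- tot + as.numeric(cnt) * e[[i]]
  }
  tot / sum(tot)
}
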