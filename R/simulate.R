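#' Simulate a proteome with matched expression data
#'
#' Generates a synthetic multi-isoform proteome plus an isoform-level FPKM
#' table with known ground truth, emulating the statistical shape of real
#' inputs: protein sequences drawn residue-by-residue from a target amino
#' acid profile (multinomial — sufficient because all downstream
#' calculations depend only on counts), and right-skewed log-normal
#' expression with multiplicative replicate noise. The manifest records the
#' exact per-isoform counts and the analytically pooled expression-weighted
#' profile, computed independently of the profile builders, so generator and
#' builders can be cross-checked to machine precision.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Integer vector of possible isoform counts per
#'   gene, sampled uniformly (a single value fixes it).
#' @param length_range Two-element integer vector; isoform lengths are
#'   sampled uniformly in this range.
#' @param target_profile Profile the residues are drawn from (default:
#'   uniform over the 20 amino acids).
#' @param expr_meanlog,expr_sdlog Parameters of the log-normal distribution
#'   of per-isoform mean FPKM. Defaults (`meanlog = 2`, `sdlog = 1.5`) give
#'   the heavy right tail typical of bulk FPKM tables.
#' @param n_replicates Number of replicate expression columns.
#' @param replicate_sdlog Multiplicative (log-normal) replicate noise.
#' @param expr_model `"lognormal"` (default), `"uniform"`, or
#'   `"point_mass"` (all isoforms share FPKM 1 — handy for degenerate-case
#'   tests).
#' @param seed Integer seed (required; the generator is fully reproducible).
#' @return A list of class `exomatch_fixture`: `proteins` (tibble:
#'   `isoform_id`, `gene_id`, `sequence`), `expression` (tibble:
#'   `isoform_id` + replicate columns), and `manifest` (list: the call
#'   parameters, per-isoform residue counts, mean expression per isoform,
#'   total residues, and `weighted_truth`, the analytic expression-weighted
#'   profile as a named vector).
#' @seealso [write_fixture()], [worked_example()]
#' @export
simulate_proteome <- function(n_genes = 50,
                              isoforms_per_gene = 1:3,
                              length_range = c(100, 600),
                              target_profile = NULL,
                              expr_meanlog = 2, expr_sdlog = 1.5,
                              n_replicates = 3, replicate_sdlog = 0.2,
                              expr_model = c("lognormal", "uniform", "point_mass"),
                              seed = NULL) {
  expr_model <- match.arg(expr_model)
  if (is.null(seed)) rlang::abort("simulate_proteome() requires an explicit seed")
  if (n_genes < 1) rlang::abort("n_genes must be at least 1")
  if (length(length_range) != 2 || any(length_range < 1) || length_range[1] > length_range[2]) {
    rlang::abort("length_range must be c(min, max) with 1 <= min <= max")
  }
  if (is.null(target_profile)) {
    target_profile <- normalize_counts(stats::setNames(rep(1, 20), aa_alphabet()),
                                       label = "uniform")
  }
  tp <- aa_vector(target_profile)
  if (abs(sum(tp) - 1) > 1e-6) rlang::abort("target_profile must be normalised")

  with_perm_seed(seed, {
    n_iso <- isoforms_per_gene[sample.int(length(isoforms_per_gene), n_genes, replace = TRUE)]
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    gene_of <- rep(gene_ids, n_iso)
    iso_ids <- paste0(gene_of, ".", unlist(lapply(n_iso, seq_len)))
    total <- length(iso_ids)

    len_cand <- seq(length_range[1], length_range[2])
    lens <- len_cand[sample.int(length(len_cand), total, replace = TRUE)]
    seqs <- vapply(lens, function(L) {
      paste(sample(aa_alphabet(), L, replace = TRUE, prob = tp), collapse = "")
    }, character(1))

    mean_expr <- switch(expr_model,
      lognormal = stats::rlnorm(total, expr_meanlog, expr_sdlog),
      uniform = stats::runif(total, 0.5, 1.5),
      point_mass = rep(1, total)
    )
    reps <- vapply(seq_len(n_replicates), function(r) {
      mean_expr * stats::rlnorm(total, 0, replicate_sdlog)
    }, numeric(total))
    colnames(reps) <- sprintf("rep%d", seq_len(n_replicates))

    proteins <- tibble::tibble(isoform_id = iso_ids, gene_id = gene_of, sequence = seqs)
    expression <- dplyr::bind_cols(tibble::tibble(isoform_id = iso_ids),
                                   tibble::as_tibble(reps))

    # analytic ground truth, independent of count_aa()/weighted_profile():
    # tabulate each sequence directly and weight by replicate-mean FPKM
    count_tab <- t(vapply(strsplit(seqs, ""), function(s) {
      tab <- table(factor(s, levels = aa_alphabet()))
      as.numeric(tab)
    }, numeric(20)))
    colnames(count_tab) <- aa_alphabet()
    e_mean <- rowMeans(reps)
    wsum <- colSums(count_tab * e_mean)
    manifest <- list(
      n_genes = n_genes, n_isoforms = total, seed = seed,
      expr_model = expr_model, n_replicates = n_replicates,
      target_profile = as.list(tp),
      lengths = stats::setNames(as.list(lens), iso_ids),
      counts = stats::setNames(lapply(seq_len(total), function(i) as.list(count_tab[i, ])), iso_ids),
      mean_expression = stats::setNames(as.list(e_mean), iso_ids),
      total_residues = sum(lens),
      weighted_truth = wsum / sum(wsum)
    )
    structure(list(proteins = proteins, expression = expression, manifest = manifest),
              class = "exomatch_fixture")
  })
}

#' Write a simulated fixture to disk
#'
#' Writes the proteome as protein FASTA (`proteome.faa`, headers
#' `>isoform_id gene=gene_id`), the expression table as TSV
#' (`expression.tsv`), and the manifest as JSON (`manifest.json`).
#'
#' @param fixture An `exomatch_fixture` from [simulate_proteome()].
#' @param dir Output directory (created if missing).
#' @return The paths, invisibly, as a named list.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "exomatch_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "proteome.faa")
  set <- Biostrings::AAStringSet(fixture$proteins$sequence)
  names(set) <- sprintf("%s gene=%s", fixture$proteins$isoform_id, fixture$proteins$gene_id)
  Biostrings::writeXStringSet(set, fa)
  ex <- file.path(dir, "expression.tsv")
  readr::write_tsv(fixture$expression, ex)
  mf <- file.path(dir, "manifest.json")
  mfst <- fixture$manifest
  mfst$weighted_truth <- as.list(mfst$weighted_truth) # keep names in JSON
  jsonlite::write_json(mfst, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(proteome = fa, expression = ex, manifest = mf))
}

#' The three-gene worked example
#'
#' A hard-coded micro-dataset used throughout the documentation, small
#' enough that every intermediate quantity is computable by hand. Three
#' single-isoform genes: `g1` with sequence `MW` at FPKM 2, `g2` with
#' `MMMW` at FPKM 1, `g3` with `AAAG` at FPKM 1.
#'
#' Hand-computed expectations (exact fractions, recorded in `expected`):
#' * weighted: `AA_M = 1*2 + 3*1 = 5`, `AA_W = 1*2 + 1*1 = 3`, `AA_A = 3`,
#'   `AA_G = 1`, total 12, so `{M: 5/12, W: 1/4, A: 1/4, G: 1/12}`;
#' * pooled (unit weights): totals `{M: 4, W: 2, A: 3, G: 1}` over 10
#'   residues;
#' * protein-average: mean of the per-protein proportions
#'   `{M: 1/2, W: 1/2}`, `{M: 3/4, W: 1/4}`, `{A: 3/4, G: 1/4}`.
#'
#' @return A list: `proteins`, `expression` (single replicate `rep1`), and
#'   `expected`, a list of three named ground-truth vectors (`weighted`,
#'   `pooled`, `protein_average`).
#' @export
#' @examples
#' ex <- worked_example()
#' weighted_profile(count_aa(ex$proteins), ex$expression)
worked_example <- function() {
  proteins <- tibble::tibble(
    isoform_id = c("g1.1", "g2.1", "g3.1"),
    gene_id = c("g1", "g2", "g3"),
    sequence = c("MW", "MMMW", "AAAG")
  )
  expression <- tibble::tibble(isoform_id = proteins$isoform_id, rep1 = c(2, 1, 1))
  zero <- stats::setNames(numeric(20), aa_alphabet())
  mk <- function(...) { v <- zero; vals <- c(...); v[names(vals)] <- vals; v }
  expected <- list(
    weighted = mk(M = 5 / 12, W = 3 / 12, A = 3 / 12, G = 1 / 12),
    pooled = mk(M = 4 / 10, W = 2 / 10, A = 3 / 10, G = 1 / 10),
    protein_average = mk(M = (1 / 2 + 3 / 4) / 3, W = (1 / 2 + 1 / 4) / 3,
                         A = (3 / 4) / 3, G = (1 / 4) / 3)
  )
  list(proteins = proteins, expression = expression, expected = expected)
}
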