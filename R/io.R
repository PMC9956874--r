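#' Read a translated proteome from protein FASTA
#'
#' Parses one record per protein isoform. Sequences are uppercased, `*` stop
#' symbols stripped, and any residue outside the 20-letter canonical alphabet
#' dropped (a message reports how many letters were removed). Records left
#' with an empty sequence are dropped with a warning.
#'
#' @param path Path to a protein FASTA file.
#' @param header_rule How to extract isoform and gene identifiers from each
#'   header. One of:
#'   * `"auto"` (default): use the Flybase rule where a `parent=` field is
#'     present, otherwise the plain rule;
#'   * `"flybase"`: isoform id is the first word (e.g. `FBpp...`); gene id is
#'     the first `FBgn` accession of the `parent=` field — headers without
#'     one are an error;
#'   * `"plain"`: isoform id is the first word; gene id comes from a
#'     `gene=<id>` field if present, else defaults to the isoform id (so
#'     gene-level operations degrade gracefully to isoform level);
#'   * a function taking the full header string and returning
#'     `list(isoform_id =, gene_id =)`.
#' @return A tibble with columns `isoform_id`, `gene_id`, `sequence`
#'   (cleaned), and `n_dropped` (non-canonical letters removed), in file
#'   order.
#' @export
read_proteome <- function(path, header_rule = c("auto", "flybase", "plain")) {
  if (!file.exists(path)) rlang::abort(sprintf("proteome file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) rlang::abort(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- lapply(headers, parse_fasta_header, rule = header_rule)

  raw <- toupper(as.character(set))
  cleaned <- gsub("\\*", "", raw)
  keep_pat <- paste0("[^", paste(aa_alphabet(), collapse = ""), "]")
  stripped <- gsub(keep_pat, "", cleaned)
  n_dropped <- nchar(cleaned) - nchar(stripped)
  if (sum(n_dropped) > 0) {
    message(sprintf("read_proteome: dropped %d non-canonical letter(s) across %d record(s)",
                    sum(n_dropped), sum(n_dropped > 0)))
  }

  out <- tibble::tibble(
    isoform_id = vapply(ids, `[[`, character(1), "isoform_id"),
    gene_id = vapply(ids, `[[`, character(1), "gene_id"),
    sequence = unname(stripped),
    n_dropped = unname(n_dropped)
  )
  if (anyDuplicated(out$isoform_id)) {
    rlang::abort(sprintf("duplicated isoform id(s) in %s: %s", path,
                         paste(unique(out$isoform_id[duplicated(out$isoform_id)]), collapse = ", ")))
  }
  empty <- nchar(out$sequence) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d record(s) with no canonical residues: %s",
                    sum(empty), paste(out$isoform_id[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  if (nrow(out) == 0) rlang::abort(sprintf("no usable records in %s", path))
  out
}

parse_fasta_header <- function(header, rule = "auto") {
  if (is.function(rule)) {
    res <- rule(header)
    if (!all(c("isoform_id", "gene_id") %in% names(res))) {
      rlang::abort(sprintf("custom header rule must return isoform_id and gene_id (header: %s)", header))
    }
    return(res[c("isoform_id", "gene_id")])
  }
  rule <- match.arg(rule, c("auto", "flybase", "plain"))
  iso <- sub("\\s.*$", "", header)
  if (iso == "") rlang::abort(sprintf("unparseable FASTA header: '%s'", header))
  has_parent <- grepl("parent=", header, fixed = TRUE)
  if (rule == "flybase" || (rule == "auto" && has_parent)) {
    if (!has_parent) {
      rlang::abort(sprintf("header for record '%s' lacks the parent= field required by the flybase rule", iso))
    }
    parent <- sub(".*parent=([^;[:space:]]+).*", "\\1", header)
    gene <- grep("^FBgn", strsplit(parent, ",")[[1]], value = TRUE)
    if (length(gene) == 0) {
      rlang::abort(sprintf("no FBgn accession in parent= field of record '%s'", iso))
    }
    return(list(isoform_id = iso, gene_id = gene[[1]]))
  }
  gene <- if (grepl("gene=", header)) sub(".*gene=([^;[:space:]]+).*", "\\1", header) else iso
  list(isoform_id = iso, gene_id = gene)
}

#' Read an isoform expression table
#'
#' Tab-separated, `#`-prefixed comment lines permitted, header row required.
#' First column is the isoform id; every remaining column is one replicate of
#' FPKM values.
#'
#' @param path Path to the TSV file.
#' @param missing_as_zero Replace missing cells with 0 (with a warning giving
#'   the count). If `FALSE`, missing cells are an error.
#' @return A tibble: `isoform_id` plus one numeric column per replicate.
#' @export
read_expression <- function(path, missing_as_zero = TRUE) {
  if (!file.exists(path)) rlang::abort(sprintf("expression file not found: %s", path))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) rlang::abort("expression table needs an isoform column and at least one replicate column")
  names(tab)[1] <- "isoform_id"
  tab$isoform_id <- as.character(tab$isoform_id)
  if (anyDuplicated(tab$isoform_id)) {
    rlang::abort(sprintf("duplicated isoform id(s) in %s: %s", path,
                         paste(unique(tab$isoform_id[duplicated(tab$isoform_id)]), collapse = ", ")))
  }
  reps <- names(tab)[-1]
  for (r in reps) {
    v <- suppressWarnings(as.numeric(tab[[r]]))
    n_na <- sum(is.na(v))
    if (n_na > 0) {
      if (!missing_as_zero) rlang::abort(sprintf("%d missing/non-numeric value(s) in replicate '%s'", n_na, r))
      warning(sprintf("replacing %d missing value(s) with 0 in replicate '%s'", n_na, r))
      v[is.na(v)] <- 0
    }
    if (any(v < 0)) rlang::abort(sprintf("negative FPKM in replicate '%s'", r))
    if (all(v == 0)) rlang::abort(sprintf("replicate column '%s' is entirely zero", r))
    tab[[r]] <- v
  }
  tab
}

#' Read a diet molar-ratio table
#'
#' Tab-separated, one `aa` column and one column of molar ratios per diet.
#' Printed tables are rounded, so each diet column is accepted if it sums to
#' within `[0.98, 1.02]` and is then renormalised to exactly one; a column
#' outside that window (e.g. grams per litre passed by mistake) is rejected.
#'
#' @param path Path to the TSV.
#' @return A named list of [aa_profile()] objects, one per diet column, each
#'   carrying a `raw_sum` attribute with the pre-normalisation column sum.
#' @export
read_diet_ratios <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("diet ratio file not found: %s", path))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!"aa" %in% names(tab)) names(tab)[1] <- "aa"
  diets <- setdiff(names(tab), "aa")
  if (length(diets) == 0) rlang::abort("diet ratio table has no diet columns")
  out <- lapply(diets, function(d) {
    v <- aa_vector(stats::setNames(tab[[d]], tab$aa), what = sprintf("diet '%s'", d))
    s <- sum(v)
    if (s < 0.98 || s > 1.02) {
      rlang::abort(sprintf(
        "diet column '%s' sums to %.4g; molar ratios must sum to ~1 (is this a g/L column?)", d, s))
    }
    p <- normalize_counts(v, label = d)
    attr(p, "raw_sum") <- s
    p
  })
  stats::setNames(out, diets)
}

#' Read an amino acid molecular-weight table
#'
#' TSV with columns `aa`, `free_mw`, and optionally `salt_mw` and
#' `salt_name` for amino acids supplied as salts (e.g. monohydrochlorides).
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per amino acid present in the file.
#' @export
read_mw_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("molecular weight file not found: %s", path))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (!all(c("aa", "free_mw") %in% names(tab))) {
    rlang::abort("molecular weight table needs columns `aa` and `free_mw`")
  }
  if (!"salt_mw" %in% names(tab)) tab$salt_mw <- NA_real_
  if (!"salt_name" %in% names(tab)) tab$salt_name <- NA_character_
  bad <- setdiff(tab$aa, aa_alphabet())
  if (length(bad) > 0) rlang::abort(sprintf("unknown amino acid(s) in MW table: %s", paste(bad, collapse = ", ")))
  if (any(tab$free_mw <= 0)) rlang::abort("free_mw must be positive")
  if (any(!is.na(tab$salt_mw) & tab$salt_mw < tab$free_mw)) {
    rlang::abort("salt_mw must be >= free_mw")
  }
  tibble::as_tibble(tab[c("aa", "free_mw", "salt_mw", "salt_name")])
}

#' Write / read an amino acid profile as TSV
#'
#' Two columns `aa` and `proportion`, 20 rows in fixed alphabetical order,
#' full double precision. Optional `#` comment lines carry provenance.
#'
#' @param p An [aa_profile()] (or anything [aa_profile()] accepts).
#' @param path Output path.
#' @param comments Character vector written as `#`-prefixed header lines.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns an [aa_profile()] labelled from the `label:` comment if present.
#' @export
write_profile <- function(p, path, comments = NULL) {
  p <- aa_profile(aa_vector(p), label = if (inherits(p, "aa_profile")) profile_label(p))
  lines <- character(0)
  if (!is.null(profile_label(p))) lines <- sprintf("# label: %s", profile_label(p))
  if (!is.null(comments)) lines <- c(lines, paste0("# ", comments))
  lines <- c(lines, "aa\tproportion",
             sprintf("%s\t%.15g", p$aa, p$proportion))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("profile file not found: %s", path))
  hdr <- grep("^#", readLines(path, n = 20), value = TRUE)
  label <- NULL
  lab_line <- grep("^# label: ", hdr, value = TRUE)
  if (length(lab_line) > 0) label <- sub("^# label: ", "", lab_line[[1]])
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  aa_profile(stats::setNames(tab$proportion, tab$aa), label = label)
}

#' Write a coverage report as TSV
#'
#' Long-format per-amino-acid table with the limiting summary in `#` header
#' comments; suitable for Cleveland-plot rendering downstream.
#'
#' @param report A `coverage_report` from [aa_coverage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(report, path) {
  g <- generics::glance(report)
  lines <- c(
    sprintf("# diet: %s", g$diet_label),
    sprintf("# demand: %s", g$demand_label),
    sprintf("# limiting_aa: %s", g$limiting_aa),
    sprintf("# limiting_coverage_pct: %.15g", g$limiting_coverage),
    sprintf("# predicted_gain_pct: %.15g", g$predicted_gain)
  )
  writeLines(lines, path)
  readr::write_tsv(tibble::as_tibble(unclass_tbl(report)), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
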