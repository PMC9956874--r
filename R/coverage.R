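#' Coverage of a demand profile by a diet profile
#'
#' For each amino acid, coverage is `100 * diet_i / demand_i`: the percentage
#' of the demanded molar proportion that the diet supplies. The essential
#' amino acid with the lowest coverage is predicted to be limiting; its
#' deficit caps protein synthesis, so raising it (at fixed total amino acid)
#' is predicted to raise fecundity by [predicted_gain()]. Non-essential
#' amino acids are reported but never selected as limiting.
#'
#' Degenerate demands are handled explicitly: `demand = 0` with `diet > 0`
#' yields infinite coverage, flagged and never limiting; `demand = 0` with
#' `diet = 0` excludes the amino acid with a warning.
#'
#' @param diet,demand Profiles ([aa_profile()] objects, named vectors, or
#'   `aa`/`proportion` data frames) over the same 20-letter alphabet.
#' @param essentials Character vector of amino acids eligible to be
#'   limiting. Defaults to the fly's ten essential amino acids.
#' @param diet_label,demand_label Labels for reporting; default to the
#'   profiles' own labels.
#' @return A tibble of class `coverage_report` with columns `aa`,
#'   `essential`, `diet`, `demand`, `coverage` (percent), `limiting`
#'   (logical; `TRUE` for every tied minimal essential), and attributes
#'   summarised by [generics::glance()]: `limiting_aa` (alphabetically first
#'   if tied), `limiting_coverage`, `predicted_gain`.
#' @seealso [predicted_gain()], [tissue_panel()]
#' @export
#' @examples
#' diets <- diet_profiles()
#' aa_coverage(diets$FLYAA, diets$MALEAA)
aa_coverage <- function(diet, demand, essentials = aa_essential(),
                        diet_label = NULL, demand_label = NULL) {
  if (is.null(diet_label)) diet_label <- label_or(diet, "diet")
  if (is.null(demand_label)) demand_label <- label_or(demand, "demand")
  dv <- aa_vector(diet, what = "diet")
  mv <- aa_vector(demand, what = "demand")
  bad_ess <- setdiff(essentials, aa_alphabet())
  if (length(bad_ess) > 0) {
    rlang::abort(sprintf("unknown essential amino acid(s): %s", paste(bad_ess, collapse = ", ")))
  }

  both_zero <- mv == 0 & dv == 0
  if (any(both_zero)) {
    warning(sprintf("excluding amino acid(s) absent from both profiles: %s",
                    paste(names(mv)[both_zero], collapse = ", ")))
  }
  cov <- ifelse(mv > 0, 100 * dv / mv, Inf)
  cov[both_zero] <- NA_real_

  out <- tibble::tibble(
    aa = aa_alphabet(),
    essential = aa_alphabet() %in% essentials,
    diet = unname(dv),
    demand = unname(mv),
    coverage = unname(cov)
  )
  ess_cov <- out$coverage[out$essential & is.finite(out$coverage)]
  if (length(ess_cov) == 0) {
    rlang::abort("no essential amino acid has a finite coverage; cannot identify a limiting amino acid")
  }
  lim_cov <- min(ess_cov)
  out$limiting <- out$essential & is.finite(out$coverage) & out$coverage == lim_cov
  lim_aas <- out$aa[out$limiting]
  if (length(lim_aas) > 1) {
    message(sprintf("tie for limiting amino acid (%s); reporting %s as primary",
                    paste(lim_aas, collapse = ", "), lim_aas[[1]]))
  }

  class(out) <- c("coverage_report", class(out))
  attr(out, "diet_label") <- diet_label
  attr(out, "demand_label") <- demand_label
  attr(out, "limiting_aa") <- lim_aas[[1]]
  attr(out, "limiting_coverage") <- lim_cov
  attr(out, "predicted_gain") <- gain_from_coverage(lim_cov)
  out
}

label_or <- function(p, default) {
  if (inherits(p, "aa_profile") && !is.null(profile_label(p))) profile_label(p) else default
}

gain_from_coverage <- function(cov) {
  if (cov == 0) Inf else 100 * (100 / cov - 1)
}

#' Predicted fecundity gain from rebalancing to the demand ratio
#'
#' The relative increase in the limiting amino acid when the diet is switched
#' to the demand ratio at fixed total amino acid concentration:
#' `100 * (100 / limiting_coverage - 1)` percent. Under single-AA
#' limitation this equals the potential increase in fecundity. A limiting
#' coverage of zero (the essential amino acid is entirely absent) gives an
#' unbounded gain, returned as `Inf`.
#'
#' @param report A `coverage_report` from [aa_coverage()], or a numeric
#'   limiting coverage in percent.
#' @return Gain in percent.
#' @export
#' @examples
#' predicted_gain(50)  # doubling the limiting AA: 100%
predicted_gain <- function(report) {
  cov <- if (inherits(report, "coverage_report")) attr(report, "limiting_coverage") else report
  if (!is.numeric(cov) || length(cov) != 1 || cov < 0) {
    rlang::abort("predicted_gain() needs a coverage_report or a single non-negative coverage percentage")
  }
  gain_from_coverage(cov)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> diet %s vs demand %s\n",
              attr(x, "diet_label"), attr(x, "demand_label")))
  cat(sprintf("  limiting: %s at %.1f%% coverage (predicted gain %.1f%%)\n",
              attr(x, "limiting_aa"), attr(x, "limiting_coverage"),
              attr(x, "predicted_gain")))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname aa_coverage
#' @param x A `coverage_report`.
#' @param ... Unused.
#' @export
tidy.coverage_report <- function(x, ...) tibble::as_tibble(unclass_tbl(x))

#' @rdname aa_coverage
#' @export
glance.coverage_report <- function(x, ...) {
  tibble::tibble(
    diet_label = attr(x, "diet_label"),
    demand_label = attr(x, "demand_label"),
    limiting_aa = attr(x, "limiting_aa"),
    limiting_coverage = attr(x, "limiting_coverage"),
    predicted_gain = attr(x, "predicted_gain"),
    n_aa = sum(!is.na(x$coverage))
  )
}

#' Limiting amino acid panel across tissues
#'
#' Evaluates each diet against each tissue-specific demand profile and
#' reports the limiting essential amino acid and its coverage — the data
#' behind Cleveland plots of how well alternative diets meet per-tissue
#' demands. When exactly two diets are supplied, per-tissue gain difference
#' (`gain_diff = gain(diet1) - gain(diet2)`) quantifies how much switching
#' diets is predicted to help each tissue.
#'
#' @param diets Named list of diet profiles.
#' @param demands Named list of tissue demand profiles.
#' @param essentials Essential set passed to [aa_coverage()].
#' @return A tibble with one row per (tissue, diet): `tissue`, `diet`,
#'   `limiting_aa`, `limiting_coverage`, `predicted_gain`, plus a
#'   `per_aa` list-column of full coverage tables.
#' @export
tissue_panel <- function(diets, demands, essentials = aa_essential()) {
  if (length(diets) == 0 || length(demands) == 0) {
    rlang::abort("tissue_panel() needs at least one diet and one demand profile")
  }
  diets <- name_if_unnamed(diets, "diet")
  demands <- name_if_unnamed(demands, "tissue")
  grid <- tidyr::expand_grid(tissue = names(demands), diet = names(diets))
  rows <- purrr::pmap(grid, function(tissue, diet) {
    rep <- aa_coverage(diets[[diet]], demands[[tissue]], essentials = essentials,
                       diet_label = diet, demand_label = tissue)
    g <- glance(rep)
    tibble::tibble(tissue = tissue, diet = diet,
                   limiting_aa = g$limiting_aa,
                   limiting_coverage = g$limiting_coverage,
                   predicted_gain = g$predicted_gain,
                   per_aa = list(tidy(rep)))
  })
  out <- dplyr::bind_rows(rows)
  if (length(diets) == 2) {
    d1 <- names(diets)[[1]]; d2 <- names(diets)[[2]]
    gd <- out |>
      dplyr::select("tissue", "diet", "predicted_gain") |>
      tidyr::pivot_wider(names_from = "diet", values_from = "predicted_gain") |>
      dplyr::mutate(gain_diff = .data[[d1]] - .data[[d2]]) |>
      dplyr::select("tissue", "gain_diff")
    out <- dplyr::left_join(out, gd, by = "tissue")
  }
  out
}

name_if_unnamed <- function(x, prefix) {
  if (is.null(names(x)) || any(names(x) == "")) {
    nm <- if (is.null(names(x))) rep("", length(x)) else names(x)
    auto <- paste0(prefix, seq_along(x))
    nm[nm == ""] <- auto[nm == ""]
    names(x) <- nm
  }
  x
}

#' Power analysis for fecundity assays
#'
#' The sample size needed to detect a difference `E` in a measure with
#' standard deviation `sigma` at confidence multiplier `Z` follows
#' `n = (Z * sigma / E)^2`. Any one of the four quantities can be solved for
#' given the other three.
#'
#' @param Z Confidence-level multiplier (e.g. 1.96 for two-sided 5%).
#' @param sigma Standard deviation of the fecundity measure.
#' @param E Detectable difference, in the same units as `sigma`.
#' @param n Sample size.
#' @param solve_for One of `"n"`, `"Z"`, `"sigma"`, `"E"`.
#' @return The solved quantity (a scalar).
#' @export
#' @examples
#' power_sample_size(Z = 2, sigma = 1, E = 1)          # n = 4
#' power_sample_size(n = 4, sigma = 1, E = 1, solve_for = "Z")
power_sample_size <- function(Z = NULL, sigma = NULL, E = NULL, n = NULL,
                              solve_for = c("n", "Z", "sigma", "E")) {
  solve_for <- match.arg(solve_for)
  args <- list(Z = Z, sigma = sigma, E = E, n = n)
  needed <- setdiff(names(args), solve_for)
  missing <- needed[vapply(args[needed], is.null, logical(1))]
  if (length(missing) > 0) {
    rlang::abort(sprintf("missing value(s) for %s", paste(missing, collapse = ", ")))
  }
  for (nm in needed) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      rlang::abort(sprintf("'%s' must be a single positive number", nm))
    }
  }
  switch(solve_for,
    n = (args$Z * args$sigma / args$E)^2,
    Z = sqrt(args$n) * args$E / args$sigma,
    sigma = sqrt(args$n) * args$E / args$Z,
    E = args$Z * args$sigma / sqrt(args$n)
  )
}
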