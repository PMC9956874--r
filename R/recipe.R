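#' Default amino acid molecular weights
#'
#' Standard free-base molecular weights (g/mol) of the 20 proteinogenic
#' amino acids, with monohydrochloride salt weights for lysine and arginine,
#' the two amino acids commonly supplied as HCl salts in chemically defined
#' fly food. Override any entry by supplying your own table to
#' [formulate_diet()] (format of [read_mw_table()]).
#'
#' @return A tibble with columns `aa`, `free_mw`, `salt_mw`, `salt_name`.
#' @export
aa_molecular_weights <- function() {
  read_mw_table(system.file("extdata", "aa_molecular_weights.tsv",
                            package = "exomatch", mustWork = TRUE))
}

#' Formulate a chemically defined diet from a molar amino acid ratio
#'
#' Converts a molar-fraction profile plus a total amino acid concentration
#' into per-amino-acid amounts for one litre of food. The total is
#' interpreted on a free-base basis: total moles
#' `N = total_g_per_l / sum_i p_i * MW_i(free)`, free-base grams
#' `N * p_i * MW_i(free)`. When `use_salt_forms = TRUE`, amino acids with a
#' salt entry in the MW table get a weighed mass scaled by
#' `MW(salt) / MW(free)` (the counter-ion adds weigh-out mass but no amino
#' acid), so dilution series scale the same profile linearly regardless of
#' salt choice.
#'
#' @param profile An [aa_profile()] (molar fractions).
#' @param total_g_per_l Total amino acid concentration, grams of free base
#'   per litre of food.
#' @param mw Molecular-weight table ([aa_molecular_weights()] by default).
#' @param use_salt_forms Weigh salts where a `salt_mw` is defined.
#' @return A tibble of class `diet_recipe`: `aa`, `molar_fraction`,
#'   `mmol_per_l`, `free_g_per_l`, `weighed_g_per_l`, `form`; attributes
#'   `label` and `total_g_per_l`. Amino acids with zero molar fraction are
#'   retained with zero amounts.
#' @export
#' @examples
#' formulate_diet(diet_profiles()$FLYAA, total_g_per_l = 10.7)
formulate_diet <- function(profile, total_g_per_l, mw = aa_molecular_weights(),
                           use_salt_forms = FALSE) {
  if (!is.numeric(total_g_per_l) || length(total_g_per_l) != 1 || total_g_per_l <= 0) {
    rlang::abort("total_g_per_l must be a single positive number")
  }
  p <- aa_vector(profile)
  if (abs(sum(p) - 1) > 1e-6) rlang::abort("profile must be normalised; see normalize_counts()")

  need <- aa_alphabet()[p > 0]
  miss <- setdiff(need, mw$aa)
  if (length(miss) > 0) {
    rlang::abort(sprintf("no molecular weight for amino acid(s): %s", paste(miss, collapse = ", ")))
  }
  free_mw <- stats::setNames(rep(NA_real_, 20), aa_alphabet())
  free_mw[mw$aa] <- mw$free_mw
  salt_mw <- stats::setNames(rep(NA_real_, 20), aa_alphabet())
  salt_mw[mw$aa] <- mw$salt_mw
  salt_name <- stats::setNames(rep(NA_character_, 20), aa_alphabet())
  salt_name[mw$aa] <- mw$salt_name

  mol_total <- total_g_per_l / sum(p * free_mw[aa_alphabet()], na.rm = TRUE)
  mmol <- 1000 * mol_total * p
  free_g <- mol_total * p * free_mw
  free_g[p == 0] <- 0

  use_salt <- use_salt_forms & !is.na(salt_mw) & p > 0
  weighed <- ifelse(use_salt, free_g * salt_mw / free_mw, free_g)
  form <- ifelse(use_salt, salt_name, "free base")

  out <- tibble::tibble(
    aa = aa_alphabet(),
    molar_fraction = unname(p),
    mmol_per_l = unname(mmol),
    free_g_per_l = unname(free_g),
    weighed_g_per_l = unname(weighed),
    form = unname(form)
  )
  class(out) <- c("diet_recipe", class(out))
  attr(out, "label") <- label_or(profile, "diet")
  attr(out, "total_g_per_l") <- total_g_per_l
  out
}

#' @export
print.diet_recipe <- function(x, ...) {
  cat(sprintf("<diet_recipe> %s at %.4g g/L free-base amino acids (%.4g mmol/L)\n",
              attr(x, "label"), attr(x, "total_g_per_l"), sum(x$mmol_per_l)))
  NextMethod()
}

#' @rdname formulate_diet
#' @param x A `diet_recipe`.
#' @param ... Unused.
#' @export
glance.diet_recipe <- function(x, ...) {
  tibble::tibble(
    label = attr(x, "label"),
    total_g_per_l = attr(x, "total_g_per_l"),
    total_weighed_g_per_l = sum(x$weighed_g_per_l),
    total_mmol_per_l = sum(x$mmol_per_l),
    n_salt_forms = sum(x$form != "free base" & x$free_g_per_l > 0)
  )
}

#' Default stock-solution plan for holidic fly food
#'
#' Assigns each amino acid to a preparation stage: isoleucine, leucine and
#' tyrosine are too insoluble for concentrated stocks and go straight into
#' the food before autoclaving; glutamate and cysteine are added from their
#' own post-autoclave solutions; the remaining essentials and non-essentials
#' go into the EAA and NEAA stock solutions respectively.
#'
#' @return A tibble with columns `aa` and `stock`.
#' @export
default_stock_plan <- function() {
  direct <- c("I", "L", "Y")
  own <- c(E = "glu_solution", C = "cys_solution")
  tibble::tibble(
    aa = aa_alphabet(),
    stock = dplyr::case_when(
      aa_alphabet() %in% direct ~ "direct_to_food",
      aa_alphabet() %in% names(own) ~ unname(own[aa_alphabet()]),
      aa_alphabet() %in% aa_essential() ~ "eaa_stock",
      TRUE ~ "neaa_stock"
    )
  )
}

#' Split a diet recipe across stock solutions
#'
#' Partitions the per-litre amino acid amounts of a recipe according to a
#' stock plan. Amounts are conserved: summing over stocks recovers the
#' recipe exactly.
#'
#' @param recipe A `diet_recipe` from [formulate_diet()].
#' @param plan A tibble with columns `aa` and `stock` assigning every amino
#'   acid with a non-zero amount to a stock ([default_stock_plan()] by
#'   default).
#' @return A tibble: `stock`, `aa`, `mmol_per_l`, `free_g_per_l`,
#'   `weighed_g_per_l`, ordered by stock then amino acid.
#' @export
split_stocks <- function(recipe, plan = default_stock_plan()) {
  stopifnot(inherits(recipe, "diet_recipe"))
  if (!all(c("aa", "stock") %in% names(plan))) {
    rlang::abort("stock plan needs columns `aa` and `stock`")
  }
  unassigned <- setdiff(recipe$aa[recipe$free_g_per_l > 0], plan$aa)
  if (length(unassigned) > 0) {
    rlang::abort(sprintf("stock plan does not cover: %s", paste(unassigned, collapse = ", ")))
  }
  tibble::as_tibble(unclass_tbl(recipe)) |>
    dplyr::inner_join(plan, by = "aa") |>
    dplyr::select("stock", "aa", "mmol_per_l", "free_g_per_l", "weighed_g_per_l") |>
    dplyr::arrange(.data$stock, .data$aa)
}
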