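# Domain types shared across the pipeline: the seven-category waste taxonomy
# and the nutrient-profile vector that is the currency of the nutrition stage.

#' The seven plate-waste food categories
#'
#' Waste is collected with the aggregate selective weighing method into exactly
#' seven bins: starchy first courses, bread, protein-based second courses,
#' vegetable side dishes, fruit, dessert, and "other" (dishes with comparable
#' starch and protein content, e.g. pizza). Any record referencing a category
#' outside this set is rejected at load time.
#'
#' @format Character vector of the seven category codes.
#' @export
pw_categories <- c("starchy", "bread", "protein", "vegetable", "fruit",
                   "dessert", "other")

#' Nutrient-profile component names
#'
#' Energy plus the macro- and micronutrient vector tracked through serving,
#' waste and intake accounting. Units are encoded in the names: kcal, g, mg
#' or micrograms (ug) per reference amount (per 100 g edible food in
#' composition tables, per child per lunch in menu-level results).
#'
#' @format Character vector of 23 component names.
#' @export
pw_nutrients <- c(
  "energy_kcal", "protein_g", "carbohydrate_g", "soluble_sugars_g", "fat_g",
  "cholesterol_mg", "fibre_g",
  "vit_A_ug", "vit_B1_mg", "vit_B2_mg", "vit_B3_mg", "vit_B6_mg",
  "vit_B9_ug", "vit_B12_ug", "vit_C_mg", "vit_D_ug",
  "Na_mg", "K_mg", "Ca_mg", "P_mg", "Fe_mg", "Zn_mg", "Cu_mg")

#' Construct a nutrient profile
#'
#' A nutrient profile is a named numeric vector over the fixed component set
#' [pw_nutrients]. Unspecified components default to zero; negative values are
#' rejected. Profiles support element-wise addition, subtraction (floored at
#' zero with a warning, see [profile_subtract()]) and scalar scaling.
#'
#' @param ... Named components, e.g. `energy_kcal = 520, protein_g = 20`.
#' @param values Alternatively, a named numeric vector of components.
#' @return A numeric vector of class `nutrient_profile` with one entry per
#'   component in [pw_nutrients].
#' @examples
#' nutrient_profile(energy_kcal = 200, protein_g = 8)
#' @export
nutrient_profile <- function(..., values = NULL) {
  x <- if (is.null(values)) c(...) else values
  out <- stats::setNames(numeric(length(pw_nutrients)), pw_nutrients)
  if (length(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("nutrient profile components must be named", call. = FALSE)
    }
    unknown <- setdiff(names(x), pw_nutrients)
    if (length(unknown)) {
      stop("unknown nutrient component(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out[names(x)] <- as.numeric(x)
  }
  if (any(is.na(out))) stop("nutrient components must not be NA", call. = FALSE)
  if (any(out < 0)) {
    stop("nutrient components must be non-negative", call. = FALSE)
  }
  structure(out, class = "nutrient_profile")
}

as_profile <- function(x) {
  stopifnot(is.numeric(x), length(x) == length(pw_nutrients))
  structure(stats::setNames(as.numeric(x), pw_nutrients),
            class = "nutrient_profile")
}

#' Add two nutrient profiles
#' @param a,b Nutrient profiles.
#' @return Their component-wise sum.
#' @export
profile_add <- function(a, b) as_profile(unclass(a) + unclass(b))

#' Subtract nutrient profiles, flooring at zero
#'
#' Component-wise `a - b`. Negative results are physically impossible (a child
#' cannot eat more of a nutrient than was served), so they are floored at zero
#' and reported with a warning; the `floored` attribute names the affected
#' components so the flag can be propagated.
#'
#' @param a,b Nutrient profiles.
#' @param warn Emit a warning when flooring occurs (default `TRUE`).
#' @return `nutrient_profile` with attribute `floored` (character vector of
#'   floored component names, possibly empty).
#' @export
profile_subtract <- function(a, b, warn = TRUE) {
  d <- unclass(a) - unclass(b)
  neg <- names(d)[d < 0]
  if (length(neg) && warn) {
    warning("intake floored at 0 for component(s): ",
            paste(neg, collapse = ", "), call. = FALSE)
  }
  d[d < 0] <- 0
  out <- as_profile(d)
  attr(out, "floored") <- neg
  out
}

#' Scale a nutrient profile by a non-negative scalar
#' @param a Nutrient profile.
#' @param k Non-negative scalar.
#' @return Scaled profile.
#' @export
profile_scale <- function(a, k) {
  stopifnot(length(k) == 1, is.finite(k), k >= 0)
  as_profile(unclass(a) * k)
}

#' @export
print.nutrient_profile <- function(x, ...) {
  cat("<nutrient_profile>\n")
  print(round(unclass(x), 3))
  invisible(x)
}

zero_profile <- function() as_profile(numeric(length(pw_nutrients)))

# stop() with a classed condition so callers/tests can distinguish schema,
# integrity and validation failures.
pw_stop <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(class = c(class, "pw_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
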