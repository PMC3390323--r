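# Potassium-efficiency screening indices computed from dry weight and
# K-content measurements. K content arrives as percent of dry weight and
# is converted to mg/g with the factor 10 (1% = 10 mg/g).

#' Potassium accumulation per plant
#'
#' `K accumulation = K content (mg/g) x dry weight (g)`, with the content
#' supplied as percent of dry weight.
#'
#' @param k_content_pct K content, percent of dry weight, in `(0, 100)`.
#' @param dry_weight_g Dry weight per plant in grams, > 0.
#' @return mg of K per plant.
#' @export
#' @examples
#' k_accumulation(1.40, 1.92)  # ~26.9 mg/plant
k_accumulation <- function(k_content_pct, dry_weight_g) {
  if (any(!is.finite(k_content_pct)) || any(k_content_pct <= 0) ||
      any(k_content_pct >= 100)) {
    abort("`k_content_pct` must lie in (0, 100).")
  }
  if (any(!is.finite(dry_weight_g)) || any(dry_weight_g <= 0)) {
    abort("`dry_weight_g` must be positive.")
  }
  (k_content_pct * 10) * dry_weight_g
}

#' Potassium use efficiency (KUE)
#'
#' `KUE = dry weight (g) x 1000 / K content (mg/g)` -- grams of biomass
#' produced per gram of accumulated K, scaled by 1000.
#'
#' @inheritParams k_accumulation
#' @return Dimensionless efficiency (dry weight may be 0, giving 0).
#' @export
#' @examples
#' kue(1.92, 1.40)  # ~137
kue <- function(dry_weight_g, k_content_pct) {
  if (any(!is.finite(k_content_pct)) || any(k_content_pct <= 0)) {
    abort("`k_content_pct` must be positive.")
  }
  if (any(!is.finite(dry_weight_g)) || any(dry_weight_g < 0)) {
    abort("`dry_weight_g` must be non-negative.")
  }
  dry_weight_g * 1000 / (k_content_pct * 10)
}

#' Relative index (low-K tolerance coefficient)
#'
#' Trait value under low K divided by the value under normal K; values
#' near 1 mark tolerant genotypes.
#'
#' @param low_value,high_value Trait values under low-K and normal-K
#'   conditions; `high_value` must be > 0.
#' @return `low_value / high_value` (report to 2 decimals by convention).
#' @export
relative_index <- function(low_value, high_value) {
  if (any(!is.finite(high_value)) || any(high_value <= 0)) {
    abort("`high_value` must be positive.")
  }
  low_value / high_value
}

#' Shoot-to-root dry-weight ratio
#'
#' Ground biomass is the shoot mass; root mass is total minus ground.
#'
#' @param total_g Total dry weight per plant (g).
#' @param ground_g Above-ground (shoot) dry weight per plant (g); must be
#'   strictly between 0 and `total_g`.
#' @return `ground / (total - ground)`.
#' @export
#' @examples
#' shoot_root_ratio(1.92, 1.62)  # 5.40
shoot_root_ratio <- function(total_g, ground_g) {
  if (any(!is.finite(total_g)) || any(!is.finite(ground_g)) ||
      any(ground_g <= 0) || any(total_g <= ground_g)) {
    abort("Need `total_g` > `ground_g` > 0.")
  }
  ground_g / (total_g - ground_g)
}

#' Derived phenotype table
#'
#' Adds every derivable screening index to a phenotype table: root dry
#' weight, shoot/root ratio, K accumulation and KUE per row.
#'
#' @param phenotypes Tibble with columns `genotype`, `treatment`
#'   (`"lowK"` / `"highK"`), `total_dry_weight`, `ground_biomass`,
#'   `k_content_pct`.
#' @return The input with `root_dry_weight`, `shoot_root`,
#'   `k_accumulation`, `kue` columns appended.
#' @export
phenotype_table <- function(phenotypes) {
  need <- c("genotype", "treatment", "total_dry_weight", "ground_biomass",
            "k_content_pct")
  if (!all(need %in% names(phenotypes))) {
    abort(paste("`phenotypes` needs columns:", paste(need, collapse = ", ")))
  }
  if (any(phenotypes$ground_biomass > phenotypes$total_dry_weight)) {
    abort("`ground_biomass` cannot exceed `total_dry_weight`.")
  }
  as_tibble(phenotypes) |>
    mutate(
      root_dry_weight = .data$total_dry_weight - .data$ground_biomass,
      shoot_root = shoot_root_ratio(.data$total_dry_weight,
                                    .data$ground_biomass),
      k_accumulation = k_accumulation(.data$k_content_pct,
                                      .data$total_dry_weight),
      kue = kue(.data$total_dry_weight, .data$k_content_pct)
    )
}

#' Low-K / high-K relative indices per genotype
#'
#' Pivots a derived phenotype table to one row per genotype and computes
#' the relative index (low-K value over high-K value) for the main
#' screening traits.
#'
#' @param phenotypes Input accepted by [phenotype_table()], containing a
#'   `lowK` and a `highK` row per genotype.
#' @param traits Traits to index (columns of the derived table).
#' @return Tibble with one row per genotype and a `ri_<trait>` column per
#'   trait.
#' @export
phenotype_relative_indices <- function(phenotypes,
                                       traits = c("total_dry_weight",
                                                  "ground_biomass",
                                                  "k_accumulation")) {
  derived <- phenotype_table(phenotypes)
  wide <- derived |>
    select("genotype", "treatment", dplyr::all_of(traits)) |>
    tidyr::pivot_wider(names_from = "treatment",
                       values_from = dplyr::all_of(traits),
                       names_glue = "{.value}_{treatment}")
  for (tr in traits) {
    wide[[paste0("ri_", tr)]] <- relative_index(
      wide[[paste0(tr, "_lowK")]], wide[[paste0(tr, "_highK")]]
    )
  }
  wide
}
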