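#' The 26 food groups
#'
#' Canonical, ordered labels for the 26 food groups into which recall items
#' are classified (grains, vegetables, animal-source foods, dairy, snacks and
#' beverages). The order is frozen: downstream objects (importance vectors,
#' score definitions) index groups by this order.
#'
#' @return Character vector of length 26.
#' @export
food_groups <- function() {
  c("rice", "wheat", "refined_grains", "other_cereals", "fried_foods",
    "nuts_legumes", "roots_tubers", "deep_color_vegetables",
    "light_color_vegetables", "fungi_algae", "pickled_vegetables", "fruits",
    "pork", "poultry", "red_meat_other_than_pork", "animal_offal",
    "processed_meat", "seafood", "eggs", "milk", "yogurt", "dairy_products",
    "sauces", "ssb", "candy_sugar", "dessert")
}

#' Default food item to food group map
#'
#' Reads the packaged YAML mapping of recall food items to the 26 food
#' groups. Real studies catalogue on the order of a thousand distinct items;
#' the packaged map carries a compact representative item list per group and
#' can be replaced by [read_food_group_map()] with a study-specific file.
#'
#' @return A `food_group_map`: tibble with columns `item` and `group`.
#' @export
default_food_group_map <- function() {
  path <- system.file("extdata", "food_group_map.yaml", package = "dietcmr")
  abort_if(path == "", "packaged food group map not found")
  read_food_group_map(path)
}

#' Read a food group map from YAML
#'
#' The file must be a mapping from group label to a list of item labels,
#' covering exactly the 26 groups of [food_groups()]; every item may appear
#' under exactly one group.
#'
#' @param path Path to a YAML file.
#' @return A `food_group_map` tibble with columns `item`, `group`.
#' @export
read_food_group_map <- function(path) {
  raw <- yaml::read_yaml(path)
  as_food_group_map(tibble::tibble(
    item = unlist(raw, use.names = FALSE),
    group = rep(names(raw), vapply(raw, length, integer(1)))
  ))
}

#' Write a food group map to YAML
#'
#' @param map A `food_group_map` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_food_group_map <- function(map, path) {
  map <- as_food_group_map(map)
  yaml::write_yaml(split(map$item, factor(map$group, levels = food_groups())),
                   path)
  invisible(path)
}

as_food_group_map <- function(map) {
  require_columns(map, c("item", "group"), "food group map")
  groups <- unique(map$group)
  extra <- setdiff(groups, food_groups())
  missing <- setdiff(food_groups(), groups)
  abort_if(length(extra) > 0,
           "unknown food group(s): ", paste(extra, collapse = ", "))
  abort_if(length(missing) > 0,
           "map must cover all 26 groups; missing: ",
           paste(missing, collapse = ", "))
  abort_if(anyDuplicated(map$item) > 0,
           "each food item must map to exactly one group; duplicated: ",
           paste(unique(map$item[duplicated(map$item)]), collapse = ", "))
  structure(tibble::as_tibble(map), class = c("food_group_map",
                                              class(tibble::tibble())))
}
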