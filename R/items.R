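#' Define the universe of selectable items
#'
#' An item universe lists the objects available on every trial and flags
#' exactly one of them as the exchangeable target (the object trained to be
#' redeemable with a human for food). The default universe is the four-object
#' set used throughout the bundled dataset: a metal strip (target), a plastic
#' rope, a wooden rod and a jute cloth.
#'
#' @param labels Character vector of item labels, length at least 2, no
#'   duplicates. Labels must not collide with the reserved tokens `"REFUSED"`,
#'   `"NONE"` and `"UNKNOWN"`.
#' @param target Label of the exchangeable item; must appear in `labels`.
#'
#' @return A tibble with columns `item` (character) and `is_target` (logical),
#'   exactly one row of which has `is_target = TRUE`.
#' @examples
#' item_universe()
#' item_universe(c("token", "stone", "leaf"), target = "token")
#' @export
item_universe <- function(labels = c("metal", "rope", "wood", "jute"),
                          target = "metal") {
  labels <- as.character(labels)
  if (length(labels) < 2) {
    abort("An item universe needs at least 2 items.")
  }
  if (anyDuplicated(labels)) {
    abort("Item labels must be unique.")
  }
  reserved <- intersect(labels, c(REFUSED, NONE, UNKNOWN))
  if (length(reserved)) {
    abort(paste0("Item labels collide with reserved tokens: ",
                 paste(reserved, collapse = ", ")))
  }
  if (!target %in% labels) {
    abort(sprintf("Target item '%s' is not among the labels.", target))
  }
  tibble(item = labels, is_target = labels == target)
}

#' @rdname item_universe
#' @param items An item-universe tibble, as returned by [item_universe()].
#' @return `target_item()` returns the label of the target item;
#'   `n_items()` the universe size m.
#' @export
target_item <- function(items = item_universe()) {
  stopifnot(is.data.frame(items), sum(items$is_target) == 1)
  items$item[items$is_target]
}

#' @rdname item_universe
#' @export
n_items <- function(items = item_universe()) {
  nrow(items)
}
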