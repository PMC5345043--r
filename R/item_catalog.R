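#' Build an item catalog for a synthetic cohort
#'
#' Creates per-item metadata: number of response categories, coding
#' direction, first-order factor assignment (with a configurable number
#' of items cross-loading on a second factor), and a wave-availability
#' mask. Exactly \code{config$n_varying} items are made unavailable in at
#' least one wave after the first; the remainder are anchor items
#' administered in every wave.
#'
#' Factor assignment is round-robin: item j goes to factor
#' ((j - 1) mod m) + 1, so factors receive near-equal item counts.
#'
#' @param config a \code{\link{generator_config}}.
#' @return An object of class \code{"item_catalog"}: a list with
#'   \code{items} (data frame: item_id, n_cat, direction, factor,
#'   factor2) and \code{availability} (items x waves logical matrix).
#' @examples
#' cat45 <- build_item_catalog(generator_config(n_persons = 10))
#' length(classify_items(cat45)$anchor_set)  # 39 under the defaults
#' @export
build_item_catalog <- function(config) {
  validate_generator_config(config)
  n_items <- config$n_items
  m <- config$n_first_order_factors
  set.seed(config$seed + 11L)

  item_id <- sprintf("item%02d", seq_len(n_items))
  fac <- ((seq_len(n_items) - 1L) %% m) + 1L
  fac2 <- rep(NA_integer_, n_items)
  if (config$n_crossload > 0 && m >= 2) {
    cross <- sample(n_items, min(config$n_crossload, n_items))
    fac2[cross] <- vapply(fac[cross], function(f) {
      sample(setdiff(seq_len(m), f), 1L)
    }, integer(1))
  }

  avail <- matrix(TRUE, n_items, config$n_waves,
                  dimnames = list(item_id, paste0("wave", seq_len(config$n_waves))))
  if (config$n_varying > 0) {
    varying <- seq(n_items - config$n_varying + 1L, n_items)
    for (i in varying) {
      # drop the item from a random non-empty subset of waves 2..n_waves
      k <- sample(config$n_waves - 1L, 1L)
      out_waves <- 1L + sample(config$n_waves - 1L, k)
      avail[i, out_waves] <- FALSE
    }
  }

  structure(list(
    items = data.frame(item_id = item_id,
                       n_cat = config$categories_per_item,
                       direction = "higher_is_worse",
                       factor = fac, factor2 = fac2,
                       stringsAsFactors = FALSE),
    availability = avail
  ), class = "item_catalog")
}

#' Split catalog items into anchor and wave-varying sets
#'
#' Anchor items are administered in every wave and carry the common scale
#' that links wave-specific metrics; any item absent from at least one
#' wave is wave-varying.
#'
#' @param catalog an \code{"item_catalog"}.
#' @return List with character vectors \code{anchor_set} and
#'   \code{varying_set}; their union is all items and they are disjoint.
#' @export
classify_items <- function(catalog) {
  stopifnot(inherits(catalog, "item_catalog"))
  all_waves <- apply(catalog$availability, 1, all)
  list(anchor_set = rownames(catalog$availability)[all_waves],
       varying_set = rownames(catalog$availability)[!all_waves])
}

#' @export
print.item_catalog <- function(x, ...) {
  cls <- classify_items(x)
  cat("Item catalog:", nrow(x$items), "items over",
      ncol(x$availability), "waves;",
      length(cls$anchor_set), "anchor,",
      length(cls$varying_set), "wave-varying\n")
  invisible(x)
}
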