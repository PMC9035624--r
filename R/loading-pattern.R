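#' Between-item loading pattern
#'
#' Assigns each item to exactly one specific dimension. In a between-item
#' multidimensional test every item measures a single specific latent trait;
#' groups of items measure different traits, and (in the bi-factor models)
#' all items additionally load on a general trait. The pattern is the
#' 0/1 matrix S with one 1 per row; here it is stored compactly as the
#' integer map item -> dimension.
#'
#' @param group_of integer vector, one entry per item, giving the specific
#'   dimension (1..`n_specific`) the item loads on.
#' @param n_specific number of specific dimensions; defaults to
#'   `max(group_of)`.
#' @param item_ids optional character item identifiers (defaults to
#'   `item1..itemm`).
#' @return an object of class `loading_pattern` with fields `n_items`,
#'   `n_specific`, `group_of`, `item_ids`.
#' @examples
#' p <- loading_pattern(rep(1:3, each = 10))
#' as_loading_matrix(p)[1:3, ]
#' @export
loading_pattern <- function(group_of, n_specific = max(group_of),
                            item_ids = NULL) {
  group_of <- as.integer(group_of)
  if (length(group_of) < 1L || anyNA(group_of))
    stop("`group_of` must be a non-empty integer vector without NA")
  if (any(group_of < 1L) || any(group_of > n_specific))
    stop("each item must map to a dimension in 1..n_specific")
  if (!all(seq_len(n_specific) %in% group_of))
    stop("every specific dimension must have at least one item")
  if (is.null(item_ids)) item_ids <- paste0("item", seq_along(group_of))
  item_ids <- as.character(item_ids)
  if (anyDuplicated(item_ids)) stop("duplicate item ids in loading pattern")
  if (length(item_ids) != length(group_of))
    stop("`item_ids` must have one entry per item")
  structure(
    list(n_items = length(group_of), n_specific = as.integer(n_specific),
         group_of = group_of, item_ids = item_ids),
    class = "loading_pattern")
}

#' Expand a loading pattern to its 0/1 indicator matrix
#'
#' @param pattern a [loading_pattern()].
#' @return an `n_items` x `n_specific` 0/1 matrix with exactly one 1 per row.
#' @export
as_loading_matrix <- function(pattern) {
  stopifnot(inherits(pattern, "loading_pattern"))
  S <- matrix(0L, pattern$n_items, pattern$n_specific,
              dimnames = list(pattern$item_ids,
                              paste0("dim", seq_len(pattern$n_specific))))
  S[cbind(seq_len(pattern$n_items), pattern$group_of)] <- 1L
  S
}

#' @export
print.loading_pattern <- function(x, ...) {
  cat("Between-item loading pattern:", x$n_items, "items,",
      x$n_specific, "specific dimensions\n")
  cat("items per dimension:", paste(tabulate(x$group_of, x$n_specific),
                                    collapse = ", "), "\n")
  invisible(x)
}
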