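#' The seven momentary mental-state items
#'
#' Builds the default catalog of the seven ecological momentary assessment
#' (EMA) items used throughout the package: three depression-cluster items
#' (feeling listless, feeling down, not feeling cheerful), two
#' anxiety-cluster items (feeling nervous, not feeling relaxed), and two
#' overlapping items that belong to both clusters (worrying, feeling
#' irritated). "Not cheerful" and "not relaxed" are recorded from
#' positively worded prompts and therefore carry a reverse-coding flag.
#'
#' @return An object of class \code{item_catalog}: a data frame with one
#'   row per item and columns \code{code}, \code{label}, \code{dep},
#'   \code{anx} (logical cluster memberships) and \code{reverse_coded}.
#'   Row order fixes the variable ordering used by every array in the
#'   package.
#' @examples
#' cat7 <- item_catalog()
#' cat7$code
#' @export
item_catalog <- function() {
  items <- data.frame(
    code = c("REL", "CHE", "IRR", "LIS", "DOW", "NER", "WOR"),
    label = c("not relaxed", "not cheerful", "irritated", "listless",
              "down", "nervous", "worrying"),
    dep = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    anx = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
    reverse_coded = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  new_item_catalog(items)
}

#' Construct and validate an item catalog
#'
#' Lower-level constructor used by [item_catalog()] and by tests that
#' exercise the path enumerator on arbitrary item/cluster configurations.
#' Each item must belong to at least one of the two clusters.
#'
#' @param items Data frame with columns \code{code}, \code{label},
#'   \code{dep}, \code{anx}, \code{reverse_coded}.
#' @return A validated \code{item_catalog}.
#' @export
new_item_catalog <- function(items) {
  stopifnot(is.data.frame(items),
            all(c("code", "label", "dep", "anx", "reverse_coded") %in%
                  names(items)))
  if (anyDuplicated(items$code) > 0L) {
    stop("item codes must be unique")
  }
  if (any(!items$dep & !items$anx)) {
    stop("every item must belong to at least one cluster")
  }
  rownames(items) <- NULL
  class(items) <- c("item_catalog", "data.frame")
  items
}

#' @export
print.item_catalog <- function(x, ...) {
  cluster <- ifelse(x$dep & x$anx, "overlapping",
                    ifelse(x$dep, "depression", "anxiety"))
  out <- data.frame(code = x$code, label = x$label, cluster = cluster,
                    reverse_coded = x$reverse_coded)
  cat(sprintf("Item catalog (%d items)\n", nrow(x)))
  print(out, row.names = FALSE)
  invisible(x)
}

# membership set of one item as a character vector in {"DEP","ANX"}
item_membership <- function(catalog, code) {
  i <- match(code, catalog$code)
  if (is.na(i)) stop(sprintf("unknown item code '%s'", code))
  c("DEP", "ANX")[c(catalog$dep[i], catalog$anx[i])]
}

item_codes <- function(catalog) catalog$code
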