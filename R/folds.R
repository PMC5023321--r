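#' Grouped k-fold assignment
#'
#' Partitions subjects into `k` folds such that all members of a group
#' (e.g. a family) share one fold, preventing dependence-driven leakage
#' between training and test sets. Groups are shuffled deterministically by
#' `seed` and assigned greedily, largest group first, each to the currently
#' smallest fold, so fold sizes differ by at most the largest group size.
#'
#' @param groupIds Vector of group labels, one per subject. Singleton labels
#'   give ordinary (ungrouped) k-fold assignment.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the shuffle; the assignment is a
#'   deterministic function of `groupIds`, `k` and `seed`.
#' @return Integer vector of fold indices in `1..k`, one per subject, with
#'   `groupIds` retained as the `"groups"` attribute.
#' @examples
#' groupedKFold(c(1, 1, 2, 3, 4, 5), k = 2, seed = 7)
#' @export
groupedKFold <- function(groupIds, k = 10, seed = 1) {
  groupIds <- as.character(groupIds)
  if (k < 2) stop("k must be >= 2")
  groups <- unique(groupIds)
  if (length(groups) < k)
    stop("fewer distinct groups (", length(groups), ") than folds (", k, ")")
  sizes <- table(groupIds)[groups]
  ord <- .withSeed(seed, sample.int(length(groups)))
  groups <- groups[ord]
  sizes <- as.integer(sizes[ord])
  ord2 <- order(-sizes)            # largest first; ties keep shuffled order
  groups <- groups[ord2]
  sizes <- sizes[ord2]
  foldSize <- integer(k)
  groupFold <- integer(length(groups))
  for (i in seq_along(groups)) {
    f <- which.min(foldSize)
    groupFold[i] <- f
    foldSize[f] <- foldSize[f] + sizes[i]
  }
  folds <- groupFold[match(groupIds, groups)]
  attr(folds, "groups") <- groupIds
  folds
}
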