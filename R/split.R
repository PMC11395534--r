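# Intuitive-rational train/test split.
#
# Each source group (the compounds contributed by one publication/assay) is
# ordered by increasing activity; test compounds are picked at evenly spaced
# ranks symmetric about the group median, and the most and least active
# compound of every group always stay in the training set. Per-group test
# counts follow largest-remainder allocation of the overall test fraction.

#' Intuitive-rational train/test split
#'
#' @param data A data.frame with columns `name`, `group` and `pic50` (extra
#'   columns are carried along).
#' @param test_fraction Target fraction of compounds in the test set,
#'   in (0, 0.5).
#' @return A list with data.frames `train` and `test`; their union is `data`
#'   and the per-group activity extremes are always in `train`. Deterministic:
#'   activity ties are broken by compound name.
#' @examples
#' d <- data.frame(name = paste0("m", 1:10), group = "a", pic50 = 1:10 / 2)
#' s <- intuitive_rational_split(d, 0.2)
#' nrow(s$test)  # 2
#' @export
intuitive_rational_split <- function(data, test_fraction = 0.2) {
  stopifnot(is.data.frame(data),
            all(c("name", "group", "pic50") %in% names(data)))
  if (!(test_fraction > 0 && test_fraction < 0.5)) {
    stop("test_fraction must be in (0, 0.5)")
  }
  groups <- split(data, data$group)
  sizes <- vapply(groups, nrow, integer(1))
  n_total <- sum(sizes)
  m_total <- round(test_fraction * n_total)

  # largest-remainder allocation, capped so both extremes stay in training
  quota <- sizes * test_fraction
  alloc <- floor(quota)
  cap <- pmax(sizes - 2L, 0L)
  alloc <- pmin(alloc, cap)
  remainder_order <- order(-(quota - floor(quota)), names(sizes))
  while (sum(alloc) < m_total) {
    progressed <- FALSE
    for (g in remainder_order) {
      if (sum(alloc) >= m_total) break
      if (alloc[g] < cap[g]) { alloc[g] <- alloc[g] + 1L; progressed <- TRUE }
    }
    if (!progressed) break   # every group at its cap
  }

  test_rows <- list()
  train_rows <- list()
  for (gname in names(groups)) {
    gd <- groups[[gname]]
    gd <- gd[order(gd$pic50, gd$name), , drop = FALSE]
    g <- nrow(gd)
    m <- alloc[[gname]]
    picks <- integer(0)
    if (m > 0L) {
      # evenly spaced 0-based ranks, symmetric about the median,
      # nudged off both extremes
      ranks <- round(seq_len(m) * (g - 1) / (m + 1))
      ranks <- pmin(pmax(ranks, 1L), g - 2L)
      while (anyDuplicated(ranks)) {       # de-clash for tiny groups
        dup <- which(duplicated(ranks))[1]
        ranks[dup] <- min(ranks[dup] + 1L, g - 2L)
        if (anyDuplicated(ranks) &&
            all(ranks == g - 2L | !duplicated(ranks))) break
      }
      picks <- unique(ranks) + 1L          # to 1-based row index
    }
    test_rows[[gname]] <- gd[picks, , drop = FALSE]
    train_rows[[gname]] <- gd[setdiff(seq_len(g), picks), , drop = FALSE]
  }
  list(train = do.call(rbind, c(train_rows, list(make.row.names = FALSE))),
       test = do.call(rbind, c(test_rows, list(make.row.names = FALSE))))
}
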