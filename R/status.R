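#' Rank a component measure within a triad
#'
#' Converts raw per-member measures (floor seconds, topic counts, judge
#' scores, peer ratings) to 1-3 component ranks. By default a higher raw value
#' means a better (lower-numbered) rank. Within-component ties share the
#' better rank, keeping the 1-3 scale: `(200, 200, 100)` ranks `(1, 1, 3)`.
#'
#' @param x numeric vector of raw measures (one per member).
#' @param higher_better logical; if `FALSE`, lower raw values rank better.
#' @return Integer ranks, same length and names as `x`.
#' @export
rank_components <- function(x, higher_better = TRUE) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  s <- if (higher_better) -x else x
  r <- rank(s, ties.method = "min")
  stats::setNames(as.integer(r), names(x))
}

#' Compare two triad members across status components
#'
#' A pair is consistently differentiated only when at least
#' `ceiling(threshold_frac * n_components)` components (4 of the full 7)
#' strictly rank one member better than the other; otherwise the pair is a
#' tie. Under `strict = TRUE` the winner must additionally have no component
#' reversed against them.
#'
#' @param components numeric matrix of component ranks, rows = components,
#'   columns = members (column names are member ids). `NA` components for a
#'   pair are skipped and the threshold is taken on the components available.
#' @param a,b member identifiers (column names), `a != b`.
#' @param threshold_frac fraction of available components that must agree.
#' @param strict logical; require zero reversals in addition to the count.
#' @return One of `"a_over_b"`, `"b_over_a"`, `"tie"`.
#' @export
pairwise_compare <- function(components, a, b, threshold_frac = 4 / 7,
                             strict = FALSE) {
  if (identical(a, b)) stop("cannot compare a member with itself", call. = FALSE)
  if (!all(c(a, b) %in% colnames(components))) {
    stop("both members must be columns of `components`", call. = FALSE)
  }
  ra <- components[, a]
  rb <- components[, b]
  ok <- !is.na(ra) & !is.na(rb)
  ra <- ra[ok]; rb <- rb[ok]
  if (length(ra) == 0) return("tie")
  need <- ceiling(threshold_frac * length(ra))
  a_wins <- sum(ra < rb)
  b_wins <- sum(rb < ra)
  if (a_wins >= need && (!strict || b_wins == 0)) return("a_over_b")
  if (b_wins >= need && (!strict || a_wins == 0)) return("b_over_a")
  "tie"
}

#' Aggregate component ranks into final triad status ranks
#'
#' Evaluates the three pairwise comparisons and assigns final ranks: a full
#' order gives `(1, 2, 3)` (`transitive`); a tied top pair that both dominate
#' the third gives `(1.5, 1.5, 3)` (`top_tie`); a tied bottom pair gives
#' `(1, 2.5, 2.5)` (`bottom_tie`); three ties give `(2, 2, 2)` (`flat`). Each
#' member's rank is `1 + wins-against-them + 0.5 * ties`, so ranks always sum
#' to 6. Any other (cyclic or partially inconsistent) pattern is classed
#' `unresolved` and falls back to the average-tie ranking of mean component
#' rank, flagged rather than failing.
#'
#' @inheritParams pairwise_compare
#' @return List with `ranks` (named numeric, one per member) and
#'   `hierarchy_class` (one of `transitive`, `top_tie`, `bottom_tie`, `flat`,
#'   `unresolved`).
#' @export
aggregate_ranks <- function(components, threshold_frac = 4 / 7, strict = FALSE) {
  members <- colnames(components)
  stopifnot(length(members) == 3)
  pairs <- utils::combn(members, 2, simplify = FALSE)
  res <- lapply(pairs, function(p) {
    pairwise_compare(components, p[1], p[2], threshold_frac = threshold_frac,
                     strict = strict)
  })
  losses <- stats::setNames(numeric(3), members)
  ties <- stats::setNames(numeric(3), members)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (res[[i]] == "a_over_b") losses[p[2]] <- losses[p[2]] + 1
    else if (res[[i]] == "b_over_a") losses[p[1]] <- losses[p[1]] + 1
    else { ties[p[1]] <- ties[p[1]] + 1; ties[p[2]] <- ties[p[2]] + 1 }
  }
  ranks <- 1 + losses + 0.5 * ties
  n_tie <- sum(unlist(res) == "tie")
  cls <- if (n_tie == 3) {
    "flat"
  } else if (n_tie == 0 && setequal(ranks, c(1, 2, 3))) {
    "transitive"
  } else if (n_tie == 1 && setequal(ranks, c(1.5, 1.5, 3))) {
    "top_tie"
  } else if (n_tie == 1 && setequal(ranks, c(1, 2.5, 2.5))) {
    "bottom_tie"
  } else {
    "unresolved"
  }
  if (cls == "unresolved") {
    ranks <- rank(colMeans(components, na.rm = TRUE), ties.method = "average")
    ranks <- stats::setNames(as.numeric(ranks), members)
  }
  list(ranks = ranks, hierarchy_class = cls)
}

#' Aggregate status ranks across a table of triads
#'
#' Tidy wrapper over [aggregate_ranks()]: takes the long component table
#' (one row per triad x component x member) and returns one row per member.
#'
#' @param components_tbl tibble with columns `triad_id`, `component`,
#'   `subject_id`, `rank`.
#' @inheritParams pairwise_compare
#' @return Tibble `triad_id`, `subject_id`, `final_rank`, `hierarchy_class`.
#' @export
aggregate_status <- function(components_tbl, threshold_frac = 4 / 7,
                             strict = FALSE) {
  components_tbl |>
    dplyr::group_by(.data$triad_id) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(d, names_from = "subject_id",
                                 values_from = "rank")
      mat <- as.matrix(wide[, setdiff(names(wide), "component"), drop = FALSE])
      rownames(mat) <- wide$component
      agg <- aggregate_ranks(mat, threshold_frac = threshold_frac, strict = strict)
      tibble::tibble(subject_id = names(agg$ranks),
                     final_rank = unname(agg$ranks),
                     hierarchy_class = agg$hierarchy_class)
    }) |>
    dplyr::ungroup()
}

#' Tally tied pairs across triads
#'
#' Each triad contributes three member pairs; a pair is tied when the two
#' members share the same final rank.
#'
#' @param ranks_tbl output of [aggregate_status()].
#' @return One-row tibble `n_triads`, `n_pairs`, `n_ties`.
#' @export
tally_ties <- function(ranks_tbl) {
  if (nrow(ranks_tbl) == 0) {
    return(tibble::tibble(n_triads = 0L, n_pairs = 0L, n_ties = 0L))
  }
  per <- ranks_tbl |>
    dplyr::group_by(.data$triad_id) |>
    dplyr::summarise(
      ties = sum(utils::combn(.data$final_rank, 2, FUN = function(p) p[1] == p[2])),
      .groups = "drop")
  tibble::tibble(n_triads = nrow(per),
                 n_pairs = 3L * nrow(per),
                 n_ties = as.integer(sum(per$ties)))
}
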