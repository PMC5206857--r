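#' Sequential-pattern sample selection
#'
#' Annotated event-extraction corpora are dominated by negative
#' trigger-argument pairs (roughly 13 negatives per positive).  Instead of
#' class weighting, the training set is balanced by keeping only the
#' unlabeled candidates whose dependency-label path resembles the paths of
#' annotated (positive) pairs: the paths of all labeled pairs form a
#' sequence database, frequent sequential patterns are mined from it, and a
#' candidate is kept when strictly more than \code{theta} mined patterns
#' are subsequences of its own path.
#'
#' @name sample_select
NULL

#' Build the sequence database from labeled pairs
#'
#' One database sequence per labeled positive pair, in input order
#' (multiset semantics: two pairs sharing a path contribute two sequences).
#' Pairs without a dependency path between trigger and argument are
#' skipped; the number skipped is attached as attribute \code{"skipped"}.
#'
#' @param labeled A data.frame of labeled candidate pairs with a list-column
#'   \code{path} (character vectors of dependency labels), or a bare list of
#'   such vectors.
#' @return A list of character vectors (the sequence database) with
#'   attribute \code{"skipped"}.
#' @export
build_sequence_db <- function(labeled) {
  paths <- if (is.data.frame(labeled)) labeled$path else labeled
  if (is.null(paths)) stop("'labeled' must carry a 'path' list-column")
  ok <- vapply(paths, function(p) !is.null(p) && length(p) > 0L && !anyNA(p),
               logical(1L))
  db <- lapply(paths[ok], as.character)
  attr(db, "skipped") <- sum(!ok)
  db
}

#' Pattern match count of a dependency path
#'
#' The number of mined patterns that are subsequences of \code{path}
#' (the path itself counts when it is in the pattern set).
#'
#' @param path Character vector of dependency labels.
#' @param ls A \code{pattern_set} from [mine_frequent_patterns()].
#' @return Integer count in \code{0:length(ls$patterns)}.
#' @export
match_count <- function(path, ls) {
  stopifnot(inherits(ls, "pattern_set"))
  sum(vapply(ls$patterns, function(p) is_subsequence(p, path), logical(1L)))
}

#' Select unlabeled candidates by pattern match count
#'
#' Keeps exactly the candidates whose match count strictly exceeds
#' \code{theta}, preserving input order.  Candidates without a path are
#' discarded (no match count is defined for them, and pathless pairs are
#' overwhelmingly negative).
#'
#' @param candidates Data.frame of candidates with a \code{path}
#'   list-column (and optionally a \code{label} column, used only for the
#'   kept/discarded report).
#' @param ls A \code{pattern_set}.
#' @param theta Non-negative count threshold; a candidate is selected when
#'   its match count is \code{> theta}.
#' @return The selected subset of \code{candidates}, with a
#'   \code{"selection_report"} attribute (kept/discarded counts and, when
#'   labels are present, the positive:negative ratio before and after).
#' @export
select_samples <- function(candidates, ls, theta) {
  stopifnot(inherits(ls, "pattern_set"), theta >= 0)
  paths <- candidates$path
  has_path <- vapply(paths, function(p) !is.null(p) && length(p) > 0L, logical(1L))
  f <- rep(0L, nrow(candidates))
  f[has_path] <- vapply(paths[has_path], match_count, integer(1L), ls = ls)
  keep <- has_path & f > theta
  out <- candidates[keep, , drop = FALSE]
  report <- list(
    n_in = nrow(candidates), n_kept = sum(keep),
    n_discarded = sum(!keep), n_pathless = sum(!has_path), theta = theta
  )
  if (!is.null(candidates$label)) {
    pos_in <- sum(candidates$label != "negative")
    neg_in <- sum(candidates$label == "negative")
    pos_out <- sum(out$label != "negative")
    neg_out <- sum(out$label == "negative")
    report <- c(report, list(
      pos_in = pos_in, neg_in = neg_in, pos_out = pos_out, neg_out = neg_out,
      ratio_in = if (pos_in > 0) neg_in / pos_in else NA_real_,
      ratio_out = if (pos_out > 0) neg_out / pos_out else NA_real_
    ))
  }
  attr(out, "selection_report") <- report
  out
}

#' Select candidate triplets by pattern match count
#'
#' A triplet carries two trigger-to-argument paths.  Under the default
#' \code{rule = "both"} a triplet is kept when each path individually
#' passes the pair criterion (match count \code{> theta}); under
#' \code{rule = "sum"} when the two match counts together exceed
#' \code{2 * theta}.
#'
#' @param triplets Data.frame with list-columns \code{path1} and
#'   \code{path2}.
#' @param ls A \code{pattern_set}.
#' @param theta Non-negative count threshold.
#' @param rule \code{"both"} (conservative AND, the default) or
#'   \code{"sum"}.
#' @return The selected subset of \code{triplets}.
#' @export
filter_triplet_candidates <- function(triplets, ls, theta, rule = c("both", "sum")) {
  rule <- match.arg(rule)
  stopifnot(inherits(ls, "pattern_set"), theta >= 0)
  count_one <- function(p) {
    if (is.null(p) || length(p) == 0L) return(NA_integer_)
    match_count(p, ls)
  }
  f1 <- vapply(triplets$path1, count_one, integer(1L))
  f2 <- vapply(triplets$path2, count_one, integer(1L))
  keep <- if (rule == "both") {
    !is.na(f1) & !is.na(f2) & f1 > theta & f2 > theta
  } else {
    !is.na(f1) & !is.na(f2) & (f1 + f2) > 2 * theta
  }
  triplets[keep, , drop = FALSE]
}
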