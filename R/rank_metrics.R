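# Per-group ranking construction and the four-metric evaluation suite:
# rank MAE, Spearman correlation, nDCG, and top-1 frequency, each averaged
# over conformer groups with a normal-approximation 95% confidence
# interval on the mean.

#' Rank the members of one conformer group with a scorer
#'
#' Each member is scored once by the shared Siamese branch and the group is
#' sorted by score.  Because the pair head is an exactly antisymmetric
#' function of the score difference, sorting by branch score is equivalent
#' to aggregating all pairwise outranking probabilities.  With
#' `orientation = "ascending"` (the default, appropriate for energies,
#' where the best structure is the minimum) the lowest score is ranked
#' first; `"descending"` reverses that.  Score ties are broken stably by
#' structure id.  True ranks come from the property values in the same
#' orientation, with average ranks on ties.
#'
#' @param scorer a function mapping a `Structure` to a numeric score, or a
#'   model accepted by [as_scorer()].
#' @param group a `ConformerGroup`.
#' @param property_name property defining the true ranking.
#' @param orientation `"ascending"` (rank 1 = smallest) or `"descending"`.
#' @return a `RankingResult`: data.frame with `group_id`, `structure_id`
#'   (predicted best first), `score`, `pred_rank`, `true_rank`.
#' @export
rank_group <- function(scorer, group, property_name,
                       orientation = c("ascending", "descending")) {
  orientation <- match.arg(orientation)
  if (!is.function(scorer)) scorer <- as_scorer(scorer)
  structs <- group$structures
  n <- length(structs)
  sid <- vapply(structs, function(s) s$structure_id, character(1))
  scores <- vapply(structs, function(s) as.numeric(scorer(s)), numeric(1))
  truth <- vapply(structs, function(s) {
    v <- s$properties[[property_name]]
    if (is.null(v)) {
      stop("structure '", s$structure_id, "' lacks property '",
           property_name, "'")
    }
    as.numeric(v)
  }, numeric(1))
  sgn <- if (orientation == "ascending") 1 else -1
  ord <- order(sgn * scores, sid)
  pred_rank <- integer(n)
  pred_rank[ord] <- seq_len(n)
  true_rank <- rank(sgn * truth, ties.method = "average")
  out <- data.frame(group_id = group$group_id, structure_id = sid[ord],
                    score = scores[ord], pred_rank = seq_len(n),
                    true_rank = true_rank[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("RankingResult", class(out))
  out
}

#' Mean absolute error between two rankings
#'
#' Mean over items of the absolute difference between predicted and true
#' rank positions.
#'
#' @param predicted_ranks,true_ranks numeric rank vectors of equal length
#'   (1-based positions; true ranks may carry average ranks on ties).
#' @return non-negative numeric.
#' @export
rank_mae <- function(predicted_ranks, true_ranks) {
  if (length(predicted_ranks) != length(true_ranks)) {
    stop("rank vectors differ in length")
  }
  mean(abs(predicted_ranks - true_ranks))
}

#' Spearman correlation between two rankings
#'
#' The Pearson correlation applied to rank vectors; ties receive average
#' ranks.  Undefined (returned as `NA`) when either vector has zero
#' variance.
#'
#' @param predicted_ranks,true_ranks numeric rank vectors of equal
#'   length >= 2.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman <- function(predicted_ranks, true_ranks) {
  if (length(predicted_ranks) != length(true_ranks)) {
    stop("rank vectors differ in length")
  }
  if (length(predicted_ranks) < 2L) stop("need at least 2 items")
  x <- rank(predicted_ranks, ties.method = "average")
  y <- rank(true_ranks, ties.method = "average")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Normalised discounted cumulative gain of a predicted ordering
#'
#' The relevance of the item with true rank `r` is `n - r` (linear gain:
#' the true best item is most relevant); the gain of the item placed at
#' predicted position `k` is discounted by `log2(k + 1)`, and the sum is
#' normalised by the ideal ordering's DCG.  Tied true ranks yield grouped
#' (equal) relevances.
#'
#' @param true_ranks_in_pred_order true rank positions listed in predicted
#'   order (predicted best first).
#' @return value in `[0, 1]`; 1 for a single item.
#' @export
ndcg <- function(true_ranks_in_pred_order) {
  n <- length(true_ranks_in_pred_order)
  if (n < 1L) stop("need at least one item")
  if (n == 1L) return(1)
  rel <- n - true_ranks_in_pred_order
  disc <- 1 / log2(seq_len(n) + 1)
  dcg <- sum(rel * disc)
  idcg <- sum(sort(rel, decreasing = TRUE) * disc)
  if (idcg == 0) return(1)
  dcg / idcg
}

#' Top-1 frequency over a set of rankings
#'
#' Fraction of groups whose predicted first item is a true best item
#' (any member tied for the minimum true rank counts as correct).
#'
#' @param rankings list of `RankingResult` objects.
#' @return value in `[0, 1]`.
#' @export
top1_frequency <- function(rankings) {
  if (!length(rankings)) stop("need at least one group")
  hits <- vapply(rankings, function(r) {
    r$true_rank[1] == min(r$true_rank)
  }, logical(1))
  mean(hits)
}

#' Summarise per-group metric values
#'
#' Mean, sample standard deviation, and normal-approximation 95% CI
#' half-width (`1.96 * sd / sqrt(n)`) across groups; missing values (e.g.
#' undefined Spearman) are dropped and counted.
#'
#' @param per_group_values numeric vector, possibly with `NA`s.
#' @return list with `mean`, `sd`, `ci95`, `n`, `n_missing`.
#' @export
summarize_metric <- function(per_group_values) {
  miss <- sum(is.na(per_group_values))
  x <- per_group_values[!is.na(per_group_values)]
  n <- length(x)
  mu <- if (n) mean(x) else NA_real_
  sdev <- if (n >= 2L) stats::sd(x) else NA_real_
  ci <- if (n >= 2L) 1.96 * sdev / sqrt(n) else NA_real_
  list(mean = mu, sd = sdev, ci95 = ci, n = n, n_missing = miss)
}

#' Evaluate a scorer on conformer groups with the four ranking metrics
#'
#' Ranks every group with [rank_group()] and aggregates rank MAE, Spearman
#' correlation, nDCG, and top-1 frequency across groups.
#'
#' @inheritParams rank_group
#' @param groups list of `ConformerGroup`.
#' @return a `MetricReport`: list with `report` (data.frame: metric, mean,
#'   sd, ci95, n), `per_group` (data.frame of per-group metric values), and
#'   `rankings` (list of `RankingResult`).
#' @export
evaluate_ranking <- function(scorer, groups, property_name,
                             orientation = c("ascending", "descending")) {
  orientation <- match.arg(orientation)
  if (!is.function(scorer)) scorer <- as_scorer(scorer)
  rankings <- lapply(groups, function(g) {
    rank_group(scorer, g, property_name, orientation)
  })
  per_group <- data.frame(
    group_id = vapply(rankings, function(r) r$group_id[1], character(1)),
    rank_mae = vapply(rankings, function(r) {
      rank_mae(r$pred_rank, r$true_rank)
    }, numeric(1)),
    spearman = vapply(rankings, function(r) {
      if (nrow(r) < 2L) NA_real_ else spearman(r$pred_rank, r$true_rank)
    }, numeric(1)),
    ndcg = vapply(rankings, function(r) ndcg(r$true_rank), numeric(1)),
    top1 = vapply(rankings, function(r) {
      as.numeric(r$true_rank[1] == min(r$true_rank))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rows <- lapply(c("rank_mae", "spearman", "ndcg", "top1"), function(mname) {
    s <- summarize_metric(per_group[[mname]])
    data.frame(metric = mname, mean = s$mean, sd = s$sd, ci95 = s$ci95,
               n = s$n, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  structure(list(report = report, per_group = per_group,
                 rankings = rankings, orientation = orientation,
                 property = property_name),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat("<MetricReport> property=", x$property, " groups=",
      nrow(x$per_group), "\n", sep = "")
  print(transform(x$report, mean = signif(mean, 4), sd = signif(sd, 4),
                  ci95 = signif(ci95, 4)), row.names = FALSE)
  invisible(x)
}

#' Write a metric report to disk
#'
#' Writes the aggregated table as CSV and as JSON, and optionally the
#' per-group rankings as CSV.
#'
#' @param x a `MetricReport`.
#' @param csv,json,rankings_csv output paths (`NULL` skips a file).
#' @return invisibly, the list of paths written.
#' @export
write_metric_report <- function(x, csv = NULL, json = NULL,
                                rankings_csv = NULL) {
  written <- character(0)
  if (!is.null(csv)) {
    utils::write.csv(x$report, csv, row.names = FALSE)
    written <- c(written, csv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(property = x$property, orientation = x$orientation,
           metrics = x$report, per_group = x$per_group),
      json, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    written <- c(written, json)
  }
  if (!is.null(rankings_csv)) {
    all <- do.call(rbind, lapply(x$rankings, as.data.frame))
    utils::write.csv(all, rankings_csv, row.names = FALSE)
    written <- c(written, rankings_csv)
  }
  invisible(written)
}
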