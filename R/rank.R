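#' Rank-based single-sample gene-set score
#'
#' For each sample, all genes are ranked ascending by expression (ties get
#' average ranks) and the mean rank of the set's matched genes is rescaled
#' to `[0, 1]` by its theoretical extremes: with `N` genes and `m` matched
#' set genes the minimum attainable mean rank is `(m + 1) / 2` (set at the
#' bottom) and the maximum is `(2N - m + 1) / 2` (set at the top).
#' `direction = "down"` reverses the ranking, so
#' `score_down = 1 - score_up` exactly. Being rank-based, the score is
#' invariant to any strictly increasing per-sample transform of expression.
#'
#' @param expr An [expression_matrix].
#' @param set A [gene_set].
#' @param direction `"up"` (high expression of set genes scores high) or
#'   `"down"`.
#' @return Named numeric vector of per-sample scores in `[0, 1]`, with
#'   attribute `matched_genes`.
#' @export
rank_set_score <- function(expr, set, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(expr, "expression_matrix"), inherits(set, "gene_set"))
  n_genes <- nrow(expr)
  matched <- intersect(set$members, rownames(expr))
  m <- length(matched)
  if (m == 0L) stop("gene set '", set$name, "': no members in the matrix")
  if (m == n_genes)
    stop("gene set '", set$name, "' covers every gene; the rank score is ",
         "undefined (zero denominator)")
  ranks <- apply(unclass(expr), 2L, rank)  # average ranks for ties
  rbar <- colMeans(ranks[matched, , drop = FALSE])
  lo <- (m + 1) / 2
  hi <- (2 * n_genes - m + 1) / 2
  score <- (rbar - lo) / (hi - lo)
  if (direction == "down") score <- 1 - score
  structure(score, matched_genes = m)
}

#' EMT score: mesenchymal minus epithelial rank score
#'
#' The per-sample epithelial-to-mesenchymal transition score is the
#' difference between the mesenchymal gene-set rank score and the
#' epithelial gene-set rank score (both in the up direction), so it lies in
#' `[-1, 1]`: positive values indicate a mesenchymal-shifted profile.
#'
#' @param expr An [expression_matrix].
#' @param epithelial,mesenchymal [gene_set] objects.
#' @return Named numeric vector of per-sample EMT scores in `[-1, 1]`.
#' @export
emt_score <- function(expr, epithelial, mesenchymal) {
  score <- as.numeric(rank_set_score(expr, mesenchymal, "up")) -
    as.numeric(rank_set_score(expr, epithelial, "up"))
  stats::setNames(score, colnames(expr))
}
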