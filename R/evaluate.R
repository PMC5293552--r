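#' Edge ranking from a network fit
#'
#' Extracts the ranked edge list over the evaluable edge set: all ordered
#' molecule pairs excluding self edges (and, unless requested, excluding
#' perturbation-to-molecule edges, since curated gold standards usually
#' cover only molecule-molecule edges). The confidence score of an edge is
#' its posterior inclusion probability.
#'
#' @param fit A `network_fit`.
#' @param include_perturbation_edges Include perturbation-to-molecule edges?
#' @return Tibble with columns `source`, `target`, `score`.
#' @export
ranking_from_fit <- function(fit, include_perturbation_edges = FALSE) {
  ed <- tidy(fit)
  if (!include_perturbation_edges) ed <- ed[ed$edge_type == "molecule", ]
  tibble::tibble(source = ed$source, target = ed$target, score = ed$inclusion)
}

# joint table of scores and gold labels over the evaluable edge set;
# pairs absent from the ranking score 0
eval_table <- function(ranking, gold, include_perturbation_edges = FALSE) {
  ranking <- tibble::as_tibble(ranking)
  if (!all(c("source", "target", "score") %in% names(ranking))) {
    abort("`ranking` needs columns source, target, score.")
  }
  if (any(!is.finite(ranking$score))) abort("Edge scores must be finite.")
  if (anyDuplicated(ranking[c("source", "target")])) {
    abort("Each ordered (source, target) pair may appear at most once.")
  }
  mols <- gold$molecules
  univ <- tidyr::expand_grid(source = mols, target = mols) |>
    dplyr::filter(.data$source != .data$target)
  pos <- gold$edges
  if (include_perturbation_edges && !is.null(gold$target_map)) {
    perts <- names(gold$target_map)
    univ <- dplyr::bind_rows(univ,
      tidyr::expand_grid(source = perts, target = mols))
    pos <- dplyr::bind_rows(pos,
      tibble::tibble(source = rep(perts, lengths(gold$target_map)),
                     target = unlist(gold$target_map, use.names = FALSE)))
  }
  univ |>
    dplyr::left_join(ranking, by = c("source", "target")) |>
    dplyr::mutate(score = dplyr::coalesce(.data$score, 0),
                  label = as.integer(paste(.data$source, .data$target) %in%
                                       paste(pos$source, pos$target)))
}

#' Area under the ROC curve of an edge ranking
#'
#' Rank-based AUROC with ties contributing one half (the normalized
#' Mann-Whitney statistic), over the evaluable edge set.
#'
#' @param ranking Tibble with columns `source`, `target`, `score`.
#' @param gold A [gold_standard].
#' @param include_perturbation_edges Evaluate perturbation-target edges too?
#' @export
auroc <- function(ranking, gold, include_perturbation_edges = FALSE) {
  tab <- eval_table(ranking, gold, include_perturbation_edges)
  n1 <- sum(tab$label == 1); n0 <- sum(tab$label == 0)
  if (n1 == 0 || n0 == 0) {
    abort("Degenerate gold standard: need at least one positive and one negative edge.")
  }
  r <- rank(tab$score)
  (sum(r[tab$label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve of an edge ranking
#'
#' Average-precision (step-interpolation) convention, with tied scores
#' processed as one block: `AUPR = sum_k (R_k - R_(k-1)) P_k` over distinct
#' score thresholds `k`.
#'
#' @inheritParams auroc
#' @export
aupr <- function(ranking, gold, include_perturbation_edges = FALSE) {
  tab <- eval_table(ranking, gold, include_perturbation_edges)
  n1 <- sum(tab$label == 1)
  if (n1 == 0) abort("AUPR needs at least one positive edge in the gold standard.")
  blk <- tab |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(tp = sum(.data$label == 1), n = dplyr::n()) |>
    dplyr::arrange(dplyr::desc(.data$score))
  ctp <- cumsum(blk$tp); cn <- cumsum(blk$n)
  prec <- ctp / cn
  rec <- ctp / n1
  sum(diff(c(0, rec)) * prec)
}

#' ROC and precision-recall curves of an edge ranking
#'
#' Full monotone curves over distinct score thresholds; the trapezoid
#' integral of the ROC points equals [auroc] exactly.
#'
#' @inheritParams auroc
#' @return List of class `edge_curves` with tibbles `roc` (fpr, tpr,
#'   threshold) and `pr` (recall, precision, threshold).
#' @export
curves <- function(ranking, gold, include_perturbation_edges = FALSE) {
  tab <- eval_table(ranking, gold, include_perturbation_edges)
  n1 <- sum(tab$label == 1); n0 <- sum(tab$label == 0)
  if (n1 == 0 || n0 == 0) {
    abort("Degenerate gold standard: need at least one positive and one negative edge.")
  }
  blk <- tab |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(tp = sum(.data$label == 1), fp = sum(.data$label == 0)) |>
    dplyr::arrange(dplyr::desc(.data$score))
  ctp <- c(0, cumsum(blk$tp)); cfp <- c(0, cumsum(blk$fp))
  roc <- tibble::tibble(threshold = c(Inf, blk$score),
                        fpr = cfp / n0, tpr = ctp / n1)
  pr <- tibble::tibble(threshold = blk$score,
                       recall = cumsum(blk$tp) / n1,
                       precision = cumsum(blk$tp) / (cumsum(blk$tp) + cumsum(blk$fp)))
  structure(list(roc = roc, pr = pr,
                 auroc = auroc(ranking, gold, include_perturbation_edges),
                 aupr = aupr(ranking, gold, include_perturbation_edges)),
            class = "edge_curves")
}

#' Evaluate a ranking against a gold standard
#'
#' @inheritParams auroc
#' @return One-row tibble with `auroc`, `aupr`, `n_pos`, `n_neg`.
#' @export
evaluate_ranking <- function(ranking, gold, include_perturbation_edges = FALSE) {
  tab <- eval_table(ranking, gold, include_perturbation_edges)
  tibble::tibble(auroc = auroc(ranking, gold, include_perturbation_edges),
                 aupr = aupr(ranking, gold, include_perturbation_edges),
                 n_pos = sum(tab$label == 1), n_neg = sum(tab$label == 0))
}
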