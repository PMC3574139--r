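#' Pair counts between a clustering and a reference labeling
#'
#' Over all n(n-1)/2 unordered item pairs: SS = same cluster & same
#' category, SD = same cluster & different categories, DS = different
#' clusters & same category, DD = different in both. SS and DD are the
#' "good" pairs. Computed by contingency-table algebra (equal to brute-force
#' pair enumeration).
#'
#' @param pred_labels predicted cluster labels.
#' @param true_labels reference category labels, same length.
#' @return list of class `pair_counts` with `SS`, `SD`, `DS`, `DD`, `total`.
#' @export
pair_counts <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels)) {
    stop("label vectors must have equal length")
  }
  n <- length(pred_labels)
  if (n < 2) stop("pair counts need at least 2 items")
  if (anyNA(pred_labels) || anyNA(true_labels)) {
    stop("labels must not contain NA")
  }
  ct <- table(pred_labels, true_labels)
  ss <- sum(choose(ct, 2))
  same_pred <- sum(choose(rowSums(ct), 2))
  same_true <- sum(choose(colSums(ct), 2))
  total <- choose(n, 2)
  counts <- list(SS = ss, SD = same_pred - ss, DS = same_true - ss,
                 DD = total - same_pred - same_true + ss, total = total)
  structure(lapply(counts, as.numeric), class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("SS = %g  SD = %g  DS = %g  DD = %g  (total %g pairs)\n",
              x$SS, x$SD, x$DS, x$DD, x$total))
  invisible(x)
}

#' External cluster-validity indices from pair counts
#'
#' Rand = (SS + DD) / total; Jaccard = SS / (SS + SD + DS);
#' Fowlkes-Mallows = SS / sqrt((SS + SD)(SS + DS)). Jaccard and FM are
#' defined as 0 when their denominators vanish (degenerate partitions), so
#' evaluation never divides by zero.
#'
#' @param counts a [pair_counts()] result.
#' @return list of class `external_indices` with `rand`, `jaccard`, `fm`.
#' @export
external_indices <- function(counts) {
  stopifnot(inherits(counts, "pair_counts"))
  if (counts$total <= 0) stop("zero total pairs")
  with(counts, {
    jd <- SS + SD + DS
    fd <- sqrt((SS + SD) * (SS + DS))
    structure(list(rand = (SS + DD) / total,
                   jaccard = if (jd > 0) SS / jd else 0,
                   fm = if (fd > 0) SS / fd else 0),
              class = "external_indices")
  })
}

#' @export
print.external_indices <- function(x, ...) {
  cat(sprintf("Rand = %.4f  Jaccard = %.4f  FM = %.4f\n",
              x$rand, x$jaccard, x$fm))
  invisible(x)
}

#' Evaluate a clustering against reference labels
#'
#' Convenience wrapper: [pair_counts()] then [external_indices()].
#'
#' @inheritParams pair_counts
#' @return list with `counts` and `indices`.
#' @export
evaluate_clustering <- function(pred_labels, true_labels) {
  counts <- pair_counts(pred_labels, true_labels)
  list(counts = counts, indices = external_indices(counts))
}

#' Cohen's kappa for two nominal labelings
#'
#' Chance-corrected agreement between two annotators: kappa =
#' (p_o - p_e) / (1 - p_e), with p_o the fraction of identical labels and
#' p_e the agreement expected from the two marginal label distributions.
#' When p_e = 1 (both annotators constant), kappa is defined as 1 if they
#' agree and 0 otherwise.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return list of class `kappa_result` with `p_o`, `p_e`, `kappa`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  n <- length(labels_a)
  if (n < 1) stop("kappa needs at least 1 item")
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  p_o <- mean(labels_a == labels_b)
  cats <- union(labels_a, labels_b)
  ma <- vapply(cats, function(c) mean(labels_a == c), numeric(1))
  mb <- vapply(cats, function(c) mean(labels_b == c), numeric(1))
  p_e <- sum(ma * mb)
  kappa <- if (p_e >= 1 - 1e-12) {
    if (p_o >= 1 - 1e-12) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(list(p_o = p_o, p_e = p_e, kappa = kappa),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("observed = %.4f  expected = %.4f  kappa = %.4f\n",
              x$p_o, x$p_e, x$kappa))
  invisible(x)
}
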