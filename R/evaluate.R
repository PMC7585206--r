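#' Spearman correlation between two tie-free orders
#'
#' For permutations, Spearman's rho reduces to
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))` with `d` the rank differences.
#'
#' @param a,b integer permutations of the same length (splicing-time
#'   sequences).
#' @return rho in \[-1, 1\].
#' @export
order_spearman <- function(a, b) {
  n <- length(a)
  a <- check_permutation(a, n); b <- check_permutation(b, n)
  d <- order_rank(a) - order_rank(b)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Spearman correlation of a splicing order with transcription direction
#'
#' rho = 1 means perfectly in-order splicing (intron 1 first, intron n last);
#' rho = -1 means splicing in exact reverse of transcription.
#'
#' @param theta a permutation or fitted [splicing_order()].
#' @return rho in \[-1, 1\].
#' @export
spearman_to_transcription <- function(theta) {
  if (inherits(theta, "splicing_order")) theta <- theta$order
  order_spearman(theta, seq_along(theta))
}

#' Fraction of transcripts whose order was recovered exactly
#'
#' A transcript counts as recovered when the inferred most likely order is
#' identical to the true order (Spearman rho exactly 1) and the optimum is
#' unique; non-unique fits count as failures.
#'
#' @param true_orders named list of true permutations.
#' @param fits named list of fitted [splicing_order()] objects (or plain
#'   permutations, then assumed unique).
#' @return fraction in \[0, 1\].
#' @export
recovery_rate <- function(true_orders, fits) {
  if (!setequal(names(true_orders), names(fits)))
    stop("true orders and fits cover different transcript sets")
  hit <- vapply(names(true_orders), function(tid) {
    f <- fits[[tid]]
    if (inherits(f, "splicing_order")) {
      f$unique && identical(as.integer(f$order),
                            as.integer(true_orders[[tid]]))
    } else {
      identical(as.integer(f), as.integer(true_orders[[tid]]))
    }
  }, logical(1))
  mean(hit)
}

#' Relative splicing position of an intron
#'
#' `(rank - 1) / (n - 1)`: 0 for the first-spliced intron, 1 for the last.
#'
#' @param intron_rank splicing position (1-based).
#' @param n intron count, at least 2.
#' @return value in \[0, 1\].
#' @export
relative_position <- function(intron_rank, n) {
  stopifnot(n >= 2, all(intron_rank >= 1), all(intron_rank <= n))
  (intron_rank - 1) / (n - 1)
}

#' Split-half stability of inferred splicing orders
#'
#' Randomly bisects every transcript's fragments, reruns pair detection and
#' order inference on each half, and reports the per-transcript Spearman rho
#' between the two inferred orders. Transcripts failing the retention or
#' uniqueness filter in either half are excluded (their number is recorded in
#' the `n_excluded` attribute). The bisection is repeated `repeats` times.
#'
#' @param fragment_sets named list of [fragment_set()] (one per transcript).
#' @param models named list of [transcript_model()].
#' @param repeats number of random bisections (default 5).
#' @param seed optional integer seed.
#' @param min_anchor,adjust_value,min_retention pipeline parameters, see
#'   [count_order_pairs()], [frequency_matrix()], [infer_orders()].
#' @return data frame with columns `repeat_id`, `transcript_id`, `rho`.
#' @export
split_half_stability <- function(fragment_sets, models, repeats = 5,
                                 seed = NULL, min_anchor = 6,
                                 adjust_value = 0.1, min_retention = 0.95) {
  with_seed(seed, {
    rows <- list()
    n_excluded <- 0L
    for (r in seq_len(repeats)) {
      for (tid in names(fragment_sets)) {
        fs <- fragment_sets[[tid]]
        model <- models[[tid]]
        if (fs$n_fragments < 2 || is.null(model)) { n_excluded <- n_excluded + 1L; next }
        g1 <- sort(sample(fs$n_fragments, floor(fs$n_fragments / 2)))
        g2 <- setdiff(seq_len(fs$n_fragments), g1)
        fit <- lapply(list(g1, g2), function(g) {
          pc <- count_order_pairs(subset_fragments(fs, g), model, min_anchor)
          if (retention_percentage(pc) < min_retention) return(NULL)
          splicing_order(pc, adjust_value = adjust_value,
                         compute_entropy = FALSE)
        })
        failed <- any(vapply(fit, is.null, logical(1))) ||
          !fit[[1]]$unique || !fit[[2]]$unique
        if (failed) { n_excluded <- n_excluded + 1L; next }
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_id = r, transcript_id = tid,
          rho = order_spearman(fit[[1]]$order, fit[[2]]$order))
      }
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(repeat_id = integer(), transcript_id = character(),
                           rho = numeric())
    attr(out, "n_excluded") <- n_excluded
    out
  })
}

#' Correlate splicing ranks with per-intron features
#'
#' Spearman correlation between the splicing position of each intron and
#' per-intron features such as intron length, distance to the TSS, GC
#' fraction, or flanking exon lengths. Reports a per-transcript rho for every
#' feature plus a pooled rho over all introns of all transcripts.
#' Missing feature values are handled pairwise-complete; features with zero
#' variance yield `NA`.
#'
#' @param fits named list of fitted [splicing_order()] objects.
#' @param features data frame with columns `transcript_id`, `intron_index`,
#'   and one column per feature.
#' @return list with data frames `per_transcript` and `pooled`.
#' @export
feature_correlation <- function(fits, features) {
  stopifnot(all(c("transcript_id", "intron_index") %in% names(features)))
  feat_cols <- setdiff(names(features), c("transcript_id", "intron_index"))
  features$splicing_rank <- mapply(function(tid, idx) {
    f <- fits[[tid]]
    if (is.null(f)) NA_real_ else f$rank[idx]
  }, features$transcript_id, features$intron_index)

  per_tx <- do.call(rbind, lapply(split(features, features$transcript_id),
    function(d) {
      rhos <- vapply(feat_cols, function(fc)
        suppressWarnings(stats::cor(d$splicing_rank, d[[fc]],
                                    method = "spearman",
                                    use = "pairwise.complete.obs")),
        numeric(1))
      data.frame(transcript_id = d$transcript_id[1], feature = feat_cols,
                 rho = unname(rhos), n = nrow(d), row.names = NULL)
    }))
  pooled <- data.frame(feature = feat_cols, rho = vapply(feat_cols,
    function(fc) suppressWarnings(
      stats::cor(features$splicing_rank, features[[fc]],
                 method = "spearman", use = "pairwise.complete.obs")),
    numeric(1)), row.names = NULL)
  n_missing <- sum(is.na(features[feat_cols]))
  if (n_missing > 0)
    message(n_missing, " missing feature value(s) handled pairwise-complete")
  list(per_transcript = per_tx, pooled = pooled)
}
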