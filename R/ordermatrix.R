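#' Pseudo-count-adjusted frequency matrix
#'
#' Converts a pair count matrix A into the frequency matrix D with
#' `D[i, j] = (A[i, j] + adjust_value) / (A[i, j] + A[j, i] + 2 * adjust_value)`
#' off the diagonal and 0 on the diagonal. With the default
#' `adjust_value = 0.1` this is the MAP estimate of the per-pair binomial
#' probability under a Beta(1.1, 1.1) prior; the pseudo counts keep every
#' off-diagonal entry strictly inside (0, 1) so that `D[i, j] + D[j, i] = 1`
#' for every pair. `adjust_value = 0` gives the raw frequency
#' `A[i, j] / (A[i, j] + A[j, i])`, with pairs lacking any read set to 0 on
#' both sides (they then contribute nothing to order likelihoods).
#'
#' @param x a [pair_counts()] object or a square count matrix.
#' @param adjust_value pseudo read count added to both directions of every
#'   pair (default 0.1); must be non-negative.
#' @return object of class `frequency_matrix`: list with `transcript_id`,
#'   `n`, `D`, `adjust_value`.
#' @export
frequency_matrix <- function(x, adjust_value = 0.1) {
  if (!is.numeric(adjust_value) || length(adjust_value) != 1 ||
      adjust_value < 0)
    stop("'adjust_value' must be a single non-negative number")
  if (inherits(x, "pair_counts")) {
    A <- x$A; tid <- x$transcript_id
  } else {
    A <- as.matrix(x); tid <- NA_character_
  }
  n <- nrow(A)
  tot <- A + t(A)
  D <- (A + adjust_value) / (tot + 2 * adjust_value)
  if (adjust_value == 0) D[tot == 0] <- 0
  diag(D) <- 0
  dimnames(D) <- list(seq_len(n), seq_len(n))
  structure(list(transcript_id = tid, n = n, D = D,
                 adjust_value = adjust_value),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("frequency_matrix for %s (%d introns, adjust_value = %g)\n",
              x$transcript_id, x$n, x$adjust_value))
  print(round(x$D, digits))
  invisible(x)
}

# coerce pair_counts / frequency_matrix / matrix to the D matrix
as_D <- function(x, adjust_value = 0.1) {
  if (inherits(x, "frequency_matrix")) return(x)
  frequency_matrix(x, adjust_value = adjust_value)
}

#' Fraction of intron pairs with read support
#'
#' The percentage of intron splicing-order pairs retained: the number of
#' unordered intron pairs \{i, j\} with at least one supporting read
#' (in either direction, before pseudo counts) divided by the total
#' n(n-1)/2 pairs of the transcript.
#'
#' @param x a [pair_counts()] object or square count matrix.
#' @return fraction in \[0, 1\].
#' @export
retention_percentage <- function(x) {
  A <- if (inherits(x, "pair_counts")) x$A else as.matrix(x)
  n <- nrow(A)
  stopifnot(n >= 2)
  tot <- A + t(A)
  sum(tot[upper.tri(tot)] > 0) / (n * (n - 1) / 2)
}

#' Correct the pair counts of one retained intron against one other intron
#'
#' Reads from the mature isoform that retains intron `ri` mimic evidence that
#' `ri` is spliced late: they inflate the count supporting "`ri` spliced after
#' the other intron", `b = A[other, ri]`. Given the percent-spliced-in value
#' of the retained intron (PSI, the fraction of mature transcripts retaining
#' it), that count is replaced by `max(b - PSI * (b + c + d), 0)`, where
#' `c = A[ri, other]` is the count supporting `ri` spliced before the other
#' intron and `d` is the number of fragments observing both introns spliced.
#' All other entries are unchanged; the corrected count is never negative.
#'
#' @param x a [pair_counts()] object.
#' @param ri transcription-direction index of the retained intron.
#' @param psi PSI value in \[0, 1\].
#' @param other index of the other intron of the pair.
#' @return the corrected [pair_counts()] object.
#' @export
correct_retained_intron <- function(x, ri, psi, other) {
  stopifnot(inherits(x, "pair_counts"))
  if (!is.numeric(psi) || length(psi) != 1 || psi < 0 || psi > 1)
    stop("'psi' must be a single value in [0, 1]")
  stopifnot(ri %in% seq_len(x$n), other %in% seq_len(x$n), ri != other)
  b <- x$A[other, ri]
  cc <- x$A[ri, other]
  d <- if (!is.null(x$both)) x$both[ri, other] else 0
  x$A[other, ri] <- max(b - psi * (b + cc + d), 0)
  x
}

#' Apply the retained-intron correction for a table of events
#'
#' Applies [correct_retained_intron()] for every retained-intron event against
#' every other intron of the transcript, using the uncorrected counts as
#' inputs for all pairs.
#'
#' @param x a [pair_counts()] object.
#' @param events data frame with columns `intron_index` and `psi` (one row per
#'   retained intron of this transcript).
#' @return the corrected [pair_counts()] object.
#' @export
correct_retained_introns <- function(x, events) {
  stopifnot(inherits(x, "pair_counts"),
            all(c("intron_index", "psi") %in% names(events)))
  A0 <- x  # corrections use the uncorrected counts for b, c, d
  out <- x
  for (k in seq_len(nrow(events))) {
    ri <- events$intron_index[k]
    psi <- events$psi[k]
    if (!is.numeric(psi) || psi < 0 || psi > 1)
      stop("'psi' must be in [0, 1]")
    stopifnot(ri %in% seq_len(x$n))
    for (other in setdiff(seq_len(x$n), ri)) {
      b <- A0$A[other, ri]
      cc <- A0$A[ri, other]
      d <- if (!is.null(A0$both)) A0$both[ri, other] else 0
      out$A[other, ri] <- max(b - psi * (b + cc + d), 0)
    }
  }
  out
}
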