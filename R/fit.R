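#' Log-likelihood of a splicing order
#'
#' The log-likelihood of an order theta given the frequency matrix D is the
#' sum of `log D[i, j]` over all ordered pairs (i, j) that theta splices in
#' that order (equivalently, the sum of the upper triangle of `log D` after
#' permuting rows and columns by theta). Pairs with no reads and no pseudo
#' counts (`D[i, j] + D[j, i] = 0`, possible only with `adjust_value = 0`)
#' contribute nothing. Natural logarithm.
#'
#' @param x a [frequency_matrix()], [pair_counts()] object, or count matrix.
#' @param theta integer permutation of `1..n`: the introns in splicing time
#'   order, first spliced first.
#' @param adjust_value pseudo count used if `x` must first be converted.
#' @return the log-likelihood (a non-positive number).
#' @export
order_loglik <- function(x, theta, adjust_value = 0.1) {
  fm <- as_D(x, adjust_value)
  theta <- check_permutation(theta, fm$n)
  M <- fm$D[theta, theta, drop = FALSE]
  up <- upper.tri(M)
  zero_pair <- (M + t(M)) == 0
  sum(ifelse(zero_pair[up], 0, log(M[up])))
}

# log D with zero-support pairs neutralized (contribute 0), for the solvers
solver_logD <- function(D) {
  L <- suppressWarnings(log(D))
  zp <- (D + t(D)) == 0
  L[zp] <- 0
  diag(L) <- 0
  L
}

#' Most unlikely splicing order
#'
#' The permutation minimizing the order likelihood is the reversal of the
#' permutation maximizing it, so the most unlikely order of a fitted model is
#' simply the most likely order read backwards.
#'
#' @param theta a permutation (splicing-time sequence) or a fitted
#'   [splicing_order()] object.
#' @return the reversed permutation.
#' @export
most_unlikely_order <- function(theta) {
  if (inherits(theta, "splicing_order")) theta <- theta$order
  rev(check_permutation(theta))
}

#' Log relative likelihood of in-order splicing
#'
#' `R = ln L(identity | D) - ln L(theta* | D)`: the log likelihood ratio of
#' the transcription-direction order (intron 1 first, intron n last) to the
#' most likely order. `R = 0` means the transcript is most likely spliced in
#' transcription order; strongly negative values mean it is not.
#'
#' @inheritParams order_loglik
#' @param theta_star the most likely order (an optimum for `x`).
#' @return a non-positive number.
#' @export
relative_loglik <- function(x, theta_star, adjust_value = 0.1) {
  if (inherits(theta_star, "splicing_order")) theta_star <- theta_star$order
  fm <- as_D(x, adjust_value)
  order_loglik(fm, seq_len(fm$n)) - order_loglik(fm, theta_star)
}

#' Normalized entropy of the splicing-order distribution
#'
#' Normalizes the order likelihoods into a probability distribution
#' `p(theta | D) = L(theta | D) / sum_theta L(theta | D)` over all n!
#' permutations and returns the Shannon entropy `-sum p log2 p` divided by
#' `log2(n!)`, so 1 means maximally heterogeneous splicing (all orders equally
#' likely) and values near 0 mean one dominant order. Defined only for
#' transcripts with fewer than 12 introns; `NA` is returned otherwise.
#'
#' The sum over n! orders is evaluated exactly by a dynamic program over
#' subsets in log space (partition function and expected log-weight), which
#' equals the literal enumeration without materializing the permutations.
#'
#' @inheritParams order_loglik
#' @return normalized entropy in \[0, 1\], or `NA` if `n >= 12`.
#' @export
order_entropy <- function(x, adjust_value = 0.1) {
  fm <- as_D(x, adjust_value)
  n <- fm$n
  stopifnot(n >= 2)
  if (n >= 12) return(NA_real_)
  L <- solver_logD(fm$D)
  bits <- bitwShiftL(1L, 0:(n - 1))
  nsub <- bitwShiftL(1L, n)
  logZ <- numeric(nsub)
  EW <- numeric(nsub)   # E[log w | subset]
  for (S in seq_len(nsub - 1)) {
    mem <- which(bitwAnd(S, bits) > 0)
    lc <- vapply(seq_along(mem), function(a) {
      i <- mem[a]
      sum(L[i, mem[-a]])
    }, numeric(1))
    sub <- S - bits[mem]
    terms <- lc + logZ[sub + 1L]
    lz <- logsumexp(terms)
    logZ[S + 1L] <- lz
    w <- exp(terms - lz)
    contrib <- w * (lc + EW[sub + 1L])
    EW[S + 1L] <- sum(contrib[w > 0])
  }
  h_bits <- (logZ[nsub] - EW[nsub]) / log(2)
  h <- h_bits / log2(factorial(n))
  min(max(h, 0), 1)
}

#' Fit the most likely intron splicing order
#'
#' The central estimator: given the read-count evidence for one transcript,
#' finds the permutation of introns maximizing the pairwise order likelihood.
#' For transcripts with fewer than `exhaustive_limit` (default 12) introns the
#' optimum over all n! permutations is found exactly by a subset dynamic
#' program, together with the exact number of optimal orders; for larger
#' transcripts (up to `max_introns - 1` introns) the equivalent 0-1 linear
#' ordering program is solved exactly by branch and bound, and uniqueness is
#' established by a second search excluding the incumbent.
#'
#' @param x a [pair_counts()] object, a square count matrix, or a
#'   [frequency_matrix()].
#' @param adjust_value pseudo read count (default 0.1) used when `x` holds
#'   counts.
#' @param method `"auto"` dispatches on intron count; `"exhaustive"` forces
#'   the exact search over all permutations (requires `n < exhaustive_limit`);
#'   `"ilp"` forces the integer-programming (branch-and-bound) solver.
#' @param exhaustive_limit intron count at and above which `"auto"` switches
#'   to the integer-programming solver (default 12).
#' @param max_introns refuse transcripts with this many introns or more
#'   (default 100).
#' @param compute_entropy also compute [order_entropy()] (only available for
#'   `n < 12`).
#' @param tol tie tolerance on log-likelihoods when counting optima.
#' @return an object of class `splicing_order` with elements `transcript_id`,
#'   `n`, `order` (most likely order, first spliced first), `rank` (splicing
#'   position of each intron), `logLik`, `unique`, `n_optima` (exhaustive
#'   method only), `relative_loglik`, `entropy`, `retention`, `method`,
#'   `adjust_value`, and `D` (the frequency matrix used).
#' @examples
#' A <- matrix(0, 2, 2); A[2, 1] <- 9; A[1, 2] <- 1
#' fit <- splicing_order(A)
#' coef(fit)
#' @export
splicing_order <- function(x, adjust_value = 0.1,
                           method = c("auto", "exhaustive", "ilp"),
                           exhaustive_limit = 12, max_introns = 100,
                           compute_entropy = TRUE, tol = 1e-9) {
  method <- match.arg(method)
  retention <- if (inherits(x, "pair_counts")) retention_percentage(x)
               else if (is.matrix(x)) retention_percentage(x)
               else NA_real_
  fm <- as_D(x, adjust_value)
  n <- fm$n
  if (n < 2) stop("splicing order needs at least 2 introns")
  if (n >= max_introns)
    stop("too many introns (", n, " >= ", max_introns, ")")
  if (method == "auto")
    method <- if (n < exhaustive_limit) "exhaustive" else "ilp"
  if (method == "exhaustive" && n >= exhaustive_limit)
    stop("exhaustive search requires fewer than ", exhaustive_limit,
         " introns; use method = \"ilp\"")
  L <- solver_logD(fm$D)
  if (method == "exhaustive") {
    sol <- lop_solve_dp(L, tol)
    n_optima <- sol$n_optima
  } else {
    sol <- lop_solve_bnb(L, tol)
    n_optima <- NA_real_
  }
  theta <- as.integer(sol$order)
  ll <- order_loglik(fm, theta)
  ent <- if (compute_entropy && n < 12) order_entropy(fm) else NA_real_
  structure(list(transcript_id = fm$transcript_id, n = n,
                 order = theta, rank = order_rank(theta),
                 logLik = ll, unique = isTRUE(sol$unique),
                 n_optima = n_optima,
                 relative_loglik = order_loglik(fm, seq_len(n)) - ll,
                 entropy = ent, retention = retention, method = method,
                 adjust_value = fm$adjust_value, D = fm),
            class = "splicing_order")
}

#' @export
print.splicing_order <- function(x, ...) {
  cat(sprintf("Most likely intron splicing order%s\n",
              if (is.na(x$transcript_id)) "" else
                paste0(" for ", x$transcript_id)))
  cat("  order:", paste(x$order, collapse = " -> "),
      if (!x$unique) "(not unique)" else "", "\n")
  cat(sprintf("  n introns: %d   method: %s\n", x$n, x$method))
  cat(sprintf("  log-likelihood: %.4f\n", x$logLik))
  cat(sprintf("  log relative likelihood (in-order vs optimum): %.4f\n",
              x$relative_loglik))
  if (!is.na(x$entropy))
    cat(sprintf("  normalized entropy: %.4f\n", x$entropy))
  if (!is.na(x$retention))
    cat(sprintf("  pair retention: %.3f\n", x$retention))
  invisible(x)
}

#' @export
summary.splicing_order <- function(object, ...) {
  tab <- data.frame(intron = seq_len(object$n),
                    splicing_position = object$rank,
                    relative_position =
                      (object$rank - 1) / (object$n - 1))
  out <- list(fit = object, intron_table = tab,
              most_unlikely = most_unlikely_order(object$order),
              spearman_vs_transcription =
                spearman_to_transcription(object$order))
  class(out) <- "summary.splicing_order"
  out
}

#' @export
print.summary.splicing_order <- function(x, ...) {
  print(x$fit)
  cat("  most unlikely order:", paste(x$most_unlikely, collapse = " -> "),
      "\n")
  cat(sprintf("  Spearman rho vs transcription order: %.3f\n",
              x$spearman_vs_transcription))
  cat("\nPer-intron splicing positions:\n")
  print(x$intron_table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.splicing_order <- function(object, ...) {
  stats::setNames(object$order, paste0("position", seq_len(object$n)))
}

#' @export
logLik.splicing_order <- function(object, ...) {
  structure(object$logLik, df = object$n * (object$n - 1) / 2,
            class = "logLik")
}

#' Simulate pair count matrices from a fitted splicing order
#'
#' Draws new pair-count matrices consistent with the fitted most likely order:
#' for every intron pair, the direction the fitted order implies receives a
#' Poisson(`mean_reads`) count and the other direction 0.
#'
#' @param object a fitted [splicing_order()].
#' @param nsim number of matrices.
#' @param seed optional integer seed.
#' @param mean_reads Poisson mean per pair (default 15).
#' @param ... unused.
#' @return list of [pair_counts()] objects.
#' @export
simulate.splicing_order <- function(object, nsim = 1, seed = NULL,
                                    mean_reads = 15, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(k)
      simulate_pair_counts(object$n, object$order, mean_reads = mean_reads))
  })
}
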