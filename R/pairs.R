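#' Classify the splicing status of every intron in every fragment
#'
#' For each (fragment, intron) pair the status is:
#' * `SPLICED` (1) if some splice gap of the fragment matches the intron's
#'   boundaries exactly (0-tolerance junction match);
#' * `UNSPLICED` (0) if no gap matches the intron and some aligned block covers
#'   an exon-intron boundary of the intron with at least `min_anchor` aligned
#'   bases on each side of that boundary;
#' * `UNKNOWN` (`NA`) otherwise, including fragments on a different
#'   chromosome than the transcript.
#'
#' @param fragments a [fragment_set()].
#' @param model a [transcript_model()].
#' @param min_anchor minimum aligned bases on each side of an exon-intron
#'   boundary for an UNSPLICED call (default 6).
#' @return integer matrix (fragments x introns, columns ordered by
#'   transcription-direction intron index) with values 1/0/`NA`.
#' @export
classify_introns <- function(fragments, model, min_anchor = 6) {
  stopifnot(min_anchor >= 1)
  n <- model$n_introns
  nf <- fragments$n_fragments
  status <- matrix(NA_integer_, nrow = nf, ncol = n)
  if (nf == 0 || n == 0) return(status)
  ir <- introns_by_index(model)
  onchrom <- fragments$chrom == model$chrom
  blk <- fragments$blocks
  gap <- fragments$gaps
  for (k in seq_len(n)) {
    is <- ir$start[k]; ie <- ir$end[k]
    spliced <- unique(gap$fragment[gap$start == is & gap$end == ie])
    cov5 <- blk$start <= is - min_anchor & blk$end >= is + min_anchor
    cov3 <- blk$start <= ie - min_anchor & blk$end >= ie + min_anchor
    unspliced <- unique(blk$fragment[cov5 | cov3])
    unspliced <- setdiff(unspliced, spliced)
    status[spliced[onchrom[spliced]], k] <- 1L
    status[unspliced[onchrom[unspliced]], k] <- 0L
  }
  status
}

#' Detect intron splicing-order pair observations
#'
#' Emits one observation "intron i spliced before intron j" for every pair of
#' a SPLICED intron i and an UNSPLICED intron j seen in the same fragment.
#' Fragments carrying a splice gap that matches no annotated intron of the
#' transcript are discarded entirely (guard against alternative 5'/3' splice
#' site bias). Each fragment contributes at most one observation per ordered
#' pair.
#'
#' @inheritParams classify_introns
#' @return data frame with columns `fragment_id`, `earlier_intron`,
#'   `later_intron`, plus attributes `n_used` and `n_discarded`.
#' @export
order_pair_observations <- function(fragments, model, min_anchor = 6) {
  keep <- annotated_gap_fragments(fragments, model)
  n_disc <- fragments$n_fragments - length(keep)
  fs <- if (n_disc > 0) subset_fragments(fragments, keep) else fragments
  status <- classify_introns(fs, model, min_anchor)
  obs <- list()
  for (f in seq_len(nrow(status))) {
    sp <- which(!is.na(status[f, ]) & status[f, ] == 1L)
    un <- which(!is.na(status[f, ]) & status[f, ] == 0L)
    if (length(sp) > 0 && length(un) > 0)
      obs[[length(obs) + 1L]] <- data.frame(
        fragment_id = fs$ids[f],
        earlier_intron = rep(sp, each = length(un)),
        later_intron = rep(un, times = length(sp)),
        stringsAsFactors = FALSE)
  }
  out <- if (length(obs) > 0) do.call(rbind, obs)
         else data.frame(fragment_id = character(),
                         earlier_intron = integer(),
                         later_intron = integer(), stringsAsFactors = FALSE)
  attr(out, "n_used") <- fs$n_fragments
  attr(out, "n_discarded") <- n_disc
  out
}

# indices of fragments whose every gap matches an annotated intron boundary
annotated_gap_fragments <- function(fragments, model) {
  if (nrow(fragments$gaps) == 0) return(seq_len(fragments$n_fragments))
  ir <- model$introns
  key <- paste(fragments$gaps$start, fragments$gaps$end)
  ann <- key %in% paste(ir$start, ir$end)
  bad <- unique(fragments$gaps$fragment[!ann])
  setdiff(seq_len(fragments$n_fragments), bad)
}

#' Pair count matrix
#'
#' Container for the n x n read-count adjacency matrix `A` of a transcript,
#' where `A[i, j]` counts fragments supporting "intron i spliced before
#' intron j" (row spliced before column). Optionally carries the symmetric
#' matrix `both` of fragments observing both introns of a pair as spliced,
#' needed by the retained-intron correction.
#'
#' @param A square numeric matrix with zero diagonal and non-negative entries.
#' @param transcript_id identifier.
#' @param both optional square matrix of both-spliced fragment counts.
#' @return object of class `pair_counts`.
#' @export
pair_counts <- function(A, transcript_id = NA_character_, both = NULL) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), all(A >= 0), all(diag(A) == 0))
  dimnames(A) <- list(seq_len(nrow(A)), seq_len(nrow(A)))
  if (!is.null(both)) {
    both <- as.matrix(both)
    stopifnot(identical(dim(both), dim(A)))
    dimnames(both) <- dimnames(A)
  }
  structure(list(transcript_id = transcript_id, n = nrow(A), A = A,
                 both = both),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("pair_counts for %s (%d introns), %d supporting reads\n",
              x$transcript_id, x$n, sum(x$A)))
  print(x$A)
  invisible(x)
}

#' Accumulate pair observations into a count matrix
#'
#' `A[i, j]` = number of distinct fragments observing intron i spliced before
#' intron j; duplicated (fragment, pair) rows are counted once.
#'
#' @param observations data frame as returned by [order_pair_observations()].
#' @param n intron count of the transcript.
#' @param transcript_id identifier.
#' @param both optional both-spliced matrix to attach.
#' @return a [pair_counts()] object.
#' @export
accumulate_counts <- function(observations, n, transcript_id = NA_character_,
                              both = NULL) {
  A <- matrix(0, n, n)
  if (nrow(observations) > 0) {
    obs <- unique(observations[, c("fragment_id", "earlier_intron",
                                   "later_intron")])
    stopifnot(all(obs$earlier_intron %in% seq_len(n)),
              all(obs$later_intron %in% seq_len(n)),
              all(obs$earlier_intron != obs$later_intron))
    tab <- table(factor(obs$earlier_intron, levels = seq_len(n)),
                 factor(obs$later_intron, levels = seq_len(n)))
    A <- matrix(as.numeric(tab), n, n)
  }
  pair_counts(A, transcript_id, both = both)
}

#' Count splicing-order pairs of one transcript from fragments
#'
#' Runs [order_pair_observations()] and [accumulate_counts()] and additionally
#' tallies the both-spliced matrix used by the retained-intron correction.
#'
#' @inheritParams classify_introns
#' @return a [pair_counts()] object with the `both` matrix attached.
#' @export
count_order_pairs <- function(fragments, model, min_anchor = 6) {
  keep <- annotated_gap_fragments(fragments, model)
  fs <- if (length(keep) < fragments$n_fragments)
    subset_fragments(fragments, keep) else fragments
  status <- classify_introns(fs, model, min_anchor)
  sp <- !is.na(status) & status == 1L
  un <- !is.na(status) & status == 0L
  A <- crossprod(sp, un)            # A[i,j] = fragments with i spliced, j not
  B <- crossprod(sp, sp)
  diag(B) <- 0
  pc <- pair_counts(A, model$transcript_id, both = B)
  attr(pc, "n_used") <- fs$n_fragments
  attr(pc, "n_discarded") <- fragments$n_fragments - fs$n_fragments
  pc
}
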