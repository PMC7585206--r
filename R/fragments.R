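#' Construct a set of aligned fragments
#'
#' A `fragment_set` holds the merged alignment evidence of sequenced molecules:
#' for every fragment the genomic intervals covered by aligned bases
#' (`blocks`; both mates of a pair merged) and the splice gaps of its
#' alignments (`gaps`, the N operations). All coordinates are 0-based
#' half-open. The simulator emits this structure directly, so the detection
#' code is agnostic of whether fragments came from a BAM file or from
#' simulation.
#'
#' @param ids character vector of fragment (read) names.
#' @param chrom character vector, one chromosome per fragment.
#' @param blocks data frame with columns `fragment` (integer index into
#'   `ids`), `start`, `end`.
#' @param gaps data frame with the same columns (may have zero rows).
#' @return an object of class `fragment_set`.
#' @export
fragment_set <- function(ids, chrom, blocks, gaps) {
  stopifnot(length(ids) == length(chrom),
            all(c("fragment", "start", "end") %in% names(blocks)),
            all(c("fragment", "start", "end") %in% names(gaps)))
  structure(list(ids = as.character(ids), chrom = as.character(chrom),
                 blocks = blocks, gaps = gaps,
                 n_fragments = length(ids)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragments, %d blocks, %d gaps\n",
              x$n_fragments, nrow(x$blocks), nrow(x$gaps)))
  invisible(x)
}

#' Extract merged fragments from a coordinate-sorted BAM file
#'
#' Reads primary alignments (secondary and supplementary records are dropped),
#' merges the two mates of a read pair into one fragment, and converts splice
#' gaps (N cigar operations) and aligned blocks to 0-based half-open genomic
#' intervals. Orphan mates yield a single-mate fragment.
#'
#' @param bam path to an indexed BAM file.
#' @param region optional `GRanges` restricting the extraction.
#' @return a [fragment_set()].
#' @export
extract_fragments <- function(bam, region = NULL) {
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- if (is.null(region))
    Rsamtools::ScanBamParam(flag = flag, what = "qname")
  else
    Rsamtools::ScanBamParam(flag = flag, what = "qname", which = region)
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(gal) == 0)
    return(fragment_set(character(), character(),
                        data.frame(fragment = integer(), start = numeric(),
                                   end = numeric()),
                        data.frame(fragment = integer(), start = numeric(),
                                   end = numeric())))
  qn <- S4Vectors::mcols(gal)$qname
  ids <- unique(qn)
  fidx <- match(qn, ids)

  blk <- GenomicAlignments::grglist(gal)         # aligned blocks per record
  jnc <- GenomicAlignments::junctions(gal)       # N-gap ranges per record

  ub <- unlist(blk, use.names = FALSE)
  blocks <- data.frame(fragment = rep(fidx, S4Vectors::elementNROWS(blk)),
                       start = GenomicRanges::start(ub) - 1,
                       end = as.numeric(GenomicRanges::end(ub)))
  uj <- unlist(jnc, use.names = FALSE)
  gaps <- data.frame(fragment = rep(fidx, S4Vectors::elementNROWS(jnc)),
                     start = GenomicRanges::start(uj) - 1,
                     end = as.numeric(GenomicRanges::end(uj)))
  # de-duplicate gaps seen on both mates
  gaps <- unique(gaps)
  # chromosome of each fragment (first record wins; chimeric mates are rare
  # and classified UNKNOWN downstream if the chromosome mismatches)
  chrom <- as.character(GenomicRanges::seqnames(gal))[match(ids, qn)]
  fragment_set(ids, chrom, blocks, gaps)
}

# subset a fragment_set by fragment indices, renumbering
subset_fragments <- function(fs, idx) {
  keepb <- fs$blocks$fragment %in% idx
  keepg <- fs$gaps$fragment %in% idx
  remap <- integer(fs$n_fragments)
  remap[idx] <- seq_along(idx)
  blocks <- fs$blocks[keepb, , drop = FALSE]
  blocks$fragment <- remap[blocks$fragment]
  gaps <- fs$gaps[keepg, , drop = FALSE]
  gaps$fragment <- remap[gaps$fragment]
  fragment_set(fs$ids[idx], fs$chrom[idx], blocks, gaps)
}

# concatenate two fragment sets
bind_fragments <- function(a, b) {
  off <- a$n_fragments
  bb <- b$blocks; bb$fragment <- bb$fragment + off
  bg <- b$gaps; bg$fragment <- bg$fragment + off
  fragment_set(c(a$ids, b$ids), c(a$chrom, b$chrom),
               rbind(a$blocks, bb), rbind(a$gaps, bg))
}
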