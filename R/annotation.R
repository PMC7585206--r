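#' Construct a transcript model
#'
#' Builds the strand-aware exon/intron model of a single isoform from genomic
#' exon coordinates. Coordinates are 0-based half-open throughout the package;
#' GTF/GFF3 input (1-based inclusive) is converted on read by
#' [read_transcript_models()].
#'
#' Intron indices count in the direction of transcription: on the minus strand
#' the intron with the smallest genomic coordinate carries the largest index.
#' `distance_to_tss` is the distance in bp from the transcription start site to
#' the transcription-direction 5' end of each intron, and is strictly
#' increasing in intron index.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of 0-based half-open exon
#'   coordinates, in genomic order, non-overlapping.
#' @param sequences optional named `DNAStringSet` of chromosome sequences used
#'   to annotate per-intron GC fraction.
#' @return an object of class `transcript_model`: a list with elements
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `tss`, `exons` (data frame
#'   of genomic-order exon coordinates), `introns` (data frame with columns
#'   `index`, `start`, `end`, `length`, `distance_to_tss`, and `gc_fraction`
#'   when sequences are supplied) and `n_introns`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends, sequences = NULL) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1,
            strand %in% c("+", "-"))
  o <- order(exon_starts)
  exon_starts <- as.numeric(exon_starts)[o]
  exon_ends <- as.numeric(exon_ends)[o]
  if (any(exon_ends <= exon_starts))
    stop("exon with non-positive length in ", transcript_id)
  if (length(exon_starts) > 1 &&
      any(exon_starts[-1] < exon_ends[-length(exon_ends)]))
    stop("overlapping exons in ", transcript_id)

  n_ex <- length(exon_starts)
  tss <- if (strand == "+") exon_starts[1] else exon_ends[n_ex]
  if (n_ex > 1) {
    istart <- exon_ends[-n_ex]
    iend <- exon_starts[-1]
    n <- n_ex - 1
    index <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    d5 <- if (strand == "+") istart - tss else tss - iend
    introns <- data.frame(index = index, start = istart, end = iend,
                          length = iend - istart, distance_to_tss = d5)
  } else {
    introns <- data.frame(index = integer(), start = numeric(),
                          end = numeric(), length = numeric(),
                          distance_to_tss = numeric())
  }
  if (!is.null(sequences) && nrow(introns) > 0) {
    seq <- sequences[[chrom]]
    gc <- vapply(seq_len(nrow(introns)), function(k) {
      s <- Biostrings::subseq(seq, introns$start[k] + 1, introns$end[k])
      f <- Biostrings::letterFrequency(s, c("GC"), as.prob = TRUE)
      as.numeric(f)
    }, numeric(1))
    introns$gc_fraction <- gc
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, tss = tss,
                 exons = data.frame(start = exon_starts, end = exon_ends),
                 introns = introns, n_introns = nrow(introns)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s strand %s\n", x$transcript_id,
              x$gene_id, x$chrom,
              paste0(min(x$exons$start), "-", max(x$exons$end)), x$strand))
  cat(sprintf("  %d exons, %d introns\n", nrow(x$exons), x$n_introns))
  invisible(x)
}

# introns of a model sorted by transcription-direction index
introns_by_index <- function(model) {
  ir <- model$introns
  ir[order(ir$index), , drop = FALSE]
}

#' Read transcript models from a GTF/GFF3 annotation
#'
#' Parses exon features grouped by transcript and derives one
#' [transcript_model()] per annotated isoform. 1-based inclusive annotation
#' coordinates are converted to the package's 0-based half-open convention.
#' Transcripts with overlapping exons are excluded with a warning; the numbers
#' of single-exon and multi-exon transcripts are reported via `message()`.
#'
#' @param path path to a GTF or GFF3 file (format detected by extension, or
#'   forced via `format`).
#' @param format passed to the rtracklayer importer; `NULL` autodetects.
#' @param keep_single_exon keep transcripts without introns (default `FALSE`;
#'   they carry no splicing-order information).
#' @param sequences optional named `DNAStringSet`, see [transcript_model()].
#' @return named list of `transcript_model` objects.
#' @export
read_transcript_models <- function(path, format = NULL,
                                   keep_single_exon = FALSE,
                                   sequences = NULL) {
  gr <- if (is.null(format)) rtracklayer::import(path)
        else rtracklayer::import(path, format = format)
  gr <- gr[!is.na(gr$type) & tolower(as.character(gr$type)) == "exon"]
  mc <- S4Vectors::mcols(gr)
  txid <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id)
          else if ("Parent" %in% names(mc)) as.character(unlist(mc$Parent))
          else stop("annotation has no transcript_id/Parent attribute on exons")
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else txid
  bad <- is.na(txid)
  if (any(bad)) {
    warning(sum(bad), " exon record(s) without a transcript id were skipped")
    gr <- gr[!bad]; gid <- gid[!bad]; txid <- txid[!bad]
  }
  df <- data.frame(tx = txid, gene = gid,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  models <- list()
  n_single <- 0L
  dropped <- character()
  for (tx in unique(df$tx)) {
    e <- df[df$tx == tx, , drop = FALSE]
    if (length(unique(e$chrom)) > 1 || !all(e$strand %in% c("+", "-"))) {
      dropped <- c(dropped, tx)
      next
    }
    m <- tryCatch(
      transcript_model(tx, e$gene[1], e$chrom[1], e$strand[1],
                       e$start, e$end, sequences = sequences),
      error = function(err) {
        warning("transcript ", tx, " excluded: ", conditionMessage(err))
        NULL
      })
    if (is.null(m)) next
    if (m$n_introns == 0) {
      n_single <- n_single + 1L
      if (!keep_single_exon) next
    }
    models[[tx]] <- m
  }
  if (length(dropped) > 0)
    warning("excluded ", length(dropped),
            " transcript(s) with inconsistent chromosome/strand: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  message(sprintf("parsed %d multi-exon and %d single-exon transcripts%s",
                  length(models) - if (keep_single_exon) n_single else 0L,
                  n_single,
                  if (keep_single_exon) "" else " (single-exon dropped)"))
  models
}

#' Select analyzable transcripts
#'
#' Keeps transcripts with at least `min_introns` introns and, when an
#' expression table is supplied, with TPM strictly above `tpm_threshold`
#' (default 0.1). Transcripts absent from a supplied expression table are
#' treated as not expressed; their number is reported via `message()`.
#'
#' @param models list of [transcript_model()] objects.
#' @param min_introns minimum intron count (default 3).
#' @param tpm optional named numeric vector or two-column data frame
#'   (transcript_id, TPM).
#' @param tpm_threshold TPM cutoff; transcripts must exceed it (default 0.1).
#' @return the selected subset of `models`.
#' @export
filter_transcripts <- function(models, min_introns = 3, tpm = NULL,
                               tpm_threshold = 0.1) {
  stopifnot(tpm_threshold >= 0)
  keep <- vapply(models, function(m) m$n_introns >= min_introns, logical(1))
  models <- models[keep]
  if (!is.null(tpm)) {
    if (is.data.frame(tpm)) {
      v <- tpm[[2]]
      names(v) <- as.character(tpm[[1]])
      tpm <- v
    }
    ids <- vapply(models, `[[`, "", "transcript_id")
    missing <- !(ids %in% names(tpm))
    if (any(missing))
      message(sum(missing),
              " transcript(s) absent from the expression table treated as not expressed")
    expr <- tpm[ids]
    expr[is.na(expr)] <- 0
    models <- models[expr > tpm_threshold]
  }
  models
}
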