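#' Pipeline run configuration
#'
#' Bundles the tunable thresholds of the pipeline with their defaults:
#' transcripts need at least `min_introns` introns (default 3) and, when an
#' expression table is used, TPM > `tpm_threshold` (default 0.1); UNSPLICED
#' calls need `min_anchor` aligned bases flanking a boundary (default 6);
#' pseudo count `adjust_value` 0.1; transcripts enter downstream analysis only
#' with pair retention >= `min_retention` (default 0.95); exhaustive search
#' below `exhaustive_limit` introns (default 12) and refusal at `max_introns`
#' (default 100).
#'
#' @param min_introns,min_anchor,adjust_value,min_retention,tpm_threshold,exhaustive_limit,max_introns,seed
#'   see description.
#' @return a `run_config` list.
#' @export
run_config <- function(min_introns = 3, min_anchor = 6, adjust_value = 0.1,
                       min_retention = 0.95, tpm_threshold = 0.1,
                       exhaustive_limit = 12, max_introns = 100,
                       seed = NULL) {
  stopifnot(adjust_value >= 0, min_retention >= 0, min_retention <= 1,
            exhaustive_limit <= max_introns, min_anchor >= 1)
  structure(list(min_introns = min_introns, min_anchor = min_anchor,
                 adjust_value = adjust_value, min_retention = min_retention,
                 tpm_threshold = tpm_threshold,
                 exhaustive_limit = exhaustive_limit,
                 max_introns = max_introns, seed = seed),
            class = "run_config")
}

config_header <- function(config) {
  vals <- vapply(config, function(v)
    if (is.null(v)) "NULL" else as.character(v), "")
  paste0("# spliceorder ", paste(names(config), vals, sep = "=",
                                 collapse = " "))
}

#' Count splicing-order pairs for every transcript in a BAM file
#'
#' Extracts merged fragments per transcript region and tallies the pair count
#' (and both-spliced) matrices. Regions with no alignments yield empty
#' matrices; discarded-fragment counts are reported via `message()`.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param models named list of [transcript_model()].
#' @param min_anchor see [classify_introns()].
#' @return named list of [pair_counts()].
#' @export
count_pairs_bam <- function(bam, models, min_anchor = 6) {
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index not found for ", bam, "; create it with indexBam()")
  avail <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  out <- list()
  n_disc <- 0L
  for (tid in names(models)) {
    m <- models[[tid]]
    if (!(m$chrom %in% avail)) {
      warning("chromosome ", m$chrom, " absent from BAM header; ",
              tid, " gets zero pairs")
      out[[tid]] <- pair_counts(matrix(0, m$n_introns, m$n_introns), tid)
      next
    }
    region <- GenomicRanges::GRanges(
      m$chrom, IRanges::IRanges(min(m$exons$start) + 1, max(m$exons$end)))
    fs <- extract_fragments(bam, region)
    pc <- count_order_pairs(fs, m, min_anchor)
    n_disc <- n_disc + attr(pc, "n_discarded")
    out[[tid]] <- pc
  }
  message("discarded ", n_disc,
          " fragment(s) with unannotated junctions across ",
          length(models), " transcript(s)")
  out
}

#' Infer most likely orders for a set of transcripts
#'
#' Applies the retention filter, fits [splicing_order()] per transcript
#' (exhaustive below `exhaustive_limit` introns, branch-and-bound integer
#' programming above), and returns one row per transcript. Transcripts
#' failing a filter keep their row with the reason in `status`.
#'
#' @param pair_list named list of [pair_counts()] objects.
#' @param config a [run_config()].
#' @param compute_entropy compute normalized entropy where defined.
#' @return data frame with columns `transcript_id`, `n_introns`, `retention`,
#'   `most_likely_order` (arrow-joined), `log_likelihood`,
#'   `relative_log_likelihood`, `unique`, `normalized_entropy`,
#'   `spearman_vs_transcription`, `method`, `status`; fitted objects in
#'   attribute `fits`.
#' @export
infer_orders <- function(pair_list, config = run_config(),
                         compute_entropy = TRUE) {
  rows <- list(); fits <- list()
  for (tid in names(pair_list)) {
    pc <- pair_list[[tid]]
    n <- pc$n
    ret <- if (n >= 2) retention_percentage(pc) else NA_real_
    base <- data.frame(transcript_id = tid, n_introns = n, retention = ret,
                       most_likely_order = NA_character_,
                       log_likelihood = NA_real_,
                       relative_log_likelihood = NA_real_, unique = NA,
                       normalized_entropy = NA_real_,
                       spearman_vs_transcription = NA_real_,
                       method = NA_character_, status = "ok",
                       stringsAsFactors = FALSE)
    if (n < config$min_introns) {
      base$status <- "too_few_introns"
    } else if (n >= config$max_introns) {
      base$status <- "too_many_introns"
    } else if (ret < config$min_retention) {
      base$status <- "low_retention"
    } else {
      fit <- splicing_order(pc, adjust_value = config$adjust_value,
                            exhaustive_limit = config$exhaustive_limit,
                            max_introns = config$max_introns,
                            compute_entropy = compute_entropy)
      fits[[tid]] <- fit
      base$most_likely_order <- paste(fit$order, collapse = "->")
      base$log_likelihood <- fit$logLik
      base$relative_log_likelihood <- fit$relative_loglik
      base$unique <- fit$unique
      base$normalized_entropy <- fit$entropy
      base$spearman_vs_transcription <- spearman_to_transcription(fit$order)
      base$method <- fit$method
    }
    rows[[tid]] <- base
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

parse_order <- function(s) as.integer(strsplit(s, "->", fixed = TRUE)[[1]])

#' Summarize inferred orders against known true orders
#'
#' @param orders data frame from [infer_orders()].
#' @param true_orders named list of true permutations.
#' @return one-row data frame: number of transcripts compared, exact recovery
#'   rate, median Spearman rho, and mean relative position of the first and
#'   last intron.
#' @export
evaluate_orders <- function(orders, true_orders) {
  ok <- orders[orders$status == "ok" & !is.na(orders$most_likely_order), ]
  common <- intersect(ok$transcript_id, names(true_orders))
  if (length(common) == 0) stop("no transcripts in common")
  allids <- intersect(orders$transcript_id, names(true_orders))
  hit <- rho <- rep(NA_real_, length(allids))
  names(hit) <- names(rho) <- allids
  relpos_first <- relpos_last <- numeric(0)
  for (tid in allids) {
    row <- orders[orders$transcript_id == tid, ][1, ]
    if (row$status != "ok" || is.na(row$most_likely_order) ||
        !isTRUE(row$unique)) {
      hit[tid] <- 0
      next
    }
    inferred <- parse_order(row$most_likely_order)
    truth <- as.integer(true_orders[[tid]])
    hit[tid] <- as.numeric(identical(inferred, truth))
    rho[tid] <- order_spearman(inferred, truth)
    rk <- order_rank(inferred)
    n <- length(inferred)
    relpos_first <- c(relpos_first, relative_position(rk[1], n))
    relpos_last <- c(relpos_last, relative_position(rk[n], n))
  }
  data.frame(n_transcripts = length(allids),
             recovery_rate = mean(hit),
             median_rho = stats::median(rho, na.rm = TRUE),
             mean_relpos_first_intron = mean(relpos_first),
             mean_relpos_last_intron = mean(relpos_last))
}

#' Write / read the pair-count table
#'
#' TSV with one row per ordered intron pair with a positive count, plus rows
#' for the both-spliced side table (`kind = "both"`). Metadata lines are
#' prefixed with `#`.
#'
#' @param pair_list named list of [pair_counts()].
#' @param path output path.
#' @param config a [run_config()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pair_list, path, config = run_config()) {
  rows <- list()
  for (tid in names(pair_list)) {
    pc <- pair_list[[tid]]
    idx <- which(pc$A > 0, arr.ind = TRUE)
    if (nrow(idx) > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid, n_introns = pc$n, kind = "pair",
        earlier_intron = idx[, 1], later_intron = idx[, 2],
        read_count = pc$A[idx])
    if (!is.null(pc$both)) {
      bidx <- which(pc$both > 0 & upper.tri(pc$both), arr.ind = TRUE)
      if (nrow(bidx) > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tid, n_introns = pc$n, kind = "both",
          earlier_intron = bidx[, 1], later_intron = bidx[, 2],
          read_count = pc$both[bidx])
    }
    if (nrow(idx) == 0)   # keep transcripts with zero pairs in the file
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid, n_introns = pc$n, kind = "pair",
        earlier_intron = NA_integer_, later_intron = NA_integer_,
        read_count = 0)
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  out <- list()
  for (tid in unique(df$transcript_id)) {
    d <- df[df$transcript_id == tid, ]
    n <- d$n_introns[1]
    A <- matrix(0, n, n)
    B <- matrix(0, n, n)
    p <- d[d$kind == "pair" & !is.na(d$earlier_intron), ]
    if (nrow(p) > 0)
      A[cbind(p$earlier_intron, p$later_intron)] <- p$read_count
    b <- d[d$kind == "both" & !is.na(d$earlier_intron), ]
    if (nrow(b) > 0) {
      B[cbind(b$earlier_intron, b$later_intron)] <- b$read_count
      B[cbind(b$later_intron, b$earlier_intron)] <- b$read_count
    }
    out[[tid]] <- pair_counts(A, tid, both = B)
  }
  out
}

#' Write / read the inferred-orders table
#'
#' @param orders data frame from [infer_orders()].
#' @param path output path.
#' @param config a [run_config()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_orders <- function(orders, path, config = run_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(orders, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_orders
#' @export
read_orders <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a retained-intron PSI table
#'
#' Expected columns: `transcript_id`, `intron_index`, `psi` (tab-separated,
#' compatible with values derived from an external intron-retention caller).
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_ri_psi <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "intron_index", "psi") %in% names(df)))
  df
}

#' Apply the retained-intron correction across transcripts
#'
#' @param pair_list named list of [pair_counts()].
#' @param psi_table data frame as from [read_ri_psi()].
#' @return corrected named list of [pair_counts()].
#' @export
correct_pairs <- function(pair_list, psi_table) {
  for (tid in unique(psi_table$transcript_id)) {
    if (is.null(pair_list[[tid]])) next
    ev <- psi_table[psi_table$transcript_id == tid, ]
    pair_list[[tid]] <- correct_retained_introns(
      pair_list[[tid]],
      data.frame(intron_index = ev$intron_index, psi = ev$psi))
  }
  pair_list
}
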