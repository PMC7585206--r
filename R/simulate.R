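#' Simulate a synthetic multi-intron transcriptome
#'
#' Generates non-overlapping transcript models on one synthetic contig, with
#' uniformly drawn intron counts and fission-yeast-like element sizes by
#' default (exons around 150 bp, introns 50-100 bp). Deterministic given
#' `seed`.
#'
#' @param n_transcripts number of transcripts (default 100).
#' @param intron_min,intron_max intron count range, drawn uniformly
#'   (defaults 3 and 8; must be >= 2).
#' @param exon_mean,exon_sd exon length distribution (rounded normal, floored
#'   at 30 bp).
#' @param intron_range intron lengths drawn uniformly in this range.
#' @param spacing gap between consecutive transcripts on the contig.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return list with `models` (named list of [transcript_model()]), `chrom`,
#'   `contig_length`, and `seed`.
#' @export
simulate_transcriptome <- function(n_transcripts = 100, intron_min = 3,
                                   intron_max = 8, exon_mean = 150,
                                   exon_sd = 30, intron_range = c(50, 100),
                                   spacing = 500, seed = NULL) {
  stopifnot(intron_min >= 2, intron_max >= intron_min, n_transcripts >= 1)
  with_seed(seed, {
    models <- vector("list", n_transcripts)
    pos <- spacing
    chrom <- "sim_contig"
    for (t in seq_len(n_transcripts)) {
      n_in <- sample(intron_min:intron_max, 1)
      n_ex <- n_in + 1
      elen <- pmax(30, round(stats::rnorm(n_ex, exon_mean, exon_sd)))
      ilen <- sample(intron_range[1]:intron_range[2], n_in, replace = TRUE)
      starts <- ends <- numeric(n_ex)
      p <- pos
      for (e in seq_len(n_ex)) {
        starts[e] <- p
        ends[e] <- p + elen[e]
        p <- ends[e] + if (e < n_ex) ilen[e] else 0
      }
      tid <- sprintf("tx%04d", t)
      models[[t]] <- transcript_model(tid, sprintf("gene%04d", t), chrom,
                                      sample(c("+", "-"), 1), starts, ends)
      pos <- p + spacing
    }
    names(models) <- vapply(models, `[[`, "", "transcript_id")
    list(models = models, chrom = chrom, contig_length = pos, seed = seed)
  })
}

#' Assign a uniformly random true splicing order to each transcript
#'
#' @param models named list of [transcript_model()] with at least 2 introns.
#' @param seed optional integer seed.
#' @return named list of integer permutations (splicing-time sequences).
#' @export
random_orders <- function(models, seed = NULL) {
  models <- models[vapply(models, function(m) m$n_introns >= 2, logical(1))]
  with_seed(seed, lapply(models, function(m) sample(m$n_introns)))
}

#' Enumerate the pre-mRNA splicing intermediates of a transcript
#'
#' A transcript with n introns spliced in order `theta` passes through n + 1
#' species: species k is the pre-mRNA with the first k introns of `theta`
#' removed (species 0 the unspliced pre-mRNA, species n the mature mRNA).
#' Each species is represented by its retained genomic segments, which map the
#' molecule back to the genome.
#'
#' @param model a [transcript_model()].
#' @param theta true splicing order.
#' @return list of n + 1 species, each a list with `k`, `removed` (intron
#'   indices spliced so far), `segments` (genomic data frame), `length`
#'   (molecule length in bases).
#' @export
splicing_intermediates <- function(model, theta) {
  n <- model$n_introns
  theta <- check_permutation(theta, n)
  ir <- introns_by_index(model)
  span <- c(min(model$exons$start), max(model$exons$end))
  lapply(0:n, function(k) {
    removed <- sort(theta[seq_len(k)])
    if (k == 0) {
      segs <- data.frame(start = span[1], end = span[2])
    } else {
      cut <- ir[removed, , drop = FALSE]
      cut <- cut[order(cut$start), , drop = FALSE]
      segs <- data.frame(start = c(span[1], cut$end),
                         end = c(cut$start, span[2]))
    }
    list(k = k, removed = removed, segments = segs,
         length = sum(segs$end - segs$start))
  })
}

#' Read-simulation configuration
#'
#' Sequencing modes follow the simulation designs used for validation:
#' 150-bp paired-end short reads with 800-bp fragments, long reads of ~800 bp,
#' super-long reads of ~5000 bp with 6000-bp fragments, and mate-pair reads
#' with fragments up to 15,000 bp. Paired modes sequence `read_length` bases
#' from both fragment ends; long-read modes sequence `read_length` bases from
#' the fragment 5' end.
#'
#' @param mode `"short_pe"`, `"mate_pair"` or `"long_read"`.
#' @param read_length read length in bp.
#' @param fragment_mean,fragment_sd fragment length distribution (rounded
#'   normal; default sd is mean/10). Fragments are clipped to the molecule and,
#'   in paired modes, floored at `2 * read_length`.
#' @param depth expected fragments per splicing intermediate (Poisson mean,
#'   default 100).
#' @return a `read_config` list.
#' @export
read_config <- function(mode = c("short_pe", "mate_pair", "long_read"),
                        read_length = 150, fragment_mean = 800,
                        fragment_sd = fragment_mean / 10, depth = 100) {
  mode <- match.arg(mode)
  stopifnot(read_length >= 1, fragment_mean >= 1, depth > 0)
  if (mode != "long_read" && read_length > fragment_mean)
    stop("read_length must not exceed fragment_mean for paired modes")
  structure(list(mode = mode, read_length = read_length,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 depth = depth),
            class = "read_config")
}

# map molecule-coordinate read intervals onto the genome through the retained
# segments of one species; returns blocks and per-read junction gaps
map_read_intervals <- function(segments, strand, mol_len, read, from, to) {
  if (strand == "-") {
    nf <- mol_len - to
    to <- mol_len - from
    from <- nf
  }
  slen <- segments$end - segments$start
  cum <- cumsum(c(0, slen))
  K <- nrow(segments)
  blocks <- vector("list", K)
  for (k in seq_len(K)) {
    s <- pmax(from, cum[k])
    e <- pmin(to, cum[k + 1])
    keep <- s < e
    if (any(keep))
      blocks[[k]] <- data.frame(
        read = read[keep],
        start = segments$start[k] + (s[keep] - cum[k]),
        end = segments$start[k] + (e[keep] - cum[k]))
  }
  blocks <- do.call(rbind, blocks)
  if (is.null(blocks))
    return(list(blocks = data.frame(read = integer(), start = numeric(),
                                    end = numeric()),
                gaps = data.frame(read = integer(), start = numeric(),
                                  end = numeric())))
  blocks <- blocks[order(blocks$read, blocks$start), , drop = FALSE]
  nr <- nrow(blocks)
  gaps <- data.frame(read = integer(), start = numeric(), end = numeric())
  if (nr > 1) {
    same <- blocks$read[-nr] == blocks$read[-1]
    if (any(same))
      gaps <- data.frame(read = blocks$read[-nr][same],
                         start = blocks$end[-nr][same],
                         end = blocks$start[-1][same])
  }
  list(blocks = blocks, gaps = gaps)
}

#' Simulate aligned fragments from the splicing intermediates of one transcript
#'
#' For every species, a Poisson(`depth`) number of fragments is drawn with
#' uniform start positions and rounded-normal lengths clipped to the molecule.
#' Paired modes emit the two terminal reads of each fragment; long-read mode
#' emits one read of `read_length` bases from the fragment 5' end. Reads are
#' mapped back to genome coordinates, so splice gaps appear exactly where the
#' species has already removed an intron, and both mates are merged into one
#' fragment record. The result feeds [count_order_pairs()] directly, no
#' aligner involved.
#'
#' @param model a [transcript_model()].
#' @param theta true splicing order of the transcript.
#' @param config a [read_config()].
#' @param seed optional integer seed.
#' @return a [fragment_set()].
#' @export
simulate_fragments <- function(model, theta, config = read_config(),
                               seed = NULL) {
  stopifnot(inherits(config, "read_config"))
  species <- splicing_intermediates(model, theta)
  with_seed(seed, {
    all_blocks <- list(); all_gaps <- list(); ids <- character()
    fcount <- 0L
    for (sp in species) {
      L <- sp$length
      nf <- stats::rpois(1, config$depth)
      if (nf == 0) next
      flen <- round(stats::rnorm(nf, config$fragment_mean, config$fragment_sd))
      if (config$mode != "long_read")
        flen <- pmax(flen, 2 * config$read_length)
      flen <- pmin(pmax(flen, 1), L)
      fstart <- floor(stats::runif(nf, 0, L - flen + 1))
      frag <- fcount + seq_len(nf)
      if (config$mode == "long_read") {
        rlen <- pmin(config$read_length, flen)
        res <- map_read_intervals(sp$segments, model$strand, L,
                                  frag, fstart, fstart + rlen)
      } else {
        rl <- pmin(config$read_length, flen)
        m1 <- map_read_intervals(sp$segments, model$strand, L,
                                 frag, fstart, fstart + rl)
        m2 <- map_read_intervals(sp$segments, model$strand, L,
                                 frag, pmax(fstart, fstart + flen - rl),
                                 fstart + flen)
        res <- list(blocks = rbind(m1$blocks, m2$blocks),
                    gaps = unique(rbind(m1$gaps, m2$gaps)))
      }
      names(res$blocks)[1] <- "fragment"
      names(res$gaps)[1] <- "fragment"
      all_blocks[[length(all_blocks) + 1L]] <- res$blocks
      all_gaps[[length(all_gaps) + 1L]] <- res$gaps
      ids <- c(ids, sprintf("%s_sp%d_f%d", model$transcript_id, sp$k,
                            seq_len(nf)))
      fcount <- fcount + nf
    }
    blocks <- if (length(all_blocks)) do.call(rbind, all_blocks)
              else data.frame(fragment = integer(), start = numeric(),
                              end = numeric())
    gaps <- if (length(all_gaps)) do.call(rbind, all_gaps)
            else data.frame(fragment = integer(), start = numeric(),
                            end = numeric())
    fragment_set(ids, rep(model$chrom, fcount), blocks, gaps)
  })
}

#' Simulate reads for a whole transcriptome
#'
#' @param models named list of [transcript_model()].
#' @param orders named list of true orders, as from [random_orders()].
#' @param config a [read_config()].
#' @param seed optional integer seed.
#' @return named list of [fragment_set()], one per transcript.
#' @export
simulate_reads <- function(models, orders, config = read_config(),
                           seed = NULL) {
  with_seed(seed, {
    out <- lapply(names(orders), function(tid)
      simulate_fragments(models[[tid]], orders[[tid]], config))
    names(out) <- names(orders)
    out
  })
}

#' Simulate a pair count matrix directly from a true order
#'
#' For every unordered intron pair, the direction consistent with `theta`
#' receives a Poisson(`mean_reads`) read count and the opposite direction 0.
#'
#' @param n intron count (>= 2).
#' @param theta true splicing order.
#' @param mean_reads Poisson mean per pair (default 15).
#' @param seed optional integer seed.
#' @return a [pair_counts()] object.
#' @export
simulate_pair_counts <- function(n, theta, mean_reads = 15, seed = NULL) {
  stopifnot(n >= 2, mean_reads > 0)
  theta <- check_permutation(theta, n)
  rank <- order_rank(theta)
  with_seed(seed, {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cnt <- stats::rpois(1, mean_reads)
        if (rank[i] < rank[j]) A[i, j] <- cnt else A[j, i] <- cnt
      }
    }
    pair_counts(A)
  })
}

#' Erase a random subset of intron pairs from a count matrix
#'
#' Zeroes both directions of `round((1 - retained_fraction) * n(n-1)/2)`
#' uniformly chosen unordered pairs, emulating pairs that were never sequenced.
#'
#' @param x a [pair_counts()] object or count matrix.
#' @param retained_fraction fraction of pairs to keep, in \[0, 1\].
#' @param seed optional integer seed.
#' @return a [pair_counts()] object.
#' @export
erase_pairs <- function(x, retained_fraction, seed = NULL) {
  stopifnot(retained_fraction >= 0, retained_fraction <= 1)
  pc <- if (inherits(x, "pair_counts")) x else pair_counts(x)
  n <- pc$n
  idx <- which(upper.tri(pc$A), arr.ind = TRUE)
  n_erase <- round((1 - retained_fraction) * nrow(idx))
  if (n_erase == 0) return(pc)
  with_seed(seed, {
    pick <- idx[sample(nrow(idx), n_erase), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      pc$A[pick[r, 1], pick[r, 2]] <- 0
      pc$A[pick[r, 2], pick[r, 1]] <- 0
    }
    pc
  })
}

#' Write the synthetic contig as FASTA
#'
#' Generates a random DNA sequence of the contig length (deterministic given
#' the transcriptome's seed) and writes it with [Biostrings::writeXStringSet()].
#'
#' @param sim result of [simulate_transcriptome()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(sim, path) {
  seq <- with_seed(if (is.null(sim$seed)) NULL else sim$seed + 1L,
                   paste(sample(c("A", "C", "G", "T"), sim$contig_length,
                                replace = TRUE), collapse = ""))
  dss <- Biostrings::DNAStringSet(stats::setNames(seq, sim$chrom))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write the synthetic annotation as GTF
#'
#' @param sim result of [simulate_transcriptome()].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_gtf <- function(sim, path) {
  rows <- lapply(sim$models, function(m)
    data.frame(start = m$exons$start + 1, end = m$exons$end,
               strand = m$strand, transcript_id = m$transcript_id,
               gene_id = m$gene_id))
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(sim$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- "exon"
  gr$source <- "spliceorder_sim"
  gr$transcript_id <- df$transcript_id
  gr$gene_id <- df$gene_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write true splicing orders as TSV
#'
#' @param orders named list of permutations.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_true_orders <- function(orders, path) {
  df <- data.frame(transcript_id = names(orders),
                   n_introns = vapply(orders, length, integer(1)),
                   true_order = vapply(orders, paste, "", collapse = "->"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
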