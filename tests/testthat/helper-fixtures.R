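# fixtures and independent oracles, all built in code

# enumerate all permutations of 1..n as rows (independent of the package)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# brute-force log-likelihood of an order: direct double loop over pairs
brute_loglik <- function(D, theta) {
  n <- length(theta)
  rank <- integer(n); rank[theta] <- seq_len(n)
  ll <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && rank[i] < rank[j]) {
      if (D[i, j] + D[j, i] > 0) ll <- ll + log(D[i, j])
    }
  }
  ll
}

# brute-force maximum over all n! orders; returns best value, all optima
brute_best <- function(D, tol = 1e-9) {
  P <- all_perms(nrow(D))
  vals <- apply(P, 1, function(p) brute_loglik(D, p))
  best <- max(vals)
  list(value = best, optima = P[vals >= best - tol, , drop = FALSE],
       argmin = P[which.min(vals), ], min_value = min(vals), values = vals)
}

# brute-force normalized entropy over all n! orders
brute_entropy <- function(D) {
  P <- all_perms(nrow(D))
  w <- exp(apply(P, 1, function(p) brute_loglik(D, p)))
  p <- w / sum(w)
  -sum(p * log2(p)) / log2(factorial(nrow(D)))
}

# random strictly-positive frequency matrix with rows/cols complementing to 1
random_D <- function(n) {
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- runif(1, 0.05, 0.95)
    D[i, j] <- p; D[j, i] <- 1 - p
  }
  structure(list(transcript_id = NA_character_, n = n, D = D,
                 adjust_value = 0.1),
            class = "frequency_matrix")
}

# a 3-exon plus-strand toy model: exons [100,200), [300,400), [500,600)
toy_model <- function(strand = "+", id = "t1") {
  transcript_model(id, "g1", "chr1", strand,
                   c(100, 300, 500), c(200, 400, 600))
}

# fragment set built from explicit block/gap coordinate lists
make_fragments <- function(blocks, gaps = NULL, chrom = "chr1") {
  nf <- length(blocks)
  bl <- do.call(rbind, lapply(seq_len(nf), function(f) {
    b <- blocks[[f]]
    data.frame(fragment = f, start = b[, 1], end = b[, 2])
  }))
  gp <- if (is.null(gaps)) {
    data.frame(fragment = integer(), start = numeric(), end = numeric())
  } else {
    rows <- lapply(seq_len(nf), function(f) {
      g <- gaps[[f]]
      if (is.null(g) || nrow(g) == 0) return(NULL)
      data.frame(fragment = f, start = g[, 1], end = g[, 2])
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) do.call(rbind, rows)
    else data.frame(fragment = integer(), start = numeric(), end = numeric())
  }
  fragment_set(paste0("frag", seq_len(nf)), rep(chrom, nf), bl, gp)
}

# write a small spliced SAM file and convert it to an indexed BAM
write_test_bam <- function(dir, records,
                           header = c("@HD\tVN:1.6\tSO:coordinate",
                                      "@SQ\tSN:chr1\tLN:10000")) {
  sam <- file.path(dir, "reads.sam")
  writeLines(c(header, records), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                   indexDestination = TRUE)
}
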