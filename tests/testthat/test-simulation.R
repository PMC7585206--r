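test_that("transcriptome generation is deterministic and respects bounds", {
  s1 <- simulate_transcriptome(n_transcripts = 10, intron_min = 3,
                               intron_max = 5, seed = 91)
  s2 <- simulate_transcriptome(n_transcripts = 10, intron_min = 3,
                               intron_max = 5, seed = 91)
  expect_identical(s1, s2)
  expect_length(s1$models, 10)
  for (m in s1$models) {
    expect_true(m$n_introns >= 3 && m$n_introns <= 5)
    expect_true(all(m$introns$length >= 50 & m$introns$length <= 100))
  }
  # byte-identical writer outputs under the same seed
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.fa"); f2 <- file.path(d, "b.fa")
  write_transcriptome_fasta(s1, f1)
  write_transcriptome_fasta(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- file.path(d, "a.gtf")
  write_transcriptome_gtf(s1, g1)
  reread <- suppressMessages(suppressWarnings(read_transcript_models(g1)))
  expect_setequal(names(reread), names(s1$models))
  m0 <- s1$models[[4]]; mr <- reread[[m0$transcript_id]]
  expect_equal(mr$exons, m0$exons)
  expect_equal(mr$introns$index, m0$introns$index)
})

test_that("random order assignment is uniform and reproducible", {
  m <- transcript_model("t", "g", "c", "+",
                        c(0, 200, 400, 600), c(100, 300, 500, 700))
  models <- list(t = m)
  expect_identical(random_orders(models, seed = 5),
                   random_orders(models, seed = 5))
  # single-intron transcripts are omitted
  m1 <- transcript_model("s", "g", "c", "+", c(0, 200), c(100, 300))
  expect_named(random_orders(list(t = m, s = m1), seed = 1), "t")
  # chi-square goodness of fit over the 6 orders of n = 3
  m3 <- transcript_model("t3", "g", "c", "+",
                         c(0, 200, 400, 600), c(100, 300, 500, 700))
  set.seed(42)
  draws <- replicate(6000,
                     paste(random_orders(list(t3 = m3))$t3, collapse = ""))
  tab <- table(draws)
  expect_length(tab, 6)
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("splicing intermediates follow the order definition", {
  m <- transcript_model("t", "g", "c", "+",
                        c(0, 200, 400, 600, 800),
                        c(100, 300, 500, 700, 900))   # 4 introns
  theta <- c(2, 4, 1, 3)
  sp <- splicing_intermediates(m, theta)
  expect_length(sp, 5)                       # n + 1 species
  expect_equal(sp[[1]]$length, 900)          # genomic span
  expect_equal(sp[[5]]$length, 500)          # mature: sum of exon lengths
  expect_equal(sp[[2]]$removed, 2)           # first spliced intron only
  expect_equal(sp[[3]]$removed, c(2, 4))
  # lengths strictly decreasing as introns are removed
  expect_true(all(diff(vapply(sp, `[[`, 0, "length")) < 0))
  # minus-strand: same species contents for the same theta
  mneg <- transcript_model("t", "g", "c", "-",
                           c(0, 200, 400, 600, 800),
                           c(100, 300, 500, 700, 900))
  spn <- splicing_intermediates(mneg, theta)
  # intron index k on minus strand is the genomic interval counted from the
  # right; species 1 must lack exactly that interval
  ir <- mneg$introns
  removed_iv <- ir[ir$index == theta[1], c("start", "end")]
  segs <- spn[[2]]$segments
  expect_false(any(segs$start <= removed_iv$start &
                     segs$end >= removed_iv$end))
})

test_that("simulated fragments carry gaps exactly at spliced introns", {
  set.seed(51)
  sim <- simulate_transcriptome(n_transcripts = 5, seed = 61)
  orders <- random_orders(sim$models, seed = 62)
  cfg <- read_config("long_read", read_length = 5000, fragment_mean = 6000,
                     depth = 40)
  for (tid in names(orders)) {
    m <- sim$models[[tid]]
    fs <- simulate_fragments(m, orders[[tid]], cfg, seed = 63)
    # every gap matches an annotated intron exactly
    key <- paste(fs$gaps$start, fs$gaps$end)
    expect_true(all(key %in% paste(m$introns$start, m$introns$end)))
    # round trip: all detected pairs are consistent with the true order
    rk <- integer(m$n_introns); rk[orders[[tid]]] <- seq_len(m$n_introns)
    obs <- order_pair_observations(fs, m)
    expect_gt(nrow(obs), 0)
    expect_true(all(rk[obs$earlier_intron] < rk[obs$later_intron]))
  }
  # fragments from the unspliced species never contain gaps
  m <- sim$models[[1]]
  n <- m$n_introns
  sp0 <- splicing_intermediates(m, seq_len(n))[[1]]
  expect_equal(sp0$removed, integer(0))
  # determinism of read simulation
  f1 <- simulate_fragments(m, orders[[1]], cfg, seed = 7)
  f2 <- simulate_fragments(m, orders[[1]], cfg, seed = 7)
  expect_identical(f1, f2)
})

test_that("paired-end mates merge into one fragment with split evidence", {
  m <- toy_model("+")
  cfg <- read_config("short_pe", read_length = 50, fragment_mean = 250,
                     depth = 200)
  fs <- simulate_fragments(m, c(2, 1), cfg, seed = 77)
  expect_gt(fs$n_fragments, 0)
  # paired mode: every fragment has at least two blocks (the two mates)
  nblocks <- table(factor(fs$blocks$fragment,
                          levels = seq_len(fs$n_fragments)))
  expect_true(all(nblocks >= 1))
  obs <- order_pair_observations(fs, m)
  rk <- c(2L, 1L); rk[c(2, 1)] <- 1:2
  if (nrow(obs) > 0)
    expect_true(all(rk[obs$earlier_intron] < rk[obs$later_intron]))
})

test_that("direct matrix simulation has the configured Poisson mean", {
  set.seed(71)
  theta <- c(3, 1, 2)
  tot <- 0
  reps <- 4000
  for (r in seq_len(reps)) {
    pc <- simulate_pair_counts(3, theta, mean_reads = 15)
    # inconsistent direction always zero
    expect_equal(pc$A[1, 3] + pc$A[2, 3] + pc$A[2, 1], 0)
    tot <- tot + pc$A[3, 1]
  }
  expect_equal(tot / reps, 15, tolerance = 0.5 / 15 * 3)
  expect_identical(simulate_pair_counts(5, 1:5, seed = 3),
                   simulate_pair_counts(5, 1:5, seed = 3))
})

test_that("pair erasure zeroes the requested number of pairs", {
  A <- matrix(0, 4, 4); A[upper.tri(A)] <- 5
  pc <- pair_counts(A)
  expect_identical(erase_pairs(pc, 1, seed = 1)$A, pc$A)
  expect_equal(sum(erase_pairs(pc, 0, seed = 1)$A), 0)
  half <- erase_pairs(pc, 0.5, seed = 2)
  expect_equal(retention_percentage(half), 0.5)   # exactly 3 of 6 erased
  # erasure zeroes both directions
  A2 <- matrix(3, 4, 4); diag(A2) <- 0
  e <- erase_pairs(pair_counts(A2), 0.5, seed = 3)
  gone <- which((e$A + t(e$A)) == 0 & upper.tri(e$A))
  expect_length(gone, 3)
})
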