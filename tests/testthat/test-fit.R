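test_that("order log-likelihood sums the ordered-pair log frequencies", {
  D <- matrix(0, 2, 2); D[1, 2] <- 0.9; D[2, 1] <- 0.1
  fm <- structure(list(transcript_id = NA, n = 2, D = D, adjust_value = 0),
                  class = "frequency_matrix")
  expect_equal(order_loglik(fm, c(1, 2)), log(0.9))
  expect_equal(order_loglik(fm, c(2, 1)), log(0.1))
  # all-0.5 matrix: every order of n=4 scores 6 * log(0.5)
  D4 <- matrix(0.5, 4, 4); diag(D4) <- 0
  fm4 <- structure(list(transcript_id = NA, n = 4, D = D4, adjust_value = 0),
                   class = "frequency_matrix")
  expect_equal(order_loglik(fm4, c(3, 1, 4, 2)), 6 * log(0.5))
  # pairs with no reads and no pseudo counts contribute nothing
  Dz <- matrix(0, 3, 3); Dz[1, 2] <- 0.8; Dz[2, 1] <- 0.2
  fmz <- structure(list(transcript_id = NA, n = 3, D = Dz, adjust_value = 0),
                   class = "frequency_matrix")
  expect_equal(order_loglik(fmz, c(1, 2, 3)), log(0.8))
  expect_error(order_loglik(fm, c(1, 1)), "permutation")
})

test_that("exhaustive search agrees with literal permutation enumeration", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(3:6, 1)
    fm <- random_D(n)
    oracle <- brute_best(fm$D)
    fit <- splicing_order(fm, method = "exhaustive")
    expect_equal(fit$logLik, oracle$value, tolerance = 1e-12)
    expect_true(any(apply(oracle$optima, 1, identical,
                          as.integer(fit$order))))
    expect_equal(fit$unique, nrow(oracle$optima) == 1)
  }
})

test_that("a transitively consistent matrix recovers its total order", {
  # D[3,1], D[3,2], D[1,2] all > 0.5: most likely order is 3 -> 1 -> 2
  D <- matrix(0, 3, 3)
  D[3, 1] <- 0.8; D[1, 3] <- 0.2
  D[3, 2] <- 0.9; D[2, 3] <- 0.1
  D[1, 2] <- 0.7; D[2, 1] <- 0.3
  fm <- structure(list(transcript_id = NA, n = 3, D = D, adjust_value = 0.1),
                  class = "frequency_matrix")
  fit <- splicing_order(fm)
  expect_equal(fit$order, c(3L, 1L, 2L))
  expect_true(fit$unique)
  # n = 2 single informative pair
  A <- matrix(0, 2, 2); A[1, 2] <- 9
  fit2 <- splicing_order(pair_counts(A))
  expect_equal(fit2$order, c(1L, 2L))
  expect_true(fit2$unique)
})

test_that("an all-0.5 matrix ties every permutation", {
  D <- matrix(0.5, 4, 4); diag(D) <- 0
  fm <- structure(list(transcript_id = NA, n = 4, D = D, adjust_value = 0.1),
                  class = "frequency_matrix")
  fit <- splicing_order(fm)
  expect_false(fit$unique)
  expect_equal(fit$n_optima, factorial(4))
  expect_equal(fit$relative_loglik, 0)
  fit_ilp <- splicing_order(fm, method = "ilp")
  expect_false(fit_ilp$unique)
  expect_equal(fit_ilp$logLik, fit$logLik)
})

test_that("the most unlikely order is the reversed most likely order", {
  expect_equal(most_unlikely_order(c(1, 4, 2, 3)), c(3L, 2L, 4L, 1L))
  expect_equal(most_unlikely_order(c(1, 2)), c(2L, 1L))
  expect_equal(most_unlikely_order(most_unlikely_order(c(3, 1, 2))),
               c(3L, 1L, 2L))
  # minimum-likelihood permutation equals the reversal of the maximum,
  # verified against literal enumeration
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    fm <- random_D(n)
    oracle <- brute_best(fm$D)
    fit <- splicing_order(fm)
    if (fit$unique) {
      expect_equal(as.integer(oracle$argmin), rev(fit$order))
      # and the two log-likelihoods sum to the total over all pairs
      tot <- sum(log(fm$D[upper.tri(fm$D)])) +
        sum(log(t(fm$D)[upper.tri(fm$D)]))
      expect_equal(order_loglik(fm, fit$order) +
                     order_loglik(fm, rev(fit$order)), tot)
    }
  }
})

test_that("branch-and-bound matches exhaustive search on random instances", {
  set.seed(19)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    A <- matrix(rpois(n * n, 5), n, n); diag(A) <- 0
    ex <- splicing_order(pair_counts(A), method = "exhaustive",
                         compute_entropy = FALSE)
    ilp <- splicing_order(pair_counts(A), method = "ilp",
                          compute_entropy = FALSE)
    expect_equal(ilp$logLik, ex$logLik, tolerance = 1e-9)
    expect_equal(ilp$unique, ex$unique)
    if (ex$unique) expect_equal(ilp$order, ex$order)
  }
  # a larger instance in the integer-programming regime stays exact:
  # counts drawn around a known order must recover it
  set.seed(23)
  n <- 14
  th <- sample(n)
  pc <- simulate_pair_counts(n, th, mean_reads = 15)
  fit <- splicing_order(pc, compute_entropy = FALSE)
  expect_equal(fit$method, "ilp")
  expect_equal(fit$order, as.integer(th))
})

test_that("relative log-likelihood is zero iff in-order is optimal", {
  D <- matrix(0, 2, 2); D[1, 2] <- 0.1; D[2, 1] <- 0.9
  fm <- structure(list(transcript_id = NA, n = 2, D = D, adjust_value = 0.1),
                  class = "frequency_matrix")
  fit <- splicing_order(fm)
  expect_equal(fit$order, c(2L, 1L))
  expect_equal(fit$relative_loglik, log(0.1) - log(0.9))
  # identity optimal -> R = 0
  D2 <- t(D)
  fm2 <- structure(list(transcript_id = NA, n = 2, D = D2,
                        adjust_value = 0.1), class = "frequency_matrix")
  expect_equal(splicing_order(fm2)$relative_loglik, 0)
  # R is never positive, and strengthening a non-identity order lowers it
  set.seed(29)
  for (rep in 1:20) {
    fm <- random_D(4)
    expect_lte(splicing_order(fm)$relative_loglik, 1e-12)
  }
  base <- random_D(4)
  prev <- Inf
  for (p in c(0.6, 0.8, 0.95)) {
    fm <- base
    fm$D[4, 1] <- p; fm$D[1, 4] <- 1 - p  # push 4-before-1 evidence up
    r <- splicing_order(fm)$relative_loglik
    expect_lte(r, prev + 1e-12)
    prev <- r
  }
})

test_that("normalized entropy matches enumeration and is 1 for flat matrices", {
  for (n in 2:5) {
    D <- matrix(0.5, n, n); diag(D) <- 0
    fm <- structure(list(transcript_id = NA, n = n, D = D,
                         adjust_value = 0.1), class = "frequency_matrix")
    expect_equal(order_entropy(fm), 1)
  }
  # worked two-intron case
  D <- matrix(0, 2, 2); D[1, 2] <- 0.99; D[2, 1] <- 0.01
  fm <- structure(list(transcript_id = NA, n = 2, D = D, adjust_value = 0.1),
                  class = "frequency_matrix")
  expect_equal(order_entropy(fm), -(0.99 * log2(0.99) + 0.01 * log2(0.01)))
  # exact agreement with literal n! enumeration
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:5, 1)
    fm <- random_D(n)
    expect_equal(order_entropy(fm), brute_entropy(fm$D), tolerance = 1e-10)
    expect_gte(order_entropy(fm), 0)
    expect_lte(order_entropy(fm), 1)
  }
  # pushing one pair from 0.5 toward 1 strictly decreases entropy
  prev <- 1
  for (p in c(0.6, 0.7, 0.85, 0.99)) {
    D <- matrix(0.5, 4, 4); diag(D) <- 0
    D[1, 2] <- p; D[2, 1] <- 1 - p
    fm <- structure(list(transcript_id = NA, n = 4, D = D,
                         adjust_value = 0.1), class = "frequency_matrix")
    h <- order_entropy(fm)
    expect_lt(h, prev)
    prev <- h
  }
})

test_that("results are invariant under relabeling of introns", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    fm <- random_D(n)
    sig <- sample(n)
    fmp <- fm
    fmp$D <- fm$D[order(sig), order(sig)]  # relabeled matrix
    dimnames(fmp$D) <- dimnames(fm$D)
    f1 <- splicing_order(fm)
    f2 <- splicing_order(fmp)
    expect_equal(f2$logLik, f1$logLik, tolerance = 1e-10)
    expect_equal(f2$entropy, f1$entropy, tolerance = 1e-10)
    if (f1$unique)
      expect_equal(order(sig)[f2$order], as.integer(f1$order))
  }
})

test_that("the order survives one wrong long-range pair", {
  # evidence consistent with 1->2->3->4 except the (1,4) pair flipped with
  # comparable weight: the optimum is still 1->2->3->4
  A <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) A[i, j] <- 10
  A[1, 4] <- 0; A[4, 1] <- 10
  fit <- splicing_order(pair_counts(A))
  expect_equal(fit$order, 1:4)
  expect_true(fit$unique)
})

test_that("size limits and method dispatch are enforced", {
  A <- matrix(1, 12, 12); diag(A) <- 0
  expect_error(splicing_order(pair_counts(A), method = "exhaustive"),
               "fewer than 12")
  expect_equal(splicing_order(pair_counts(A),
                              compute_entropy = FALSE)$method, "ilp")
  expect_true(is.na(order_entropy(pair_counts(A))))
  big <- matrix(1, 100, 100); diag(big) <- 0
  expect_error(splicing_order(pair_counts(big)), "too many introns")
})

test_that("fit methods expose the permutation, likelihood and simulation", {
  A <- matrix(0, 3, 3); A[3, 1] <- 8; A[3, 2] <- 7; A[1, 2] <- 9
  fit <- splicing_order(pair_counts(A, "tx1"))
  expect_equal(unname(coef(fit)), c(3L, 1L, 2L))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  expect_output(print(fit), "3 -> 1 -> 2")
  s <- summary(fit)
  expect_equal(s$most_unlikely, c(2L, 1L, 3L))
  expect_output(print(s), "Spearman")
  sims <- simulate(fit, nsim = 3, seed = 1, mean_reads = 20)
  expect_length(sims, 3)
  for (pc in sims) {
    consistent <- pc$A[3, 1] + pc$A[3, 2] + pc$A[1, 2]
    inconsistent <- pc$A[1, 3] + pc$A[2, 3] + pc$A[2, 1]
    expect_equal(inconsistent, 0)
    expect_gte(consistent, 0)
  }
})
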