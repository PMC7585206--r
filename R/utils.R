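# internal helpers

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# validate a permutation of 1..n given as the splicing-time sequence
check_permutation <- function(theta, n = length(theta)) {
  theta <- as.integer(theta)
  if (length(theta) != n || anyNA(theta) || !setequal(theta, seq_len(n)))
    stop("'theta' must be a permutation of 1..", n)
  theta
}

# rank vector: rank[i] = splicing position of intron i
order_rank <- function(theta) {
  rank <- integer(length(theta))
  rank[theta] <- seq_along(theta)
  rank
}
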