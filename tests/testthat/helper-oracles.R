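# Independent oracles used to check the package's implementations.
# These deliberately use the most literal/naive computation available.

# Exact enumeration of the upper-tail hypergeometric formula
#   P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n).
# For N <= 40 every binomial coefficient and partial sum is an integer
# below C(40,20) < 2^53, so double arithmetic is exact and the result is
# the correctly rounded rational value.
oracle_hyper_tail <- function(N, n, M, m) {
  if (m == 0) return(1)
  i <- 0:(m - 1)
  num <- sum(choose(M, i) * choose(N - M, n - i))
  1 - num / choose(N, n)
}

# Literal quadratic-time transcription of the weighted KS walk: the value
# at position j is recomputed from scratch as the sum of the first j steps.
oracle_es_quadratic <- function(metric, hit, weight_p = 1) {
  N <- length(hit)
  Nh <- sum(hit)
  w <- abs(metric)^weight_p
  denom_hit <- sum(w[hit])
  run <- numeric(N)
  for (j in seq_len(N)) {
    s <- 0
    for (i in seq_len(j)) {
      if (hit[i]) s <- s + w[i] / denom_hit
      else s <- s - 1 / (N - Nh)
    }
    run[j] <- s
  }
  # same signed-extremum rule as the implementation: larger magnitude,
  # ties (within 1e-9) toward the positive excursion
  if (max(run) + min(run) >= -1e-9) max(run) else min(run)
}

# Brute-force herb-target projection: triple loop over
# (herb, ingredient, target).
oracle_projection <- function(net) {
  herbs <- names(net$herbs)
  out <- stats::setNames(vector("list", length(herbs)), herbs)
  for (h in herbs) {
    acc <- character(0)
    for (ing in net$herbs[[h]]) {
      for (tg in net$ingredients[[ing]]) acc <- c(acc, tg)
    }
    out[[h]] <- sort(unique(acc))
  }
  out
}

# Random small tripartite network for property tests.
random_network <- function(seed, n_herbs = 4, n_ing = 10, n_targets = 12) {
  withr::with_seed(seed, {
    tab <- data.frame(
      herb_id = sample(sprintf("H%d", seq_len(n_herbs)), n_ing,
                       replace = TRUE),
      ingredient_id = sprintf("i%02d", seq_len(n_ing)),
      ob = runif(n_ing, 30, 90), dl = runif(n_ing, 0.2, 0.9))
    pool <- sprintf("T%02d", seq_len(n_targets))
    tmap <- lapply(seq_len(n_ing), function(i)
      sample(pool, sample.int(4, 1)))
    names(tmap) <- tab$ingredient_id
    build_network(tab, tmap)
  })
}

# Small well-formed ingredient TSV on disk.
write_tiny_ingredient_tsv <- function(path, ob3 = "12.5") {
  writeLines(c(
    "herb_id\tingredient_id\tingredient_name\tob\tdl",
    "YYH\ti1\ticariin\t41.6\t0.45",
    "YYH\ti2\tanhydroicaritin\t45.4\t0.44",
    paste("RCR\ti3\tcompound-x", ob3, "0.21", sep = "\t")), path)
  path
}
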