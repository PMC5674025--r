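toy_matrix <- function(seed = 20, n_genes = 50, n_per_group = 4) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * 2 * n_per_group, 8), n_genes,
                dimnames = list(sprintf("G%03d", seq_len(n_genes)), NULL))
    expression_matrix(m, rep(c("a", "b"), each = n_per_group))
  })
}

test_that("ranking metrics match their formulas on a 5-gene matrix", {
  m <- matrix(c(1, 2, 3, 4,   5, 6, 7, 8,
                10, 10, 10, 10, 10, 10, 10, 10,
                4, 5, 4, 5,   1, 2, 1, 2,
                8, 9, 8, 9,   8, 9, 8, 9,
                0, 1, 0, 1,   5, 6, 5, 6),
              nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), NULL))
  mat <- expression_matrix(m, rep(c("grp1", "grp2"), each = 4))
  rl <- rank_genes(mat, "signal_to_noise")
  for (i in 1:5) {
    x1 <- m[i, 1:4]; x2 <- m[i, 5:8]
    fl <- function(s, mu) max(s, if (mu == 0) 0.2 else 0.2 * abs(mu))
    want <- (mean(x1) - mean(x2)) /
      (fl(sd(x1), mean(x1)) + fl(sd(x2), mean(x2)))
    expect_equal(unname(rl$metric[paste0("g", i)]), want,
                 tolerance = 1e-12)
  }
  expect_false(is.unsorted(-rl$metric))
  # gene up in group 1 has positive score near the top
  expect_gt(rl$metric[["g3"]], 0)
  expect_equal(rl$genes[1], "g3")

  # metric ties (constant genes hit the variance floor) break by symbol
  expect_equal(rank_genes(mat, "log_fc")$genes,
               rank_genes(mat, "log_fc")$genes)
  m2 <- m; m2[1, ] <- m2[2, ] <- 5
  rl2 <- rank_genes(expression_matrix(m2, mat$groups))
  pos <- match(c("g1", "g2"), rl2$genes)
  expect_equal(diff(pos), 1L)  # adjacent, alphabetical
})

test_that("ES hits +1 for a top-gene singleton and rejects degenerate sets", {
  rl <- structure(list(genes = c("A", "B"), metric = c(A = 1, B = -1)),
                  class = "ranked_list")
  expect_equal(enrichment_score(rl, "A", weight_p = 0)$es, 1.0)
  expect_error(enrichment_score(rl, "Q"), "no member")
  expect_error(enrichment_score(rl, c("A", "B")), "entire")
})

test_that("ES equals the literal quadratic-time walk on random instances", {
  for (s in 1:50) {
    withr::with_seed(s, {
      metric <- sort(rnorm(50), decreasing = TRUE)
      genes <- sprintf("G%03d", 1:50)
      rl <- structure(list(genes = genes,
                           metric = stats::setNames(metric, genes)),
                      class = "ranked_list")
      members <- sample(genes, sample(2:20, 1))
      p <- sample(c(0, 1, 1.5), 1)
      mine <- enrichment_score(rl, members, weight_p = p)
      want <- oracle_es_quadratic(metric, genes %in% members, p)
      expect_equal(mine$es, want, tolerance = 1e-12)
    })
  }
})

test_that("ES is invariant to positive rescaling of the metric", {
  withr::with_seed(31, {
    genes <- sprintf("G%03d", 1:60)
    metric <- sort(rnorm(60), decreasing = TRUE)
    rl <- structure(list(genes = genes,
                         metric = stats::setNames(metric, genes)),
                    class = "ranked_list")
    rl2 <- rl; rl2$metric <- rl2$metric * 37.5
    members <- sample(genes, 12)
    expect_equal(enrichment_score(rl, members)$es,
                 enrichment_score(rl2, members)$es, tolerance = 1e-12)
  })
})

test_that("unweighted walk returns to zero and has near-zero mean ES", {
  withr::with_seed(32, {
    genes <- sprintf("G%03d", 1:80)
    metric <- sort(rnorm(80), decreasing = TRUE)
    rl <- structure(list(genes = genes,
                         metric = stats::setNames(metric, genes)),
                    class = "ranked_list")
    es_vals <- replicate(1000, {
      e <- enrichment_score(rl, sample(genes, 10), weight_p = 0)
      expect_lt(abs(e$running[80]), 1e-9)
      e$es
    })
    # the signed extremum is only approximately centred (hit steps are
    # large and rare, miss steps small and frequent), so "near zero" is
    # judged relative to the ES spread, not the standard error
    expect_lt(abs(mean(es_vals)), 0.15 * sd(es_vals))
  })
})

test_that("gsea_run is bitwise deterministic under a fixed seed", {
  mat <- toy_matrix()
  cc <- withr::with_seed(33, gene_set_collection(
    stats::setNames(lapply(1:4, function(i)
      sample(rownames(mat$values), 8)), paste0("s", 1:4))))
  r1 <- gsea_run(mat, cc, n_perm = 50, seed = 123)
  r2 <- gsea_run(mat, cc, n_perm = 50, seed = 123)
  expect_identical(r1, r2)
  expect_true(all(r1$p_nominal > 0 & r1$p_nominal <= 1))
  expect_true(all(abs(r1$es) <= 1))
})

test_that("tiny samples trigger exhaustive enumeration of labelings", {
  mat <- toy_matrix(seed = 34, n_genes = 30, n_per_group = 2)
  cc <- withr::with_seed(35, gene_set_collection(
    list(s1 = sample(rownames(mat$values), 6))))
  res <- gsea_run(mat, cc, n_perm = 1000, seed = 9)
  expect_true(attr(res, "exhaustive"))
  # choose(4,2) - 1 = 5 distinct non-observed labelings
  expect_equal(res$n_perm, 5L)
})

test_that("null data give calibrated nominal p-values", {
  mat <- toy_matrix(seed = 36, n_genes = 300, n_per_group = 6)
  cc <- withr::with_seed(37, gene_set_collection(
    stats::setNames(lapply(1:40, function(i)
      sample(rownames(mat$values), 15)), sprintf("s%02d", 1:40))))
  res <- gsea_run(mat, cc, n_perm = 200, seed = 38)
  frac <- mean(res$p_nominal < 0.05)
  # 40 correlated-ish sets: allow 3 binomial SDs around 0.05
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("a planted coherent set is recovered by the full GSEA run", {
  ex <- gen_expression(500, 8, 0, 0, seed = 40)
  v <- ex$mat$values
  planted <- rownames(v)[1:20]
  v[1:20, 9:16] <- v[1:20, 9:16] + 1.2
  mat <- expression_matrix(v, ex$mat$groups)
  cc <- withr::with_seed(41, gene_set_collection(c(
    stats::setNames(lapply(1:15, function(i)
      sample(rownames(v)[21:500], 20)), paste0("null", 1:15)),
    list(planted = planted))))
  res <- gsea_run(mat, cc, n_perm = 200, seed = 42)
  expect_equal(res$term_id[1], "planted")
  expect_lt(res$p_nominal[1], 0.05)
  expect_lt(res$es[1], 0)  # up in group 2 = negative ES by sign convention
})

test_that("running-sum profile writes a complete TSV", {
  rl <- structure(list(genes = c("A", "B", "C", "D"),
                       metric = c(A = 2, B = 1, C = -1, D = -2)),
                  class = "ranked_list")
  es <- enrichment_score(rl, c("A", "C"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_es_profile(es, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$running, es$running)
  expect_equal(sum(tab$hit), 2L)
})
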