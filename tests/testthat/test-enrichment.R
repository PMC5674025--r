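test_that("tail probability matches exact enumeration on a frozen example", {
  # N=20, n=5, M=4, m=1: 1 - C(16,5)/C(20,5)
  expected <- 1 - choose(16, 5) / choose(20, 5)
  expect_equal(hypergeom_upper_tail(20, 5, 4, 1), expected,
               tolerance = 1e-12)
  expect_equal(expected, 0.7182662, tolerance = 1e-7)
  # empty sum: m = 0 gives exactly 1
  expect_identical(hypergeom_upper_tail(20, 5, 4, 0), 1)
})

test_that("tail probability is monotone in m and point masses sum to 1", {
  N <- 25; M <- 9; n <- 11
  tails <- hypergeom_upper_tail(N, n, M, 0:min(n, M))
  expect_true(all(diff(tails) <= 1e-15))
  point <- tails - c(tails[-1], 0)
  expect_equal(sum(point), 1, tolerance = 1e-12)
})

test_that("argument constraints raise domain errors naming the constraint", {
  expect_error(hypergeom_upper_tail(10, 11, 3, 1), "n <= N")
  expect_error(hypergeom_upper_tail(10, 5, 11, 1), "M <= N")
  expect_error(hypergeom_upper_tail(10, 5, 3, 4), "min\\(n, M\\)")
  expect_error(hypergeom_upper_tail(-1, 0, 0, 0), ">= 0")
})

test_that("tail agrees with a Monte-Carlo estimate within 4 SEs", {
  N <- 60; M <- 18; n <- 14; m <- 6
  p <- hypergeom_upper_tail(N, n, M, m)
  draws <- withr::with_seed(77, stats::rhyper(1e5, M, N - M, n))
  phat <- mean(draws >= m)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(phat - p), 4 * se)
})

test_that("a query equal to one term's members puts that term first", {
  cc <- gene_set_collection(list(hit = c("A", "B", "C", "D"),
                                 other = c("E", "F", "G"),
                                 mixed = c("A", "E", "H")))
  res <- enrich(c("A", "B", "C", "D"), cc, background = LETTERS[1:10])
  expect_equal(res$term_id[1], "hit")
  expect_true(res$significant[1])
  expect_true(all(res$fdr >= res$p))
  expect_equal(res$fdr, stats::p.adjust(res$p, "BH"))
})

test_that("BH adjustment follows the step-up rule on a hand-checked vector", {
  # adjusted_i = min_{j >= i} p_(j) * k / j (hand computation):
  # (0.01, 0.02, 0.03, 0.5) -> (0.04, 0.04, 0.04, 0.5)
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
})

test_that("N counts only annotated background genes; contract fields hold", {
  cc <- gene_set_collection(list(t1 = c("A", "B", "C"),
                                 t2 = c("C", "D", "E")))
  # background has 8 genes but only 5 are annotated
  res <- enrich(c("A", "B", "C"), cc, background = LETTERS[1:8])
  expect_true(all(res$N == 5L))
  expect_true(all(res$m <= pmin(res$n, res$M)))
  expect_true(all(res$M <= res$N & res$n <= res$N))
})

test_that("enrichment is invariant to input order and drops alien query genes", {
  cc <- withr::with_seed(9, {
    u <- sprintf("g%02d", 1:40)
    gene_set_collection(stats::setNames(
      lapply(1:6, function(i) sample(u, 8)), paste0("t", 1:6)))
  })
  bg <- sprintf("G%02d", 1:40)
  q <- c("G01", "G03", "G07", "G11", "G13")
  r1 <- enrich(q, cc, bg)
  r2 <- enrich(rev(q), cc, rev(bg))
  expect_equal(r1, r2)
  expect_message(enrich(c(q, "ZZZ9"), cc, bg), "dropped")
})

test_that("degenerate inputs error or warn as contracted", {
  cc <- gene_set_collection(list(t1 = c("A", "B", "C")))
  expect_error(enrich("A", cc, character(0)), "empty background")
  expect_warning(res <- enrich("Z", cc, c("A", "B", "C", "Z")),
                 "empty query")
  expect_equal(nrow(res), 0L)
})

test_that("identical backgrounds give identical dual results; subsets enforced", {
  cc <- gene_set_collection(list(t1 = c("A", "B", "C"),
                                 t2 = c("D", "E", "F")))
  bg <- LETTERS[1:6]
  d <- dual_background_enrich(c("A", "B"), cc, bg, bg)
  expect_equal(d$all$p, d$ab$p)
  expect_true(all(d$consistency$status %in%
                    c("both", "neither", "all_only", "ab_only")))
  expect_error(dual_background_enrich(c("A"), cc, LETTERS[1:4],
                                      LETTERS[1:6]),
               "subset")
})

test_that("background subsampling keeps the query and is seed-reproducible", {
  cc <- withr::with_seed(12, {
    u <- sprintf("G%02d", 1:60)
    gene_set_collection(stats::setNames(
      lapply(1:8, function(i) sample(u, 10)), paste0("t", 1:8)))
  })
  bg_all <- sprintf("G%02d", 1:60)
  bg_ab <- sprintf("G%02d", 1:30)
  q <- c("G01", "G05", "G09")
  d1 <- dual_background_enrich(q, cc, bg_all, bg_ab,
                               subsample_n = 40, subsample_seed = 13)
  d2 <- dual_background_enrich(q, cc, bg_all, bg_ab,
                               subsample_n = 40, subsample_seed = 13)
  expect_equal(d1, d2)
  # subsampled universes shrink N relative to the full-set run
  full <- dual_background_enrich(q, cc, bg_all, bg_ab)
  expect_lte(d1$all$N[1], full$all$N[1])
  expect_error(dual_background_enrich(q, cc, bg_all, bg_ab,
                                      subsample_n = 40),
               "subsample_seed")
})

test_that("GMT files round-trip a collection exactly", {
  cc <- withr::with_seed(10, {
    u <- sprintf("G%03d", 1:50)
    gene_set_collection(
      stats::setNames(lapply(1:5, function(i) sample(u, 6 + i)),
                      paste0("term", 1:5)),
      description = stats::setNames(paste("desc", 1:5), paste0("term", 1:5)))
  })
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(cc, path)
  back <- read_gmt(path)
  expect_equal(lapply(back, sort), lapply(cc, sort))
  expect_equal(attr(back, "description"), attr(cc, "description"))
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("lonely\tdesc", bad)
  expect_error(read_gmt(bad), "3 fields")
})
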