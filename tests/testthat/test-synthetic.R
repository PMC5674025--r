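test_that("herb-table generator respects the pass fraction end points", {
  all_in <- gen_herb_table(3, 10, frac_passing = 1, seed = 50)
  kept <- screen_ingredients(all_in$table, screen_config(exempt_herbs = character()))
  expect_equal(nrow(kept), 30L)

  none <- gen_herb_table(3, 10, frac_passing = 0, seed = 51)
  expect_warning(kept0 <- screen_ingredients(none$table,
    screen_config(exempt_herbs = character())), NA)
  expect_equal(nrow(kept0), 0L)
})

test_that("pass fraction is calibrated: observed rate within 3 binomial SDs", {
  g <- gen_herb_table(10, 1000, frac_passing = 0.5, seed = 52)
  kept <- screen_ingredients(g$table, screen_config(exempt_herbs = character()))
  frac <- nrow(kept) / 10000
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # truth records exactly the retained rows
  expect_setequal(kept$ingredient_id, g$truth$retained_ids)
})

test_that("generators are pure functions of (parameters, seed)", {
  a <- gen_herb_table(4, 6, 0.5, seed = 53)
  b <- gen_herb_table(4, 6, 0.5, seed = 53)
  expect_identical(a, b)
  c1 <- gen_expression(50, 4, 5, 2, seed = 54)
  c2 <- gen_expression(50, 4, 5, 2, seed = 54)
  expect_identical(c1, c2)
  expect_false(identical(c1$mat$values,
                         gen_expression(50, 4, 5, 2, seed = 55)$mat$values))
})

test_that("exempt herbs survive screening despite failing properties", {
  g <- gen_herb_table(3, 8, 0.5, seed = 56, herb_ids = c("A", "B", "ML"),
                      exempt_herbs = "ML")
  ml <- g$table[g$table$herb_id == "ML", ]
  expect_true(all(ml$dl < 0.18))
  kept <- screen_ingredients(g$table, screen_config(exempt_herbs = "ML"))
  expect_true(all(ml$ingredient_id %in% kept$ingredient_id))
})

test_that("target map plants an exact sharing profile", {
  g <- gen_herb_table(3, 4, 1, seed = 57)
  retained <- screen_ingredients(g$table,
    screen_config(exempt_herbs = character()))
  tm <- gen_target_map(retained, universe_size = 50,
                       sharing_profile = c("2" = 5), seed = 58)
  # small profiles cannot cover every ingredient; the drop warning is the
  # documented behaviour
  net <- suppressWarnings(build_network(retained, tm$tmap))
  h <- common_target_histogram(project_herb_targets(net))
  expect_equal(h[["2"]], 5L)

  # empty profile: no targets at all is infeasible to build a network from,
  # so plant only singletons instead and expect all herb-degrees 1
  tm1 <- gen_target_map(retained, 50, c("1" = 12), seed = 59)
  net1 <- suppressWarnings(build_network(retained, tm1$tmap))
  proj1 <- project_herb_targets(net1)
  expect_true(all(proj1$herb_degree == 1L))

  expect_error(gen_target_map(retained, 50, c("7" = 1), seed = 60),
               "more herbs")
  expect_error(gen_target_map(retained, 3, c("1" = 10), seed = 61),
               "universe")
})

test_that("expression generator plants recoverable effects", {
  ex <- gen_expression(n_genes = 400, n_per_group = 10, n_de = 8,
                       effect_sd_units = 5, seed = 62)
  res <- call_degs(ex$mat)
  expect_true(all(ex$truth$de_genes %in% res$significant))
  # direction encoded as group2 minus group1 sign
  lfc <- res$table$log_fc[match(ex$truth$de_genes, res$table$gene)]
  expect_equal(sign(lfc), unname(ex$truth$direction))
})

test_that("gene-set generator plants a first-ranked term and GMT round-trips", {
  ex <- gen_expression(300, 5, 20, 5, seed = 63)
  u <- rownames(ex$mat$values)
  gs <- gen_gene_sets(n_terms = 12, term_size_range = c(10, 30),
                      planted_term_members = ex$truth$de_genes,
                      seed = 64, universe = u)
  res <- enrich(ex$truth$de_genes, gs$collection, background = u)
  expect_equal(res$term_id[1], gs$truth$planted_id)

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs$collection, path)
  expect_equal(lapply(read_gmt(path), sort),
               lapply(gs$collection, sort))

  single <- gen_gene_sets(1, c(5, 5), NULL, seed = 65, universe = u)
  expect_equal(length(single$collection), 1L)
  expect_null(single$truth$planted_id)
})

test_that("full-study bundles are internally consistent and seed-sensitive", {
  s1 <- gen_full_study(seed = 1)
  s2 <- gen_full_study(seed = 2)
  expect_false(identical(s1$truth$overlap, s2$truth$overlap))

  for (st in list(s1, s2)) {
    # planted overlap lies inside all three truth sets
    expect_true(all(st$truth$overlap %in% st$truth$targets))
    expect_true(all(st$truth$overlap %in% st$truth$disease_over_threshold))
    expect_true(all(st$truth$overlap %in% st$truth$de_genes))
    # truth-level triple intersection equals the plant exactly
    v <- intersect_three(st$truth$disease_over_threshold,
                         st$truth$de_genes, st$truth$targets)
    expect_setequal(v$abc, st$truth$overlap)
    expect_equal(length(v$abc), 81L)
  }
})

test_that("a study bundle writes and re-reads through native formats", {
  st <- gen_full_study(seed = 3)
  dir <- withr::local_tempdir()
  write_study_bundle(st, dir)
  expect_true(all(file.exists(file.path(dir,
    c("ingredients.tsv", "target_map.tsv", "disease_genes.tsv",
      "expression.tsv", "groups.cls", "gene_sets.gmt",
      "gsea_gene_sets.gmt", "truth.json")))))
  tab <- read_ingredient_table(file.path(dir, "ingredients.tsv"),
                               cfg = st$cfg)
  expect_equal(nrow(tab), nrow(st$ingredients))
  ex <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "groups.cls"))
  expect_equal(ex$values, st$expr$values, tolerance = 1e-12)
  expect_equal(as.character(ex$groups), as.character(st$expr$groups))
  cc <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(lapply(cc, sort), lapply(st$collection, sort))
})
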