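# Seeded generators for every input the pipeline consumes, each returning
# the generated object together with a truth record so recovery can be
# asserted exactly. One master seed fans out to per-generator sub-seeds
# (fixed offsets via split_seed), so changing one generator's draws never
# perturbs another's.

#' Generate a herb-ingredient property table
#'
#' Draws OB from a mixture straddling the 30\% threshold and DL from a
#' mixture straddling 0.18, with each row's pass/fail status decided
#' up-front: passing rows draw OB ~ U(30, 100) and DL ~ U(0.18, 1);
#' failing rows fail at least one criterion (OB ~ U(0, 30) and/or
#' DL ~ U(0, 0.18), failure mode uniform over the three combinations).
#' The expected retained fraction therefore equals \code{frac_passing}
#' exactly. Rows of exempt herbs emulate inorganic constituents: low DL,
#' arbitrary OB, retained through the exemption.
#'
#' @param n_herbs number of herbs (>= 1).
#' @param n_ingredients_per_herb rows per herb (recycled to
#'   \code{n_herbs}).
#' @param frac_passing probability a non-exempt row passes both criteria.
#' @param seed integer seed.
#' @param herb_ids optional herb codes (default H01, H02, ...).
#' @param exempt_herbs herb codes whose rows are exempt (default none).
#' @param n_pass_per_herb optional integer vector: exact number of passing
#'   rows per herb instead of Bernoulli draws (used by
#'   \code{\link{gen_full_study}} to plant exact per-herb counts).
#' @return list with \code{table} (an \code{ingredient_table}) and
#'   \code{truth} (logical \code{pass} per row, retained ids, the
#'   parameters and seed).
#' @export
gen_herb_table <- function(n_herbs, n_ingredients_per_herb, frac_passing,
                           seed, herb_ids = NULL,
                           exempt_herbs = character(),
                           n_pass_per_herb = NULL) {
  stopifnot(n_herbs >= 1, frac_passing >= 0, frac_passing <= 1)
  if (is.null(herb_ids)) herb_ids <- sprintf("H%02d", seq_len(n_herbs))
  stopifnot(length(herb_ids) == n_herbs)
  n_per <- rep_len(n_ingredients_per_herb, n_herbs)
  with_seed(seed, {
    herb <- rep(herb_ids, n_per)
    n <- length(herb)
    exempt <- herb %in% exempt_herbs
    if (is.null(n_pass_per_herb)) {
      pass <- stats::runif(n) < frac_passing
    } else {
      stopifnot(length(n_pass_per_herb) == n_herbs,
                all(n_pass_per_herb <= n_per))
      pass <- unlist(lapply(seq_len(n_herbs), function(h) {
        v <- rep(FALSE, n_per[h])
        v[sample(n_per[h], n_pass_per_herb[h])] <- TRUE
        v
      }))
    }
    # exempt rows: inorganic-compound profile (low DL, any OB)
    pass[exempt] <- FALSE
    mode <- sample(3, n, replace = TRUE)  # 1 ob fails, 2 dl fails, 3 both
    # failing draws stop short of the thresholds so 2/3-decimal rounding
    # can never promote a failing row
    ob <- ifelse(pass | mode == 2, stats::runif(n, 30, 100),
                 stats::runif(n, 0, 29.99))
    dl <- ifelse(pass | mode == 1, stats::runif(n, 0.18, 1),
                 stats::runif(n, 0, 0.179))
    dl[exempt] <- stats::runif(sum(exempt), 0, 0.179)
    tab <- data.frame(
      herb_id = herb,
      ingredient_id = sprintf("I%05d", seq_len(n)),
      ingredient_name = sprintf("compound-%05d", seq_len(n)),
      ob = round(ob, 2), dl = round(dl, 3),
      exempt = exempt)
    class(tab) <- c("ingredient_table", "data.frame")
    retained <- pass | exempt
    list(table = tab,
         truth = list(pass = pass, retained = retained,
                      retained_ids = tab$ingredient_id[retained],
                      params = list(n_herbs = n_herbs, n_per = n_per,
                                    frac_passing = frac_passing,
                                    exempt_herbs = exempt_herbs),
                      seed = seed))
  })
}

#' Generate an ingredient-target map with a planted sharing profile
#'
#' Constructs targets so that the exact-mode shared-target histogram of
#' the resulting network reproduces \code{sharing_profile} bin for bin:
#' each profile entry (k, count) creates \code{count} targets assigned to
#' exactly k distinct herbs. Within a herb, its targets are spread over
#' its retained ingredients (shuffled round-robin), so every ingredient is
#' covered whenever the herb receives at least as many target links as it
#' has ingredients.
#'
#' When \code{herb_quota} is supplied (herb -> total target count), each
#' target's k herbs are the ones with the largest remaining quota
#' (deterministic tie-break by position), realizing an exact per-herb
#' degree sequence; otherwise herbs are sampled uniformly.
#'
#' @param retained an \code{ingredient_table} of retained rows.
#' @param universe_size size of the synthetic gene-symbol pool
#'   (G000001...).
#' @param sharing_profile named integer vector, herb-count -> number of
#'   targets (e.g. \code{c("9" = 2, "8" = 9)}); values must sum to at most
#'   \code{universe_size} and no herb-count may exceed the number of
#'   herbs.
#' @param seed integer seed.
#' @param herb_quota optional named integer vector herb_id -> total target
#'   count; must sum to the profile's total herb-degree.
#' @return list with \code{tmap} (named list ingredient -> targets),
#'   \code{truth} (per-herb target sets, the planted histogram, target
#'   symbols, parameters and seed).
#' @export
gen_target_map <- function(retained, universe_size, sharing_profile, seed,
                           herb_quota = NULL) {
  ks <- as.integer(names(sharing_profile))
  cnt <- as.integer(sharing_profile)
  stopifnot(length(ks) == length(cnt), all(cnt >= 0), all(ks >= 1))
  herbs <- unique(retained$herb_id)
  if (any(ks > length(herbs)))
    stop("infeasible profile: more herbs requested than exist (",
         max(ks), " > ", length(herbs), ")")
  n_targets <- sum(cnt)
  if (n_targets > universe_size)
    stop("infeasible profile: ", n_targets, " targets > universe size ",
         universe_size)
  total_degree <- sum(ks * cnt)
  if (!is.null(herb_quota)) {
    stopifnot(setequal(names(herb_quota), herbs))
    if (sum(herb_quota) != total_degree)
      stop("herb_quota must sum to the profile's total herb-degree (",
           total_degree, ")")
    herb_quota <- herb_quota[herbs]
  }

  with_seed(seed, {
    pool <- sprintf("G%06d", seq_len(universe_size))
    targets <- sample(pool, n_targets)
    target_k <- rep(ks, cnt)
    # decreasing k keeps the quota-greedy construction feasible
    ord <- order(-target_k)
    targets_o <- targets[ord]
    target_k_o <- target_k[ord]

    quota <- herb_quota
    herb_targets <- stats::setNames(
      replicate(length(herbs), character(0), simplify = FALSE), herbs)
    for (i in seq_along(targets_o)) {
      k <- target_k_o[i]
      chosen <- if (is.null(quota)) {
        sample(herbs, k)
      } else {
        avail <- which(quota > 0)
        if (length(avail) < k)
          stop("infeasible herb_quota: cannot place a ", k, "-herb target")
        herbs[avail[order(-quota[avail])][seq_len(k)]]
      }
      for (h in chosen) herb_targets[[h]] <- c(herb_targets[[h]],
                                               targets_o[i])
      if (!is.null(quota)) quota[chosen] <- quota[chosen] - 1L
    }
    if (!is.null(quota) && any(quota != 0))
      stop("infeasible herb_quota: unfilled demand remains")

    # spread each herb's targets over its ingredients (shuffled round-robin)
    tmap <- list()
    for (h in herbs) {
      ings <- sample(retained$ingredient_id[retained$herb_id == h])
      tg <- herb_targets[[h]]
      if (length(tg) == 0L) next
      idx <- rep_len(seq_along(ings), length(tg))
      for (j in seq_along(ings)) {
        mem <- tg[idx == j]
        if (length(mem))
          tmap[[ings[j]]] <- sort(unique(c(tmap[[ings[j]]], mem)))
      }
    }
    hist_truth <- stats::setNames(cnt[order(ks)],
                                  as.character(sort(ks)))
    list(tmap = tmap,
         truth = list(herb_targets = lapply(herb_targets,
                                            function(v) sort(unique(v))),
                      histogram = hist_truth[hist_truth > 0],
                      targets = sort(targets),
                      params = list(universe_size = universe_size,
                                    sharing_profile = sharing_profile,
                                    herb_quota = herb_quota),
                      seed = seed))
  })
}

#' Generate a two-group log-expression matrix with planted DEGs
#'
#' Baseline log2 intensities are i.i.d. Normal(8, 1) (so the within-group
#' SD is 1); each planted differentially expressed gene is mean-shifted in
#' group 2 by \code{effect_sd_units} within-group SDs, in a random (or
#' supplied) direction.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (>= 3).
#' @param n_de number of planted DEGs.
#' @param effect_sd_units shift size in within-group SD units.
#' @param seed integer seed.
#' @param genes optional gene symbols (default G000001...).
#' @param de_genes optional planted DEG symbols (default: random subset).
#' @param de_direction optional +1/-1 vector for the planted genes
#'   (+1 = up in group 2).
#' @return list with \code{mat} (an \code{\link{expression_matrix}},
#'   groups \code{g1}/\code{g2}) and \code{truth} (DE genes, directions,
#'   effect, seed).
#' @export
gen_expression <- function(n_genes, n_per_group, n_de, effect_sd_units,
                           seed, genes = NULL, de_genes = NULL,
                           de_direction = NULL) {
  stopifnot(n_de <= n_genes, n_per_group >= 3)
  if (is.null(genes)) genes <- sprintf("G%06d", seq_len(n_genes))
  stopifnot(length(genes) == n_genes)
  with_seed(seed, {
    if (is.null(de_genes)) de_genes <- sample(genes, n_de)
    stopifnot(all(de_genes %in% genes), length(de_genes) == n_de)
    if (is.null(de_direction))
      de_direction <- sample(c(-1, 1), n_de, replace = TRUE)
    stopifnot(length(de_direction) == n_de,
              all(de_direction %in% c(-1, 1)))
    vals <- matrix(stats::rnorm(n_genes * 2 * n_per_group, mean = 8, sd = 1),
                   nrow = n_genes,
                   dimnames = list(genes,
                                   paste0("s", seq_len(2 * n_per_group))))
    g2 <- (n_per_group + 1):(2 * n_per_group)
    idx <- match(de_genes, genes)
    vals[idx, g2] <- vals[idx, g2] + de_direction * effect_sd_units
    mat <- expression_matrix(vals, rep(c("g1", "g2"), each = n_per_group))
    list(mat = mat,
         truth = list(de_genes = de_genes,
                      direction = stats::setNames(de_direction, de_genes),
                      effect_sd_units = effect_sd_units, seed = seed))
  })
}

#' Generate a gene-set collection with an optional planted term
#'
#' Random terms are sampled uniformly from the universe; the planted term
#' (if any) contains exactly the supplied members and is the recovery
#' handle for enrichment tests.
#'
#' @param n_terms number of random terms.
#' @param term_size_range length-2 integer vector (min, max) of random
#'   term sizes.
#' @param planted_term_members optional character vector of member genes.
#' @param seed integer seed.
#' @param universe character vector the random terms are drawn from.
#' @param planted_id term id of the planted term (default
#'   \code{"PLANTED"}).
#' @return list with \code{collection} (a
#'   \code{\link{gene_set_collection}}) and \code{truth} (planted term id
#'   and members, seed).
#' @export
gen_gene_sets <- function(n_terms, term_size_range, planted_term_members =
                            NULL, seed, universe,
                          planted_id = "PLANTED") {
  stopifnot(length(term_size_range) == 2L,
            term_size_range[1] >= 1,
            term_size_range[2] <= length(universe),
            term_size_range[1] <= term_size_range[2])
  with_seed(seed, {
    sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                    n_terms, replace = TRUE)
    sets <- lapply(sizes, function(s) sample(universe, s))
    names(sets) <- sprintf("T%04d", seq_len(n_terms))
    if (!is.null(planted_term_members)) {
      stopifnot(length(planted_term_members) >= 1)
      sets[[planted_id]] <- unique(planted_term_members)
    }
    list(collection = gene_set_collection(sets),
         truth = list(planted_id = if (is.null(planted_term_members)) NULL
                      else planted_id,
                      planted_members =
                        if (is.null(planted_term_members)) NULL
                        else sort(unique(normalize_symbols(
                          planted_term_members))),
                      seed = seed))
  })
}

#' Generate a complete synthetic study bundle
#'
#' A miniature end-to-end analog of the whole analysis — screening, network
#' construction, disease-gene filtering, differential expression, triple
#' intersection, over-representation and GSEA — with defaults that plant
#' the canonical study conditions of the motivating ten-herb formula
#' analysis: per-herb retained ingredient counts (23, 6, 9, 38, 3, 3, 8,
#' 6, 5, 4; 105 in all, with the exempt mineral herb ML retained through
#' the exemption), an 806-target universe realized against the per-herb
#' target counts (246, 198, 215, 115, 69, 32, 223, 358, 149, 182), the
#' shared-target histogram bins 4-9 = (69, 65, 30, 23, 9, 2) with the
#' remaining 608 targets split 461/147 over degrees 1/2, and an 81-gene
#' overlap planted so that disease genes \eqn{\cap} targets equals the
#' overlap exactly (every overlap gene is differentially expressed at 5
#' within-group SDs, so the recovered triple intersection is exact).
#'
#' @param seed master integer seed; sub-generators receive fixed-offset
#'   sub-seeds.
#' @param n_genes size of the synthetic gene universe (default 3000).
#' @param n_per_group samples per expression group (default 10).
#' @param n_overlap size of the planted disease/DEG/target overlap
#'   (default 81).
#' @param effect_sd_units planted DE effect size (default 5).
#' @param gsea_effect_sd_units coherent up-shift of the planted GSEA set,
#'   in within-group SDs (default 1): a subtle pathway-level signal, the
#'   regime GSEA is designed to detect.
#' @param n_random_terms random gene-set terms (default 50).
#' @return object of class \code{synthetic_study}: list with
#'   \code{ingredients} (full table incl. failing rows), \code{cfg} (the
#'   screen configuration), \code{tmap}, \code{disease} (gene/score
#'   table), \code{expr} (an \code{expression_matrix}), \code{collection}
#'   (gene sets for over-representation incl. the planted term),
#'   \code{gsea_collection} (null terms from unaffected genes plus the
#'   planted coherently up-regulated set) and \code{truth}.
#' @export
gen_full_study <- function(seed = 1, n_genes = 3000, n_per_group = 10,
                           n_overlap = 81, effect_sd_units = 5,
                           gsea_effect_sd_units = 1,
                           n_random_terms = 50) {
  herbs <- c("YYH", "RCR", "NZZ", "DS", "YJ", "EZ", "YMC", "HSW", "ML", "BJ")
  n_retained <- c(23, 6, 9, 38, 3, 3, 8, 6, 5, 4)
  herb_quota <- stats::setNames(
    c(246, 198, 215, 115, 69, 32, 223, 358, 149, 182), herbs)
  profile <- c("1" = 461, "2" = 147, "4" = 69, "5" = 65, "6" = 30,
               "7" = 23, "8" = 9, "9" = 2)
  cfg <- screen_config(exempt_herbs = "ML")

  ht <- gen_herb_table(
    n_herbs = 10,
    n_ingredients_per_herb = n_retained * 3 + 4,
    frac_passing = 1 / 3, seed = split_seed(seed, 1),
    herb_ids = herbs, exempt_herbs = "ML",
    n_pass_per_herb = ifelse(herbs == "ML", 0L, n_retained))
  # ML passes nothing numerically; its first 5 rows stand for the 5
  # retained inorganic compounds, the rest are trimmed so the exemption
  # retains exactly 5.
  ml_rows <- which(ht$table$herb_id == "ML")
  drop <- ml_rows[-seq_len(n_retained[herbs == "ML"])]
  ht$table <- ht$table[-drop, , drop = FALSE]
  ht$truth$pass <- ht$truth$pass[-drop]
  ht$truth$retained <- ht$truth$retained[-drop]
  rownames(ht$table) <- NULL
  ht$truth$retained_ids <-
    ht$table$ingredient_id[ht$truth$retained]

  retained <- screen_ingredients(ht$table, cfg)
  tm <- gen_target_map(retained, universe_size = n_genes,
                       sharing_profile = profile,
                       seed = split_seed(seed, 2),
                       herb_quota = herb_quota)

  rest <- with_seed(split_seed(seed, 3), {
    targets <- tm$truth$targets
    universe <- sprintf("G%06d", seq_len(n_genes))
    overlap <- sample(targets, n_overlap)

    # disease list: overlap genes + extra high-score genes OUTSIDE the
    # target set (so disease ∩ targets is exactly the planted overlap),
    # plus sub-threshold noise records.
    non_target <- setdiff(universe, targets)
    extra_a <- sample(non_target, 219)
    noise <- sample(setdiff(non_target, extra_a), 100)
    disease <- data.frame(
      gene = c(overlap, extra_a, noise),
      score = c(stats::runif(n_overlap + 219, 5.001, 100),
                stats::runif(100, 0, 5)))
    disease <- disease[sample(nrow(disease)), , drop = FALSE]
    rownames(disease) <- NULL

    # planted DEGs: the overlap (directions fixed: first 40 up in group 2)
    # + 100 extra DEGs inside disease-but-not-target (so the A∩B
    # background exceeds the overlap) + 20 elsewhere.
    dir_overlap <- c(rep(1, min(40, n_overlap)),
                     rep(-1, max(0, n_overlap - 40)))
    extra_b_in_a <- sample(extra_a, 100)
    extra_b_out <- sample(setdiff(non_target, c(extra_a, noise)), 20)
    de_genes <- c(overlap, extra_b_in_a, extra_b_out)
    de_dir <- c(dir_overlap,
                sample(c(-1, 1), length(de_genes) - n_overlap,
                       replace = TRUE))
    # the GSEA plant: a separate pathway-style set of genes, outside the
    # disease list, the targets and the strong DEG plant, that will get a
    # moderate coherent up-shift (subtle coordinate regulation is the
    # regime GSEA is built to detect; a 5-SD single-gene effect would
    # dominate the phenotype-permutation null instead)
    gsea_genes <- sample(setdiff(non_target,
                                 c(extra_a, noise, extra_b_out)),
                         30)
    list(universe = universe, overlap = sort(overlap), disease = disease,
         de_genes = de_genes, de_dir = de_dir, gsea_genes = gsea_genes)
  })

  ex <- gen_expression(
    n_genes = n_genes, n_per_group = n_per_group,
    n_de = length(rest$de_genes), effect_sd_units = effect_sd_units,
    seed = split_seed(seed, 4), genes = rest$universe,
    de_genes = rest$de_genes, de_direction = rest$de_dir)
  # add the deterministic coherent up-shift of the GSEA plant in group 2
  vals <- ex$mat$values
  g2_cols <- which(ex$mat$groups == levels(ex$mat$groups)[2])
  vals[match(rest$gsea_genes, rest$universe), g2_cols] <-
    vals[match(rest$gsea_genes, rest$universe), g2_cols] +
    gsea_effect_sd_units
  expr <- expression_matrix(vals, ex$mat$groups)

  planted_ora <- with_seed(split_seed(seed, 5), {
    inside <- sample(rest$overlap, 30)
    outside <- sample(setdiff(rest$universe,
                              c(rest$disease$gene, rest$de_genes,
                                rest$gsea_genes)), 10)
    c(inside, outside)
  })
  gs <- gen_gene_sets(n_terms = n_random_terms,
                      term_size_range = c(20, 100),
                      planted_term_members = planted_ora,
                      seed = split_seed(seed, 7),
                      universe = rest$universe,
                      planted_id = "PLANTED_ORA")
  collection <- gs$collection
  # GSEA null terms are drawn from genes with no planted effect: a term
  # containing strongly differentially expressed genes is genuinely
  # phenotype-associated, so leaving such terms in the "random" pool would
  # plant more than one enriched set.
  gsea_gs <- gen_gene_sets(n_terms = n_random_terms,
                           term_size_range = c(20, 100),
                           planted_term_members = rest$gsea_genes,
                           seed = split_seed(seed, 8),
                           universe = setdiff(rest$universe,
                                              c(ex$truth$de_genes,
                                                rest$gsea_genes)),
                           planted_id = "PLANTED_GSEA")
  gsea_collection <- gsea_gs$collection

  truth <- list(
    retained_ids = ht$truth$retained_ids,
    n_retained_per_herb = stats::setNames(n_retained, herbs),
    herb_targets = tm$truth$herb_targets,
    herb_quota = herb_quota,
    histogram = tm$truth$histogram,
    targets = tm$truth$targets,
    de_genes = ex$truth$de_genes,
    de_direction = ex$truth$direction,
    effect_sd_units = effect_sd_units,
    gsea_genes = sort(rest$gsea_genes),
    gsea_effect_sd_units = gsea_effect_sd_units,
    disease_over_threshold =
      sort(rest$disease$gene[rest$disease$score > 5]),
    overlap = rest$overlap,
    planted_ora_term = "PLANTED_ORA",
    planted_gsea_term = "PLANTED_GSEA",
    seed = seed)

  structure(list(ingredients = ht$table, cfg = cfg, tmap = tm$tmap,
                 disease = rest$disease, expr = expr,
                 collection = collection, gsea_collection = gsea_collection,
                 truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study bundle (seed", x$truth$seed, "):\n")
  cat(" ", nrow(x$ingredients), "ingredient rows over",
      length(unique(x$ingredients$herb_id)), "herbs;",
      length(x$truth$retained_ids), "retained\n")
  cat(" ", length(x$truth$targets), "network targets; planted overlap",
      length(x$truth$overlap), "genes\n")
  cat(" ", nrow(x$expr$values), "x", ncol(x$expr$values),
      "expression matrix;", length(x$truth$de_genes), "planted DEGs\n")
  cat(" ", length(x$collection), "ORA gene sets (term",
      x$truth$planted_ora_term, "planted );",
      length(x$gsea_collection), "GSEA gene sets (term",
      x$truth$planted_gsea_term, "planted )\n")
  invisible(x)
}

#' Write a study bundle to disk in native formats
#'
#' TSV for the ingredient/disease tables and expression matrix, CLS for
#' the group labels, GMT for the gene sets, JSON for the truth record
#' (requires the jsonlite package).
#'
#' @param study a \code{\link{gen_full_study}} bundle.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$ingredients,
                     file.path(dir, "ingredients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tmap_tab <- data.frame(
    ingredient_id = rep(names(study$tmap), lengths(study$tmap)),
    target = unlist(study$tmap, use.names = FALSE))
  utils::write.table(tmap_tab, file.path(dir, "target_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$disease, file.path(dir, "disease_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(study$expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "groups.cls"))
  write_gmt(study$collection, file.path(dir, "gene_sets.gmt"))
  write_gmt(study$gsea_collection, file.path(dir, "gsea_gene_sets.gmt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    warning("jsonlite not available; truth.json not written")
  }
  invisible(dir)
}
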