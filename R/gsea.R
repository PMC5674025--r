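#' Rank genes by a two-group association metric
#'
#' Produces the ranked list that drives the enrichment-score walk. The
#' default metric is signal-to-noise, \eqn{(\mu_1 - \mu_2)/(\sigma_1 +
#' \sigma_2)}, the classic GSEA default; \code{t_stat} is Welch's t and
#' \code{log_fc} the plain mean difference. All three are signed so that a
#' gene up-shifted in the FIRST group (first factor level) gets a positive
#' value and ranks near the top.
#'
#' For the variance-based metrics each group's standard deviation is
#' floored at \code{0.2 * |mean|} (and at 0.2 when the mean is 0), the
#' reference implementation's guard against zero-variance genes blowing up
#' the denominator.
#'
#' Ties in the metric are broken by gene symbol so runs are reproducible.
#'
#' @param mat an \code{\link{expression_matrix}}.
#' @param metric \code{"signal_to_noise"} (default), \code{"t_stat"} or
#'   \code{"log_fc"}.
#' @return object of class \code{ranked_list}: list with \code{genes}
#'   (best-to-worst) and \code{metric} (named numeric, non-increasing).
#' @export
rank_genes <- function(mat,
                       metric = c("signal_to_noise", "t_stat", "log_fc")) {
  metric <- match.arg(metric)
  stopifnot(inherits(mat, "expression_matrix"))
  x <- mat$values
  g <- mat$groups
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  if (metric != "log_fc" && (length(i1) < 2L || length(i2) < 2L))
    stop("variance-based metrics need >= 2 samples per group")
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  row_sd <- function(xx) {
    nn <- ncol(xx)
    mu <- rowMeans(xx)
    sqrt(pmax(0, (rowSums(xx * xx) - nn * mu * mu) / (nn - 1)))
  }
  floor_sd <- function(s, mu) {
    lo <- 0.2 * abs(mu)
    lo[lo == 0] <- 0.2
    pmax(s, lo)
  }
  score <- switch(metric,
    log_fc = m1 - m2,
    signal_to_noise = {
      s1 <- floor_sd(row_sd(x[, i1, drop = FALSE]), m1)
      s2 <- floor_sd(row_sd(x[, i2, drop = FALSE]), m2)
      (m1 - m2) / (s1 + s2)
    },
    t_stat = {
      s1 <- floor_sd(row_sd(x[, i1, drop = FALSE]), m1)
      s2 <- floor_sd(row_sd(x[, i2, drop = FALSE]), m2)
      (m1 - m2) / sqrt(s1^2 / length(i1) + s2^2 / length(i2))
    })
  genes <- rownames(x)
  ord <- order(-score, genes)
  structure(list(genes = genes[ord],
                 metric = stats::setNames(score[ord], genes[ord])),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("Ranked list of", length(x$genes), "genes; metric range [",
      signif(min(x$metric), 4), ",", signif(max(x$metric), 4), "]\n")
  invisible(x)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down the ranked list, incrementing a running sum at each member
#' ("hit") by \eqn{|r_i|^p} normalized by the sum over hits, and
#' decrementing at each non-member ("miss") by \eqn{1/(N - N_h)}. The
#' enrichment score is the maximum-magnitude deviation of the walk from
#' zero, signed: positive when members concentrate at the top of the list.
#' With \code{weight_p = 0} the walk is the classic unweighted KS statistic
#' and returns exactly to 0 at the end of the list.
#'
#' If every hit has metric exactly 0 (so the weighted increments are
#' undefined), equal hit weights are used, which is the \code{weight_p = 0}
#' behaviour.
#'
#' @param ranked a \code{\link{rank_genes}} result.
#' @param members character vector of gene symbols; must intersect the
#'   ranked list but not cover it entirely.
#' @param weight_p weighting exponent on the metric (default 1).
#' @return object of class \code{gsea_es}: list with \code{es},
#'   \code{running} (the full profile, one value per list position),
#'   \code{hits} (member positions), \code{arg_es} (position of the
#'   extremum).
#' @examples
#' rl <- structure(list(genes = c("A", "B"),
#'                      metric = c(A = 1, B = -1)),
#'                 class = "ranked_list")
#' enrichment_score(rl, "A", weight_p = 0)$es   # 1
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_list"), weight_p >= 0)
  members <- unique(normalize_symbols(members))
  hit <- ranked$genes %in% members
  n <- length(hit)
  nh <- sum(hit)
  if (nh == 0L) stop("no member of the set appears in the ranked list")
  if (nh == n) stop("the set covers the entire ranked list")
  es_walk(abs(ranked$metric)^weight_p, hit, n, nh,
          positions = which(hit), genes = ranked$genes)
}

# Core walk given precomputed |metric|^p weights and hit indicator.
# The signed ES is the larger-magnitude excursion; an exact tie between
# the positive and negative extremes (possible in the unweighted walk) is
# resolved toward the positive side, with a 1e-9 tolerance so floating-
# point accumulation order cannot flip the choice.
es_walk <- function(w, hit, n, nh, positions = which(hit), genes = NULL) {
  wh <- sum(w[hit])
  inc <- if (wh > 0) w / wh else rep(1 / nh, n)
  step <- ifelse(hit, inc, -1 / (n - nh))
  running <- cumsum(step)
  up <- max(running); dn <- min(running)
  if (up + dn >= -1e-9) {
    es <- up; i <- which.max(running)
  } else {
    es <- dn; i <- which.min(running)
  }
  structure(list(es = es, running = running, hits = positions,
                 arg_es = i, genes = genes),
            class = "gsea_es")
}

#' @export
print.gsea_es <- function(x, ...) {
  cat("Enrichment score:", signif(x$es, 6), "at position", x$arg_es,
      "of", length(x$running), "(", length(x$hits), "hits )\n")
  invisible(x)
}

#' Plot the running-sum profile
#'
#' @param x a \code{gsea_es}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.gsea_es <- function(x, ...) {
  graphics::plot(x$running, type = "l", xlab = "rank",
                 ylab = "running ES", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::rug(x$hits)
  graphics::abline(v = x$arg_es, lty = 2)
  invisible(x)
}

#' Write a running-sum profile as TSV
#'
#' @param es a \code{gsea_es}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_es_profile <- function(es, path) {
  stopifnot(inherits(es, "gsea_es"))
  tab <- data.frame(rank = seq_along(es$running),
                    gene = es$genes %||% NA_character_,
                    hit = seq_along(es$running) %in% es$hits,
                    running = es$running)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Gene Set Enrichment Analysis with phenotype permutation
#'
#' Full GSEA in three steps: (1) the weighted Kolmogorov-Smirnov
#' enrichment score of each set on the observed ranking
#' (\code{\link{enrichment_score}}); (2) significance by permuting the
#' phenotype labels \code{n_perm} times and recomputing the ranking and
#' every set's ES under each permutation — nominal p is the fraction of
#' same-sign null scores at least as extreme as the observed one, with a
#' +1 pseudo-count in numerator and denominator so p is never exactly 0;
#' (3) multiple-testing control by the signed-null NES procedure: each ES
#' (observed and null) is divided by the mean |null ES| of its sign for its
#' set, null NES values are pooled across sets, and the FDR q of an
#' observed NES* is the ratio of the tail fraction in the pooled null to
#' the tail fraction among observed NES values of the same sign (capped at
#' 1).
#'
#' When the requested \code{n_perm} exceeds the number of distinct label
#' assignments (small samples), all distinct non-observed assignments are
#' enumerated instead and the result is flagged \code{exhaustive}.
#'
#' @param mat an \code{\link{expression_matrix}}.
#' @param collection a \code{\link{gene_set_collection}}; sets are used
#'   when 1 <= (members in matrix) < (number of genes).
#' @param n_perm number of phenotype permutations (default 1000, >= 10).
#' @param seed integer seed for the permutation stream (required: results
#'   are only reproducible given the seed).
#' @param metric ranking metric, see \code{\link{rank_genes}}.
#' @param weight_p ES weighting exponent (default 1).
#' @return data.frame of class \code{gsea_result}, one row per tested set,
#'   sorted by |NES| descending: \code{term_id}, \code{size}, \code{es},
#'   \code{nes}, \code{p_nominal}, \code{fdr_q}, \code{n_perm},
#'   \code{seed}. Attribute \code{"exhaustive"} says whether the
#'   permutation space was enumerated.
#' @export
gsea_run <- function(mat, collection, n_perm = 1000, seed,
                     metric = c("signal_to_noise", "t_stat", "log_fc"),
                     weight_p = 1) {
  metric <- match.arg(metric)
  stopifnot(inherits(mat, "expression_matrix"),
            inherits(collection, "gene_set_collection"),
            n_perm >= 10, !missing(seed))
  genes <- rownames(mat$values)
  ngene <- length(genes)
  keep <- vapply(collection, function(mem) {
    k <- sum(mem %in% genes)
    k >= 1L && k < ngene
  }, NA)
  if (!any(keep)) stop("no gene set overlaps the expression matrix")
  sets <- collection[keep]
  set_member <- lapply(sets, function(mem) genes %in% mem)

  ranked <- rank_genes(mat, metric)
  obs <- lapply(set_member, function(ind)
    enrichment_score(ranked, genes[ind], weight_p)$es)
  obs_es <- unlist(obs)

  # Permutation labelings: either sampled or exhaustively enumerated.
  g <- mat$groups
  nsamp <- length(g)
  n1 <- sum(g == levels(g)[1])
  n_distinct <- choose(nsamp, n1)
  exhaustive <- (n_distinct - 1) < n_perm
  perms <- with_seed(seed, {
    if (exhaustive) {
      cols <- utils::combn(nsamp, n1)
      obs_idx <- which(g == levels(g)[1])
      keep_col <- !apply(cols, 2, function(cc) identical(cc, obs_idx))
      lapply(which(keep_col), function(j) cols[, j])
    } else {
      lapply(seq_len(n_perm), function(i) sample(nsamp, n1))
    }
  })
  n_used <- length(perms)

  null_es <- matrix(NA_real_, nrow = length(sets), ncol = n_used,
                    dimnames = list(names(sets), NULL))
  for (j in seq_len(n_used)) {
    gp <- factor(ifelse(seq_len(nsamp) %in% perms[[j]],
                        levels(g)[1], levels(g)[2]), levels = levels(g))
    pm <- structure(list(values = mat$values, groups = gp),
                    class = "expression_matrix")
    rl <- rank_genes(pm, metric)
    w <- abs(rl$metric)^weight_p
    ord_idx <- match(rl$genes, genes)
    for (s in seq_along(sets)) {
      hit <- set_member[[s]][ord_idx]
      null_es[s, j] <- es_walk(w, hit, ngene, sum(hit))$es
    }
  }

  # Nominal p and NES against the same-sign null of each set.
  p_nom <- nes <- numeric(length(sets))
  null_nes <- null_es
  for (s in seq_along(sets)) {
    nulls <- null_es[s, ]
    pos <- nulls[nulls >= 0]; neg <- nulls[nulls < 0]
    mean_pos <- if (length(pos)) mean(pos) else NA_real_
    mean_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    if (obs_es[s] >= 0) {
      p_nom[s] <- (sum(pos >= obs_es[s]) + 1) / (length(pos) + 1)
      nes[s] <- if (is.na(mean_pos) || mean_pos == 0) NA_real_
                else obs_es[s] / mean_pos
    } else {
      p_nom[s] <- (sum(neg <= obs_es[s]) + 1) / (length(neg) + 1)
      nes[s] <- if (is.na(mean_neg) || mean_neg == 0) NA_real_
                else obs_es[s] / mean_neg
    }
    null_nes[s, ] <- ifelse(nulls >= 0,
                            if (is.na(mean_pos)) NA_real_ else nulls / mean_pos,
                            if (is.na(mean_neg)) NA_real_ else nulls / mean_neg)
  }

  # Pooled-null FDR q per signed NES.
  pool <- null_nes[is.finite(null_nes)]
  fdr_q <- vapply(seq_along(sets), function(s) {
    v <- nes[s]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      null_tail <- if (any(pool >= 0)) mean(pool[pool >= 0] >= v) else 0
      obs_tail <- mean(nes[is.finite(nes) & nes >= 0] >= v)
    } else {
      null_tail <- if (any(pool < 0)) mean(pool[pool < 0] <= v) else 0
      obs_tail <- mean(nes[is.finite(nes) & nes < 0] <= v)
    }
    min(1, null_tail / max(obs_tail, .Machine$double.eps))
  }, 0)

  res <- data.frame(
    term_id = names(sets),
    size = vapply(set_member, sum, 1L),
    es = obs_es, nes = nes, p_nominal = p_nom, fdr_q = fdr_q,
    n_perm = n_used, seed = as.integer(seed), row.names = NULL)
  res <- res[order(-abs(res$nes), res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("gsea_result", "data.frame")
  attr(res, "exhaustive") <- exhaustive
  res
}
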