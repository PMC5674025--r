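#' Upper-tail hypergeometric probability of an annotation overlap
#'
#' Probability of observing at least \code{m} query genes inside an
#' annotation term when \code{n} query genes are drawn without replacement
#' from a background of \code{N} genes of which \code{M} carry the
#' annotation:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}
#'   {\binom{N}{n}}}
#' i.e. \eqn{P(X \ge m)} for \eqn{X \sim \mathrm{Hypergeometric}(N, M, n)}.
#' Evaluated through the hypergeometric survival function
#' (\code{stats::phyper}), which computes the same tail in a numerically
#' stable way; \code{m = 0} gives \eqn{P = 1} (empty sum).
#'
#' @param N background (universe) size.
#' @param n query size.
#' @param M annotated genes in the background.
#' @param m query genes carrying the annotation.
#' @return the tail probability, vectorized over its arguments.
#' @examples
#' hypergeom_upper_tail(20, 5, 4, 1)  # 1 - choose(16,5)/choose(20,5)
#' hypergeom_upper_tail(20, 5, 4, 0)  # empty sum: exactly 1
#' @export
hypergeom_upper_tail <- function(N, n, M, m) {
  k <- max(length(N), length(n), length(M), length(m))
  N <- rep_len(N, k); n <- rep_len(n, k)
  M <- rep_len(M, k); m <- rep_len(m, k)
  chk <- function(cond, msg) if (any(!cond)) stop("domain error: ", msg)
  chk(N >= 0 & M >= 0 & n >= 0 & m >= 0, "all arguments must be >= 0")
  chk(M <= N, "M <= N required")
  chk(n <= N, "n <= N required")
  chk(m <= pmin(n, M), "m <= min(n, M) required")
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term of a collection for over-representation of a query gene
#' list against a background, using \code{\link{hypergeom_upper_tail}} (the
#' probability of AT LEAST the observed overlap). The effective universe N
#' is the background restricted to annotated genes (genes carried by at
#' least one term of the collection); unannotated background genes cannot
#' contribute to any overlap and are excluded before N is computed. Query
#' genes outside the background are dropped with a message. Benjamini-
#' Hochberg FDR is applied across all tested terms of the run, and a term
#' is significant when \code{fdr <= fdr_threshold} (inclusive).
#'
#' Terms are tested only when they intersect the query (\code{m >= 1}) and
#' have at least \code{min_term_size} members inside the universe; smaller
#' terms are degenerate (their p-values are uninformative and only dilute
#' the FDR correction).
#'
#' @param query character vector of gene symbols.
#' @param collection a \code{\link{gene_set_collection}}.
#' @param background character vector: the gene universe the query was
#'   drawn from.
#' @param fdr_threshold significance cutoff on BH-adjusted p (default
#'   0.05, inclusive).
#' @param min_term_size minimum in-universe term size to test (default 3).
#' @param report_empty also report untested terms with \code{m = 0}
#'   (default \code{FALSE}).
#' @param background_mode label recorded in the result (\code{"all_genes"}
#'   or \code{"intersection_AB"}); purely descriptive.
#' @return data.frame of class \code{enrichment_result}, one row per tested
#'   term, sorted by p: columns \code{term_id}, \code{term_name}, \code{N},
#'   \code{n}, \code{M}, \code{m}, \code{p}, \code{fdr},
#'   \code{significant}, \code{background_mode}.
#' @examples
#' cc <- gene_set_collection(list(t1 = c("A", "B", "C"),
#'                                t2 = c("D", "E", "F")))
#' enrich(c("A", "B", "C"), cc, background = LETTERS[1:6])
#' @export
enrich <- function(query, collection, background, fdr_threshold = 0.05,
                   min_term_size = 3, report_empty = FALSE,
                   background_mode = "all_genes") {
  stopifnot(inherits(collection, "gene_set_collection"),
            length(collection) > 0)
  if (length(background) == 0L) stop("empty background")
  background <- unique(normalize_symbols(background))
  query <- unique(normalize_symbols(query))

  annotated <- unique(unlist(collection, use.names = FALSE))
  universe <- intersect(background, annotated)
  N <- length(universe)
  if (N == 0L) stop("no background gene is annotated in the collection")

  dropped <- setdiff(query, background)
  if (length(dropped))
    message(length(dropped),
            " query gene(s) outside the background were dropped")
  q <- intersect(query, universe)
  n <- length(q)
  if (n == 0L) {
    warning("empty query after background intersection")
    res <- data.frame(term_id = character(), term_name = character(),
                      N = integer(), n = integer(), M = integer(),
                      m = integer(), p = numeric(), fdr = numeric(),
                      significant = logical(),
                      background_mode = character())
    class(res) <- c("enrichment_result", "data.frame")
    return(res)
  }

  M <- vapply(collection, function(mem) length(intersect(mem, universe)), 1L)
  m <- vapply(collection, function(mem) length(intersect(mem, q)), 1L)
  testable <- M >= min_term_size & (m >= 1L | report_empty)
  ids <- names(collection)[testable]
  desc <- attr(collection, "description")
  p <- hypergeom_upper_tail(N, n, M[testable], m[testable])
  res <- data.frame(
    term_id = ids,
    term_name = unname(desc[ids] %||% ids),
    N = N, n = n, M = M[testable], m = m[testable],
    p = p, fdr = stats::p.adjust(p, method = "BH"),
    row.names = NULL)
  res$significant <- res$fdr <= fdr_threshold
  res$background_mode <- background_mode
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Over-representation under two backgrounds
#'
#' Runs \code{\link{enrich}} twice — once against the full gene universe
#' and once against a restricted background (canonically the intersection
#' of disease genes and differentially expressed genes) — and tabulates
#' per-term consistency. The restricted background asks whether a term's
#' enrichment is driven by the candidate genes themselves rather than by
#' the composition of the wider universe; no ordering between the two
#' p-values is implied or asserted.
#'
#' @param query character vector of gene symbols.
#' @param collection a \code{gene_set_collection}.
#' @param bg_all the full background.
#' @param bg_ab the restricted background; must be a subset of
#'   \code{bg_all}.
#' @param subsample_n optional integer: test against random background
#'   subsets of this size (drawn from each background, always retaining
#'   the query genes) instead of the full sets. The full-set comparison is
#'   the default; subsampling covers the reading of "random gene sets
#'   picked from the backgrounds" some protocols use.
#' @param subsample_seed seed for the background subsampling (required
#'   when \code{subsample_n} is given).
#' @param ... passed on to \code{\link{enrich}}.
#' @return list of class \code{dual_enrichment}: \code{all} and \code{ab}
#'   enrichment results plus \code{consistency}, a data.frame flagging each
#'   term as \code{both} / \code{all_only} / \code{ab_only} /
#'   \code{neither}.
#' @export
dual_background_enrich <- function(query, collection, bg_all, bg_ab,
                                   subsample_n = NULL,
                                   subsample_seed = NULL, ...) {
  bg_all <- unique(normalize_symbols(bg_all))
  bg_ab <- unique(normalize_symbols(bg_ab))
  if (!all(bg_ab %in% bg_all))
    stop("bg_ab must be a subset of bg_all")
  if (!is.null(subsample_n)) {
    if (is.null(subsample_seed))
      stop("subsample_seed is required with subsample_n")
    q <- unique(normalize_symbols(query))
    sub_bg <- function(bg, k) {
      keep <- intersect(q, bg)
      rest <- setdiff(bg, keep)
      if (k < length(keep) || k > length(bg))
        stop("subsample_n must lie in [|query in background|, |background|]")
      sort(c(keep, sample(rest, k - length(keep))))
    }
    with_seed(subsample_seed, {
      bg_all <- sub_bg(bg_all, subsample_n)
      bg_ab <- intersect(sub_bg(bg_ab, min(subsample_n, length(bg_ab))),
                         bg_all)
      bg_ab <- sort(unique(c(bg_ab, intersect(q, bg_ab))))
    })
    bg_all <- sort(unique(c(bg_all, bg_ab)))
  }
  res_all <- enrich(query, collection, bg_all,
                    background_mode = "all_genes", ...)
  res_ab <- enrich(query, collection, bg_ab,
                   background_mode = "intersection_AB", ...)
  ids <- sort(union(res_all$term_id, res_ab$term_id))
  sig_all <- ids %in% res_all$term_id[res_all$significant]
  sig_ab <- ids %in% res_ab$term_id[res_ab$significant]
  consistency <- data.frame(
    term_id = ids,
    status = ifelse(sig_all & sig_ab, "both",
             ifelse(sig_all, "all_only",
             ifelse(sig_ab, "ab_only", "neither"))))
  structure(list(all = res_all, ab = res_ab, consistency = consistency),
            class = "dual_enrichment")
}

#' @export
print.dual_enrichment <- function(x, ...) {
  cat("Dual-background over-representation:\n")
  print(table(x$consistency$status))
  invisible(x)
}

#' Write enrichment results as TSV
#'
#' @param res an \code{enrichment_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
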