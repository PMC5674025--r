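#' Read a disease-gene relevance table
#'
#' Two-column TSV (gene, score), GeneCards-style. Duplicate genes keep the
#' maximum relevance score; the number of collapsed duplicates is recorded
#' in attribute \code{"n_collapsed"} and reported with a message.
#'
#' @param path TSV file path with header columns \code{gene}, \code{score}
#'   (case-insensitive; \code{relevance_score} accepted).
#' @return data.frame with columns \code{gene} (normalized symbols) and
#'   \code{score}.
#' @export
read_disease_genes <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  nm <- tolower(names(raw))
  i_gene <- match("gene", nm)
  i_score <- match("score", nm)
  if (is.na(i_score)) i_score <- match("relevance_score", nm)
  if (is.na(i_gene) || is.na(i_score))
    stop("format error: need columns gene and score")
  gene <- normalize_symbols(raw[[i_gene]])
  score <- suppressWarnings(as.numeric(raw[[i_score]]))
  if (any(is.na(score) | score < 0))
    stop("validation error: scores must be non-negative numbers (row(s) ",
         paste(which(is.na(score) | score < 0), collapse = ", "), ")")
  n_dup <- sum(duplicated(gene))
  if (n_dup > 0L) {
    message(n_dup, " duplicate gene record(s) collapsed to the maximum score")
    score <- tapply(score, gene, max)
    gene <- names(score)
    score <- unname(score)
  }
  out <- data.frame(gene = gene, score = score)
  attr(out, "n_collapsed") <- n_dup
  out
}

#' Filter disease genes by relevance score
#'
#' Retains genes whose database relevance score exceeds \code{score_min}.
#' The comparison is strict by default (score must be > the threshold, so a
#' score of exactly 5 is excluded at the default cutoff); set
#' \code{strict = FALSE} for an inclusive >= rule.
#'
#' @param records data.frame with columns \code{gene},
#'   \code{score}/\code{relevance_score} (see
#'   \code{\link{read_disease_genes}}).
#' @param score_min relevance cutoff (default 5).
#' @param strict logical; strict inequality (default \code{TRUE}).
#' @return character vector of retained gene symbols (sorted, unique).
#' @examples
#' rec <- data.frame(gene = c("TP53", "BRCA1", "ACTB"),
#'                   score = c(12, 5, 0.4))
#' filter_disease_genes(rec)                 # score 5 excluded
#' filter_disease_genes(rec, strict = FALSE) # score 5 included
#' @export
filter_disease_genes <- function(records, score_min = 5, strict = TRUE) {
  score <- records$score %||% records$relevance_score
  if (is.null(score)) stop("records must have a score column")
  stopifnot(is.numeric(score), all(score >= 0))
  gene <- normalize_symbols(records$gene)
  keep <- if (strict) score > score_min else score >= score_min
  sort(unique(gene[keep]))
}

#' Two-group expression matrix
#'
#' Bundles a genes x samples matrix of finite log2 expression values with a
#' two-level group factor (each group needs at least 2 samples for
#' variance-based statistics).
#'
#' @param values numeric matrix, rownames = gene/probe identifiers.
#' @param groups character/factor of length \code{ncol(values)} with
#'   exactly two levels.
#' @return object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || anyNA(rownames(values)) ||
      any(!nzchar(rownames(values))))
    stop("values must have complete gene identifiers as rownames")
  if (any(!is.finite(values))) stop("expression values must be finite")
  groups <- as.factor(groups)
  if (length(groups) != ncol(values))
    stop("groups must have one label per sample column")
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Call differentially expressed genes between two groups
#'
#' Per-gene two-sided test of mean difference on log2 expression. The
#' default is Welch's t test with the significant set defined by raw
#' \code{P < alpha}, the convention of GEO2R-style quick DEG calls at
#' P < 0.05; \code{method = "moderated_t"} instead uses limma's moderated t
#' (empirical-Bayes pooled variance shrinkage), which is what GEO2R runs
#' under the hood — the two are exposed as a flag because they can disagree
#' at small sample sizes. Log fold change is mean(group 2) - mean(group 1),
#' groups taken in factor-level order.
#'
#' Genes with zero variance in both groups cannot be tested: they are
#' flagged \code{degenerate} and assigned \code{p = 1} rather than raising
#' an error.
#'
#' When \code{probe_map} is supplied (probe -> gene), probe-level rows are
#' collapsed to genes by keeping the smallest-p probe per gene (count of
#' collapsed rows in attribute \code{"n_collapsed"}).
#'
#' @param mat an \code{\link{expression_matrix}}.
#' @param alpha significance level on the p-value (default 0.05).
#' @param method \code{"welch_t"} (default) or \code{"moderated_t"}.
#' @param use_adjusted use BH-adjusted p for the significant set instead of
#'   raw p (default \code{FALSE}).
#' @param probe_map optional named character vector probe -> gene symbol.
#' @return object of class \code{deg_result}: list with \code{table} (one
#'   row per gene: \code{gene}, \code{log_fc}, \code{t}, \code{p},
#'   \code{p_adj}, \code{degenerate}; sorted by p ascending, ties broken by
#'   |log_fc| descending then symbol) and \code{significant} (character
#'   vector).
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200, 8), 20, 10,
#'             dimnames = list(paste0("G", 1:20), NULL))
#' m[1, 6:10] <- m[1, 6:10] + 5
#' res <- call_degs(expression_matrix(m, rep(c("a", "b"), each = 5)))
#' head(res$table)
#' @export
call_degs <- function(mat, alpha = 0.05,
                      method = c("welch_t", "moderated_t"),
                      use_adjusted = FALSE, probe_map = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(mat, "expression_matrix"),
            is.numeric(alpha), alpha > 0, alpha <= 1)
  x <- mat$values
  g <- mat$groups
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1, stats::var)
  log_fc <- m2 - m1
  degenerate <- (v1 == 0 & v2 == 0)

  if (method == "welch_t") {
    n1 <- length(i1); n2 <- length(i2)
    se2 <- v1 / n1 + v2 / n2
    tstat <- ifelse(se2 > 0, log_fc / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 1)
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    design <- stats::model.matrix(~g)
    fit <- limma::eBayes(limma::lmFit(x, design))
    tstat <- fit$t[, 2]
    p <- fit$p.value[, 2]
  }
  p[degenerate] <- 1
  tstat[degenerate] <- 0

  tab <- data.frame(gene = rownames(x), log_fc = log_fc, t = tstat, p = p,
                    degenerate = degenerate, row.names = NULL)
  n_collapsed <- 0L
  if (!is.null(probe_map)) {
    gene <- normalize_symbols(unname(probe_map[tab$gene]))
    if (anyNA(gene)) stop("probe_map is missing entries for some rows")
    tab$gene <- gene
    ord <- order(tab$p, -abs(tab$log_fc), tab$gene)
    tab <- tab[ord, , drop = FALSE]
    n_collapsed <- sum(duplicated(tab$gene))
    tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  }
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab <- tab[order(tab$p, -abs(tab$log_fc), tab$gene),
             c("gene", "log_fc", "t", "p", "p_adj", "degenerate")]
  rownames(tab) <- NULL
  crit <- if (use_adjusted) tab$p_adj else tab$p
  out <- structure(list(table = tab,
                        significant = tab$gene[crit < alpha],
                        alpha = alpha, method = method,
                        use_adjusted = use_adjusted),
                   class = "deg_result")
  attr(out, "n_collapsed") <- n_collapsed
  out
}

#' @export
print.deg_result <- function(x, ...) {
  cat("DEG call (", x$method, "): ", length(x$significant), " of ",
      nrow(x$table), " genes with ",
      if (x$use_adjusted) "adjusted " else "", "P < ", x$alpha, "\n",
      sep = "")
  invisible(x)
}

#' Three-set Venn intersection of gene lists
#'
#' Computes all seven disjoint regions of the 3-set Venn diagram over
#' disease genes (A), differentially expressed genes (B) and network
#' targets (C). Symbols are normalized before intersection so the three
#' sources agree. The triple intersection \code{abc} is the
#' candidate-target list.
#'
#' @param A,B,C character vectors of gene symbols.
#' @return object of class \code{venn3}: list with the input sizes, the
#'   seven region sets (\code{a_only}, \code{b_only}, \code{c_only},
#'   \code{ab_only}, \code{ac_only}, \code{bc_only}, \code{abc}) and a
#'   \code{region_sizes} integer vector.
#' @examples
#' v <- intersect_three(c("X", "Y"), c("Y", "Z"), "Y")
#' v$abc
#' @export
intersect_three <- function(A, B, C) {
  A <- unique(normalize_symbols(A))
  B <- unique(normalize_symbols(B))
  C <- unique(normalize_symbols(C))
  u <- sort(unique(c(A, B, C)))
  ina <- u %in% A; inb <- u %in% B; inc_ <- u %in% C
  regions <- list(
    a_only  = u[ina & !inb & !inc_],
    b_only  = u[!ina & inb & !inc_],
    c_only  = u[!ina & !inb & inc_],
    ab_only = u[ina & inb & !inc_],
    ac_only = u[ina & !inb & inc_],
    bc_only = u[!ina & inb & inc_],
    abc     = u[ina & inb & inc_])
  structure(c(list(n_A = length(A), n_B = length(B), n_C = length(C)),
              regions,
              list(region_sizes = vapply(regions, length, 1L))),
            class = "venn3")
}

#' @export
print.venn3 <- function(x, ...) {
  cat("3-set intersection: |A| =", x$n_A, " |B| =", x$n_B,
      " |C| =", x$n_C, "\n")
  print(x$region_sizes)
  cat("Triple intersection:", length(x$abc), "genes\n")
  invisible(x)
}

#' Write Venn regions to disk
#'
#' Region sizes as JSON-like TSV plus one single-column TSV of members per
#' region.
#'
#' @param venn a \code{\link{intersect_three}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_venn <- function(venn, dir) {
  stopifnot(inherits(venn, "venn3"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(region = names(venn$region_sizes),
               size = unname(venn$region_sizes)),
    file.path(dir, "region_sizes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (r in names(venn$region_sizes))
    writeLines(venn[[r]], file.path(dir, paste0(r, ".tsv")))
  invisible(dir)
}
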