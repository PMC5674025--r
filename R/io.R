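# Readers/writers for the standard interchange formats the pipeline
# consumes: GMT gene-set collections, CLS phenotype labels, and TSV
# expression matrices.

#' Read a GMT gene-set collection
#'
#' Standard tab-separated format: term id, description, then member genes.
#' Member symbols are normalized and de-duplicated; empty terms and
#' duplicate term ids are rejected.
#'
#' @param path GMT file path.
#' @return object of class \code{gene_set_collection}: named list of
#'   character vectors with a \code{"description"} attribute (named
#'   character vector) and optional \code{"category"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("format error: GMT line(s) with < 3 fields: ",
         paste(bad, collapse = ", "))
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(f) unique(normalize_symbols(f[-(1:2)])))
  gene_set_collection(stats::setNames(sets, ids),
                      description = stats::setNames(desc, ids))
}

#' Construct a gene-set collection
#'
#' @param sets named list: term id -> character vector of member symbols
#'   (unique, at least one per term).
#' @param description optional named character vector of term descriptions.
#' @param category optional named character vector (e.g. BP/CC/MF/pathway).
#' @return object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, description = NULL, category = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets))) stop("duplicate term ids")
  sets <- lapply(sets, function(m) unique(normalize_symbols(m)))
  if (any(lengths(sets) == 0L)) stop("every term needs >= 1 member gene")
  if (is.null(description))
    description <- stats::setNames(names(sets), names(sets))
  structure(sets, description = description, category = category,
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection:", length(x), "terms; sizes",
      min(lengths(x)), "-", max(lengths(x)), "\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection a \code{gene_set_collection}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "description")
  lines <- vapply(names(collection), function(id)
    paste(c(id, desc[[id]] %||% id, collection[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read/write CLS phenotype label files
#'
#' The three-line categorical CLS format: counts header, class names, and
#' one label index or name per sample.
#'
#' @param path CLS file path.
#' @return factor of group labels, one per sample.
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("format error: CLS needs 3 lines")
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  classes <- strsplit(trimws(lines[2]), "[[:space:]]+")[[1]]
  if (classes[1] != "#") stop("format error: CLS line 2 must start with #")
  classes <- classes[-1]
  labels <- strsplit(trimws(lines[3]), "[[:space:]]+")[[1]]
  if (length(labels) != hdr[1])
    stop("format error: CLS sample count mismatch")
  if (all(grepl("^[0-9]+$", labels)))
    labels <- classes[as.integer(labels) + 1L]
  factor(labels, levels = classes)
}

#' @rdname read_cls
#' @param groups factor/character of sample group labels.
#' @export
write_cls <- function(groups, path) {
  groups <- as.factor(groups)
  writeLines(c(
    paste(length(groups), nlevels(groups), 1),
    paste("#", paste(levels(groups), collapse = " ")),
    paste(as.integer(groups) - 1L, collapse = " ")), path)
  invisible(path)
}

#' Read an expression matrix from TSV (+ CLS labels)
#'
#' @param path TSV with gene identifiers in the first column and one column
#'   per sample.
#' @param cls_path path to the matching CLS label file.
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, cls_path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  expression_matrix(values, read_cls(cls_path))
}

#' @rdname read_expression
#' @param mat an \code{expression_matrix} to write.
#' @export
write_expression <- function(mat, path, cls_path) {
  stopifnot(inherits(mat, "expression_matrix"))
  tab <- data.frame(gene = rownames(mat$values), mat$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_cls(mat$groups, cls_path)
  invisible(path)
}
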