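#' Build a herb-ingredient-target tripartite network
#'
#' Assembles the typed three-layer graph: herb nodes connect to their
#' retained ingredients ("contains" edges) and ingredients connect to their
#' predicted gene targets ("targets" edges). Edges only ever join adjacent
#' layers. Retained ingredients with no entry in the target map are dropped
#' with a warning (their count is recorded in attribute
#' \code{"n_unmapped"}), so the network never contains isolated ingredient
#' nodes. Gene symbols are normalized (uppercase, whitespace-stripped) at
#' ingestion.
#'
#' The graph is stored as plain adjacency lists — no graph library is
#' required by any downstream operation.
#'
#' @param retained an \code{ingredient_table} of retained rows (see
#'   \code{\link{screen_ingredients}}).
#' @param tmap a named list: ingredient_id -> character vector of target
#'   gene symbols (each mapped ingredient must have at least one target).
#' @return an object of class \code{tripartite_network} with elements
#'   \code{herbs} (herb -> ingredient ids), \code{ingredients}
#'   (ingredient -> target symbols), \code{targets} (sorted target
#'   universe).
#' @examples
#' tab <- data.frame(herb_id = "H1", ingredient_id = c("i1", "i2"),
#'                   ob = c(40, 50), dl = c(0.3, 0.4))
#' net <- build_network(tab, list(i1 = c("A", "B"), i2 = c("B", "C")))
#' summary(net)
#' @export
build_network <- function(retained, tmap) {
  if (is.null(retained) || nrow(retained) == 0L)
    stop("nothing to build: empty retained ingredient list")
  stopifnot(is.list(tmap))
  if (length(tmap) && is.null(names(tmap)))
    stop("tmap must be a named list (ingredient_id -> targets)")

  mapped <- retained$ingredient_id %in% names(tmap)
  n_unmapped <- sum(!mapped)
  if (n_unmapped > 0L)
    warning(n_unmapped, " retained ingredient(s) without a target map entry ",
            "were excluded from the network")
  kept <- retained[mapped, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("nothing to build: no retained ingredient has a target map entry")

  ing_ids <- unique(kept$ingredient_id)
  ingredients <- lapply(tmap[ing_ids], function(tg) {
    tg <- sort(unique(normalize_symbols(tg)))
    if (length(tg) == 0L) stop("a mapped ingredient has an empty target set")
    tg
  })
  herbs <- lapply(split(kept$ingredient_id, kept$herb_id),
                  function(v) sort(unique(v)))
  net <- structure(
    list(herbs = herbs, ingredients = ingredients,
         targets = sort(unique(unlist(ingredients, use.names = FALSE)))),
    class = "tripartite_network")
  attr(net, "n_unmapped") <- n_unmapped
  net
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat("Herb-ingredient-target network:",
      length(x$herbs), "herbs,",
      length(x$ingredients), "ingredients,",
      length(x$targets), "targets\n")
  invisible(x)
}

#' Node and edge counts of the network
#'
#' Totals count distinct entities network-wide (an ingredient or target
#' shared by several herbs is counted once); per-herb rows count the
#' distinct ingredients and targets reachable from that herb.
#'
#' @param net a \code{tripartite_network}.
#' @return an object of class \code{network_summary}: a list with
#'   \code{n_ingredients}, \code{n_targets}, and a per-herb data.frame
#'   \code{per_herb} (columns \code{herb_id}, \code{n_ingredients},
#'   \code{n_targets}).
#' @export
count_summary <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  per_herb <- data.frame(
    herb_id = names(net$herbs),
    n_ingredients = vapply(net$herbs, length, 1L),
    n_targets = vapply(net$herbs, function(ings)
      length(unique(unlist(net$ingredients[ings], use.names = FALSE))), 1L),
    row.names = NULL
  )
  structure(list(n_ingredients = length(net$ingredients),
                 n_targets = length(net$targets),
                 per_herb = per_herb),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Totals:", x$n_ingredients, "ingredients,", x$n_targets, "targets\n")
  print(x$per_herb, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tripartite_network <- function(object, ...) count_summary(object)

#' Project herb-target relations
#'
#' A target belongs to a herb iff some ingredient of that herb maps to it.
#' The projection also carries each target's herb-degree: the number of
#' distinct herbs reaching it, the quantity binned by
#' \code{\link{common_target_histogram}}.
#'
#' @param net a \code{tripartite_network}.
#' @return an object of class \code{herb_target_projection}: list with
#'   \code{herb_targets} (herb -> sorted target vector) and
#'   \code{herb_degree} (named integer vector over the target universe).
#' @export
project_herb_targets <- function(net) {
  stopifnot(inherits(net, "tripartite_network"))
  herb_targets <- lapply(net$herbs, function(ings)
    sort(unique(unlist(net$ingredients[ings], use.names = FALSE))))
  degree <- table(unlist(herb_targets, use.names = FALSE))
  herb_degree <- stats::setNames(as.integer(degree), names(degree))
  herb_degree <- herb_degree[sort(names(herb_degree))]
  structure(list(herb_targets = herb_targets, herb_degree = herb_degree),
            class = "herb_target_projection")
}

#' @export
print.herb_target_projection <- function(x, ...) {
  cat("Herb-target projection:", length(x$herb_targets), "herbs,",
      length(x$herb_degree), "targets; herb-degree range",
      min(x$herb_degree), "-", max(x$herb_degree), "\n")
  invisible(x)
}

#' Shared-target histogram
#'
#' In \code{exact} mode, bin \code{k} counts the targets hit by exactly
#' \code{k} distinct herbs, so the bins partition the target universe and
#' sum to its size. In \code{at_least} mode bin \code{k} gives the
#' cumulative tail (targets hit by \code{k} or more herbs). The default is
#' \code{exact}, matching the usual "targets shared by the same number of
#' herbs" presentation.
#'
#' @param proj a \code{herb_target_projection}.
#' @param mode \code{"exact"} (default) or \code{"at_least"}.
#' @return named integer vector, names = herb counts 1..max degree.
#' @examples
#' tab <- data.frame(herb_id = c("H1", "H2"), ingredient_id = c("i1", "i2"),
#'                   ob = 40, dl = 0.3)
#' proj <- project_herb_targets(build_network(tab,
#'   list(i1 = c("A", "B"), i2 = "B")))
#' common_target_histogram(proj)            # A:1 herb, B:2 herbs
#' common_target_histogram(proj, "at_least")
#' @export
common_target_histogram <- function(proj, mode = c("exact", "at_least")) {
  mode <- match.arg(mode)
  stopifnot(inherits(proj, "herb_target_projection"))
  kmax <- max(proj$herb_degree)
  exact <- vapply(seq_len(kmax),
                  function(k) sum(proj$herb_degree == k), 1L)
  names(exact) <- as.character(seq_len(kmax))
  if (mode == "exact") exact else rev(cumsum(rev(exact)))
}

#' Export a tripartite network
#'
#' Writes Cytoscape-compatible interchange files. SIF uses relation labels
#' \code{contains} (herb -> ingredient) and \code{targets}
#' (ingredient -> target); GraphML carries a \code{type} node attribute
#' (herb/ingredient/target); TSV is a three-column edge list
#' (\code{source}, \code{relation}, \code{target}) that round-trips exactly
#' through \code{\link{read_network_tsv}}. All outputs are sorted
#' lexicographically so files diff cleanly between runs.
#'
#' @param net a \code{tripartite_network}.
#' @param format \code{"sif"}, \code{"graphml"} or \code{"tsv"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, format = c("sif", "graphml", "tsv"), path) {
  format <- match.arg(format)
  stopifnot(inherits(net, "tripartite_network"))
  edges <- network_edges(net)
  if (format == "sif") {
    lines <- paste(edges$source, edges$relation, edges$target)
    tryCatch(writeLines(lines, path),
             error = function(e) stop("I/O error writing ", path, ": ",
                                      conditionMessage(e)))
  } else if (format == "tsv") {
    tryCatch(utils::write.table(edges, path, sep = "\t", quote = FALSE,
                                row.names = FALSE),
             error = function(e) stop("I/O error writing ", path, ": ",
                                      conditionMessage(e)))
  } else {
    write_graphml(net, edges, path)
  }
  invisible(path)
}

# Edge list in deterministic lexicographic order (contains before targets).
network_edges <- function(net) {
  he <- data.frame(
    source = rep(names(net$herbs), lengths(net$herbs)),
    relation = "contains",
    target = unlist(net$herbs, use.names = FALSE))
  it <- data.frame(
    source = rep(names(net$ingredients), lengths(net$ingredients)),
    relation = "targets",
    target = unlist(net$ingredients, use.names = FALSE))
  edges <- rbind(he, it)
  edges <- edges[order(edges$relation, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  edges
}

write_graphml <- function(net, edges, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "type", `for` = "node",
                      attr.name = "type", attr.type = "string")
  g <- xml2::xml_add_child(doc, "graph", id = "net", edgedefault = "directed")
  node_type <- c(
    stats::setNames(rep("herb", length(net$herbs)), names(net$herbs)),
    stats::setNames(rep("ingredient", length(net$ingredients)),
                    names(net$ingredients)),
    stats::setNames(rep("target", length(net$targets)), net$targets))
  node_type <- node_type[order(names(node_type))]
  for (i in seq_along(node_type)) {
    nd <- xml2::xml_add_child(g, "node", id = names(node_type)[i])
    d <- xml2::xml_add_child(nd, "data", key = "type")
    xml2::xml_set_text(d, unname(node_type[i]))
  }
  for (i in seq_len(nrow(edges)))
    xml2::xml_add_child(g, "edge", source = edges$source[i],
                        target = edges$target[i], label = edges$relation[i])
  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop("I/O error writing ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a network edge-list TSV
#'
#' Inverse of \code{export_network(..., format = "tsv")}.
#'
#' @param path TSV with columns \code{source}, \code{relation},
#'   \code{target}.
#' @return data.frame edge list in the export's canonical order.
#' @export
read_network_tsv <- function(path) {
  ed <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  stopifnot(all(c("source", "relation", "target") %in% names(ed)))
  ed <- ed[order(ed$relation, ed$source, ed$target), , drop = FALSE]
  rownames(ed) <- NULL
  ed
}
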