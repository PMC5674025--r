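#' Screening configuration for ingredient retention
#'
#' ADME screening keeps a chemical ingredient when both its oral
#' bioavailability (OB, percent scale: 30 means 30\%) and drug-likeness
#' (DL, unitless in \[0, 1\]) reach their thresholds. Herbs on the
#' exemption list bypass both criteria entirely; the canonical case is a
#' mineral/animal-derived herb whose constituents are inorganic compounds
#' with intrinsically low DL, which the TCMSP-style rule would discard
#' wholesale. Thresholds are inclusive.
#'
#' @param ob_min minimum oral bioavailability, percent (default 30).
#' @param dl_min minimum drug-likeness, unitless (default 0.18).
#' @param exempt_herbs character vector of herb codes whose ingredients are
#'   retained regardless of OB/DL (default \code{"ML"}).
#' @return an object of class \code{screen_config}.
#' @examples
#' screen_config()
#' screen_config(ob_min = 40, exempt_herbs = character())
#' @export
screen_config <- function(ob_min = 30, dl_min = 0.18, exempt_herbs = "ML") {
  stopifnot(is.numeric(ob_min), length(ob_min) == 1L, ob_min >= 0,
            is.numeric(dl_min), length(dl_min) == 1L, dl_min >= 0,
            is.character(exempt_herbs))
  structure(list(ob_min = ob_min, dl_min = dl_min,
                 exempt_herbs = unique(exempt_herbs)),
            class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("Ingredient screen: OB >=", x$ob_min, "%  and  DL >=", x$dl_min, "\n")
  cat("Exempt herbs:",
      if (length(x$exempt_herbs)) paste(x$exempt_herbs, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Read a herb-ingredient property table
#'
#' Reads a TSV/CSV table with one row per (herb, ingredient) pair and the
#' screening properties OB (percent) and DL (unitless). Column matching is
#' case-insensitive on the names \code{herb_id}, \code{ingredient_id},
#' \code{ingredient_name} (optional), \code{ob}, \code{dl}; \code{herb} and
#' \code{ingredient} are accepted as synonyms. Malformed numeric cells and
#' out-of-range values are reported with their row numbers. Duplicate
#' (herb, ingredient) pairs are rejected: provenance tables should be clean,
#' and silent deduplication would hide upstream merge errors.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param cfg a \code{\link{screen_config}} used to set the per-row
#'   exemption flag at load time.
#' @return a data.frame of class \code{ingredient_table} with columns
#'   \code{herb_id}, \code{ingredient_id}, \code{ingredient_name},
#'   \code{ob}, \code{dl}, \code{exempt}.
#' @seealso \code{\link{screen_ingredients}}
#' @export
read_ingredient_table <- function(path, dialect = c("tsv", "csv"),
                                  cfg = screen_config()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = TRUE,
                           quote = "\"", comment.char = "")
  nm <- tolower(names(raw))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- match(cand, nm)
      if (!is.na(i)) return(i)
    }
    NA_integer_
  }
  i_herb <- pick("herb_id", "herb")
  i_ing  <- pick("ingredient_id", "ingredient")
  i_name <- pick("ingredient_name", "name")
  i_ob   <- pick("ob")
  i_dl   <- pick("dl")
  missing <- c(herb = is.na(i_herb), ingredient = is.na(i_ing),
               ob = is.na(i_ob), dl = is.na(i_dl))
  if (any(missing))
    stop("format error: missing required column(s): ",
         paste(names(missing)[missing], collapse = ", "))

  parse_num <- function(txt, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("validation error: malformed ", what, " value(s) in row(s) ",
           paste(bad, collapse = ", "), " (e.g. \"", txt[bad[1]], "\")")
    v
  }
  ob <- parse_num(raw[[i_ob]], "ob")
  dl <- parse_num(raw[[i_dl]], "dl")
  if (any(ob < 0))
    stop("validation error: negative OB in row(s) ",
         paste(which(ob < 0), collapse = ", "))
  if (any(dl < 0 | dl > 1))
    stop("validation error: DL outside [0, 1] in row(s) ",
         paste(which(dl < 0 | dl > 1), collapse = ", "))

  tab <- data.frame(
    herb_id = trimws(raw[[i_herb]]),
    ingredient_id = trimws(raw[[i_ing]]),
    ingredient_name = if (!is.na(i_name)) trimws(raw[[i_name]])
                      else trimws(raw[[i_ing]]),
    ob = ob, dl = dl,
    stringsAsFactors = FALSE
  )
  key <- paste(tab$herb_id, tab$ingredient_id, sep = "\r")
  if (anyDuplicated(key))
    stop("validation error: duplicate (herb, ingredient) pair(s) in row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  tab$exempt <- tab$herb_id %in% cfg$exempt_herbs
  class(tab) <- c("ingredient_table", "data.frame")
  tab
}

#' Apply the OB/DL retention rule
#'
#' A record is retained iff (\code{ob >= ob_min} and \code{dl >= dl_min})
#' or its herb is exempt. Input order is preserved. The returned table
#' carries a per-herb screening report in attribute \code{"report"}
#' (retained/dropped counts), also available via
#' \code{\link{screening_report}}.
#'
#' @param records an \code{ingredient_table} (or data.frame with columns
#'   \code{herb_id}, \code{ingredient_id}, \code{ob}, \code{dl}, and
#'   optionally \code{exempt}).
#' @param cfg a \code{\link{screen_config}}.
#' @return the retained rows, same class, with a \code{"report"} attribute.
#' @examples
#' tab <- data.frame(herb_id = c("A", "A", "ML"),
#'                   ingredient_id = c("i1", "i2", "i3"),
#'                   ob = c(35, 10, 80), dl = c(0.2, 0.5, 0.05))
#' screen_ingredients(tab, screen_config())
#' @export
screen_ingredients <- function(records, cfg = screen_config()) {
  req <- c("herb_id", "ingredient_id", "ob", "dl")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  if (nrow(records) == 0L) {
    warning("empty ingredient table: nothing to screen")
    out <- records
    attr(out, "report") <- data.frame(herb_id = character(),
                                      retained = integer(),
                                      dropped = integer())
    return(out)
  }
  exempt <- if ("exempt" %in% names(records)) as.logical(records$exempt)
            else records$herb_id %in% cfg$exempt_herbs
  exempt <- exempt | records$herb_id %in% cfg$exempt_herbs
  keep <- (records$ob >= cfg$ob_min & records$dl >= cfg$dl_min) | exempt
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out$exempt <- exempt[keep]

  herbs <- unique(records$herb_id)
  report <- data.frame(
    herb_id = herbs,
    retained = vapply(herbs, function(h) sum(keep & records$herb_id == h), 1L),
    dropped = vapply(herbs, function(h) sum(!keep & records$herb_id == h), 1L),
    row.names = NULL
  )
  attr(out, "report") <- report
  out
}

#' Per-herb screening report
#'
#' @param screened output of \code{\link{screen_ingredients}}.
#' @return data.frame with columns \code{herb_id}, \code{retained},
#'   \code{dropped}.
#' @export
screening_report <- function(screened) {
  rep <- attr(screened, "report")
  if (is.null(rep)) stop("no screening report attached; run screen_ingredients()")
  rep
}

#' Write a screening report as TSV
#'
#' @param screened output of \code{\link{screen_ingredients}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_screening_report <- function(screened, path) {
  utils::write.table(screening_report(screened), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
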