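#' Read and write plain edge lists
#'
#' The primary on-disk format: one edge per line as two node labels
#' separated by a tab, comma, or any run of whitespace (auto-detected per
#' line), with `#` starting a comment.  Labels are kept verbatim; duplicate
#' lines merge into one edge with a warning; columns beyond the second are
#' ignored with a warning.
#'
#' @param path file path.
#' @return `read_edgelist()`: a directed graph.  `write_edgelist()`: the
#'   path, invisibly.
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "a\tb", "b\tc"), f)
#' read_edgelist(f)
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(make_digraph(character(0), character(0)))
  }
  parts <- lapply(lines, function(l) {
    if (grepl(",", l, fixed = TRUE)) {
      trimws(strsplit(l, ",", fixed = TRUE)[[1]])
    } else {
      strsplit(trimws(l), "\\s+")[[1]]
    }
  })
  nfield <- lengths(parts)
  if (any(nfield < 2L)) {
    stop("malformed edge line ", lineno[which(nfield < 2L)[1]],
         " in '", path, "': need two node labels")
  }
  if (any(nfield > 2L)) {
    warning("ignoring extra columns on ", sum(nfield > 2L), " line(s)")
  }
  make_digraph(vapply(parts, `[`, character(1), 1L),
               vapply(parts, `[`, character(1), 2L))
}

#' @rdname read_edgelist
#' @param g a directed graph.
#' @param sep delimiter, tab by default.
#' @export
write_edgelist <- function(g, path, sep = "\t") {
  g <- as_digraph(g)
  el <- edge_pairs(g)
  writeLines(paste(el[, 1L], el[, 2L], sep = sep), path)
  invisible(path)
}

#' Read a node ranking
#'
#' Two tab- or whitespace-separated columns: node label and integer rank
#' (0 = top of the hierarchy).  Used to score agony on cyclic graphs.
#'
#' @param path file path.
#' @return a named integer vector.
#' @export
read_ranking <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(parts) < 2L)) stop("ranking lines need 'node rank'")
  rk <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(rk)) stop("non-integer rank in '", path, "'")
  stats::setNames(rk, vapply(parts, `[`, character(1), 1L))
}

newick_quote <- function(x) {
  needs <- grepl("[][(),:;'\" \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Export an arborescence forest
#'
#' Serializes the forest of an [arborescence_score()] result:
#'
#' * `"edgelist"`: the surviving forest edges, one per line.
#' * `"newick"`: one rooted tree string per arborescence (one per line,
#'   `;`-terminated); labels containing Newick-reserved characters are
#'   single-quoted.
#' * `"dot"`: a Graphviz digraph; condensed super-nodes are labelled with
#'   their member lists, and with `include_removed = TRUE` the edges deleted
#'   during rooting appear dashed.
#'
#' @param result an `arborescence_result`.
#' @param format one of `"edgelist"`, `"newick"`, `"dot"`.
#' @param include_removed also draw rooting-phase deletions (DOT only).
#' @return a character vector of output lines.
#' @examples
#' res <- arborescence_score(toy_tree())
#' export_forest(res, "newick")
#' @export
export_forest <- function(result, format = c("edgelist", "newick", "dot"),
                          include_removed = FALSE) {
  stopifnot(inherits(result, "arborescence_result"))
  format <- match.arg(format)
  forest <- result$forest
  el <- edge_pairs(forest)
  switch(format,
    edgelist = if (nrow(el)) paste(el[, 1L], el[, 2L], sep = "\t")
               else character(0),
    newick = {
      children <- split(el[, 2L], factor(el[, 1L], levels = igraph::V(forest)$name))
      subtree <- function(v) {
        kids <- children[[v]]
        lab <- newick_quote(v)
        if (is.null(kids) || !length(kids)) return(lab)
        paste0("(", paste(vapply(sort(kids), subtree, character(1)),
                          collapse = ","), ")", lab)
      }
      vapply(sort(result$roots), function(r) paste0(subtree(r), ";"),
             character(1))
    },
    dot = {
      q <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
      node_lines <- vapply(igraph::V(forest)$name, function(v) {
        members <- result$members[[v]]
        lab <- if (length(members) > 1L) {
          paste0(v, "\\n{", paste(sort(members), collapse = ","), "}")
        } else v
        paste0("  ", q(v), " [label=", q(lab), "];")
      }, character(1))
      edge_lines <- if (nrow(el)) {
        paste0("  ", q(el[, 1L]), " -> ", q(el[, 2L]), ";")
      } else character(0)
      removed_lines <- if (include_removed && nrow(result$removed_in_rooting)) {
        rm_el <- result$removed_in_rooting
        paste0("  ", q(rm_el[, 1L]), " -> ", q(rm_el[, 2L]),
               " [style=dashed];")
      } else character(0)
      unname(c("digraph arborescence_forest {", node_lines, edge_lines,
               removed_lines, "}"))
    })
}
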