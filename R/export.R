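#' Export a network for interchange with graph viewers
#'
#' `"graphml"` writes a single GraphML document carrying all node and edge
#' attributes. `"sif"` writes simple-interaction-format lines
#' (`geneA co geneB`) plus optional node/edge attribute TSVs holding what
#' SIF itself cannot (tissue, max |log2FC|, peak day, bridging flag, edge
#' correlation at full precision). Re-import reproduces the graph.
#'
#' @param g An `igraph` graph with named vertices.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @param node_attr_path,edge_attr_path Attribute TSV paths (SIF only;
#'   optional).
#' @param interaction Interaction label used in SIF lines (default "co").
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "sif"),
                         node_attr_path = NULL, edge_attr_path = NULL,
                         interaction = "co") {
  format <- match.arg(format)
  stopifnot(inherits(g, "igraph"))
  if (is.null(igraph::V(g)$name)) {
    stop("graph vertices must be named")
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g)
  lines <- if (nrow(el)) {
    paste(el[, 1], interaction, el[, 2], sep = "\t")
  } else character(0)
  ## isolated nodes appear as single-token lines so the node set round-trips
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, iso), path, useBytes = TRUE)
  if (!is.null(node_attr_path)) {
    na <- data.frame(gene = igraph::V(g)$name, stringsAsFactors = FALSE)
    for (at in igraph::vertex_attr_names(g)) {
      if (at != "name") na[[at]] <- format_attr(igraph::vertex_attr(g, at))
    }
    write.table(na, node_attr_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(edge_attr_path)) {
    ea <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                     stringsAsFactors = FALSE)
    for (at in igraph::edge_attr_names(g)) {
      ea[[at]] <- format_attr(igraph::edge_attr(g, at))
    }
    write.table(ea, edge_attr_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

format_attr <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "sif"),
                         node_attr_path = NULL, edge_attr_path = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ## igraph stores its own numeric vertex id attribute on write; drop it
    if ("id" %in% igraph::vertex_attr_names(g)) {
      g <- igraph::delete_vertex_attr(g, "id")
    }
    return(g)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- !(lengths(parts) %in% c(1L, 3L))
  if (any(bad)) stop("malformed SIF line(s): ", paste(which(bad), collapse = ", "))
  edges <- do.call(rbind, lapply(parts[lengths(parts) == 3L],
                                 function(p) p[c(1, 3)]))
  iso <- unlist(parts[lengths(parts) == 1L])
  nodes <- unique(c(if (!is.null(edges)) as.vector(t(edges)), iso))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges[, 1], nodes),
                                    match(edges[, 2], nodes)))
  }
  if (!is.null(node_attr_path)) {
    na <- read.delim(node_attr_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    na <- na[match(igraph::V(g)$name, na$gene), , drop = FALSE]
    for (at in setdiff(names(na), "gene")) {
      g <- igraph::set_vertex_attr(g, at, value = na[[at]])
    }
  }
  if (!is.null(edge_attr_path) && !is.null(edges)) {
    ea <- read.delim(edge_attr_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    key_file <- paste(ea$gene_a, ea$gene_b)
    key_g <- paste(edges[, 1], edges[, 2])
    ea <- ea[match(key_g, key_file), , drop = FALSE]
    for (at in setdiff(names(ea), c("gene_a", "gene_b"))) {
      g <- igraph::set_edge_attr(g, at, value = ea[[at]])
    }
  }
  g
}
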