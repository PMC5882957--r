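#' Build the thresholded co-expression network
#'
#' Includes the edge (x, y) iff the PCIT mask is TRUE and the correlation
#' passes the declared threshold: |r| > `threshold` (default, the standard
#' reading) or r^2 > `threshold` under `mode = "r2"`. Isolated nodes are
#' retained; they are pruned later by the topology operations.
#'
#' @param r Correlation matrix (genes x genes).
#' @param mask Logical significance mask from [pcit_mask()].
#' @param node_attrs Data frame of node attributes with a `gene` column
#'   (typically from [assign_tissue()]); must cover every gene.
#' @param threshold Correlation threshold in \[0, 1) (default 0.90).
#' @param mode `"abs"`: include iff |r| > threshold; `"r2"`: include iff
#'   r^2 > threshold.
#' @return An `igraph` undirected graph; vertices carry `tissue`,
#'   `max_abs_log2fc` and `peak_day` attributes, edges carry `r` (also set
#'   as `weight`); graph attributes record the threshold and mode.
#' @export
build_network <- function(r, mask, node_attrs, threshold = 0.90,
                          mode = c("abs", "r2")) {
  mode <- match.arg(mode)
  if (!(threshold >= 0 && threshold < 1)) stop("need 0 <= threshold < 1")
  r <- check_corr_matrix(r)
  if (!identical(dim(r), dim(mask))) stop("r and mask shapes disagree")
  genes <- rownames(r)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(r)))
  missing_attr <- setdiff(genes, node_attrs$gene)
  if (length(missing_attr)) {
    stop("node attribute table missing gene(s): ",
         paste(missing_attr, collapse = ", "))
  }
  na <- node_attrs[match(genes, node_attrs$gene), , drop = FALSE]

  pass <- if (mode == "abs") abs(r) > threshold else r^2 > threshold
  keep <- mask & pass
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)

  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  igraph::V(g)$name <- genes
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
    igraph::E(g)$r <- r[idx]
    igraph::E(g)$weight <- r[idx]
  }
  igraph::V(g)$tissue <- as.character(na$tissue)
  if ("max_abs_log2fc" %in% names(na)) {
    igraph::V(g)$max_abs_log2fc <- na$max_abs_log2fc
  }
  if ("peak_day" %in% names(na)) igraph::V(g)$peak_day <- na$peak_day
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g <- igraph::set_graph_attr(g, "threshold_mode", mode)
  g
}

#' Summary counts for a graph or a list of graphs
#'
#' @param g An `igraph` graph, or a named list of graphs.
#' @return Data frame with node count, edge count, degree min/median/max
#'   and connected-component count per graph.
#' @export
network_summary <- function(g) {
  if (inherits(g, "igraph")) g <- list(network = g)
  rows <- lapply(names(g), function(nm) {
    gr <- g[[nm]]
    n <- igraph::vcount(gr)
    deg <- if (n) igraph::degree(gr) else numeric(0)
    data.frame(graph = nm, nodes = as.integer(n),
               edges = as.integer(igraph::ecount(gr)),
               degree_min = if (n) min(deg) else 0,
               degree_median = if (n) median(deg) else 0,
               degree_max = if (n) max(deg) else 0,
               components = if (n) {
                 as.integer(igraph::components(gr)$no)
               } else 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
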