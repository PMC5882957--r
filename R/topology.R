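#' Assign each gene to the tissue of its maximum fold change
#'
#' Maps every gene to the tissue and day at which its |log2FC| peaks. Exact
#' ties are broken by the declared tissue order, then by the earliest day,
#' and flagged in the output. All-zero profiles cannot be assigned and are
#' flagged `unassigned`.
#'
#' @param profiles Profile matrix (genes x conditions).
#' @return Data frame with columns `gene`, `tissue`, `max_abs_log2fc`,
#'   `peak_day`, `tie`, `unassigned`.
#' @export
assign_tissue <- function(profiles) {
  m <- as.matrix(profiles)
  if (nrow(m) == 0) stop("empty profile matrix")
  cc <- parse_conditions(colnames(m))
  tissues <- profile_tissues(profiles)
  ## column priority: declared tissue order, then ascending day
  prio <- order(match(cc$tissue, tissues), cc$day)
  a <- abs(m)
  out <- data.frame(gene = rownames(m), tissue = NA_character_,
                    max_abs_log2fc = 0, peak_day = NA_integer_,
                    tie = FALSE, unassigned = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    mx <- max(a[i, ])
    if (mx == 0) {
      out$unassigned[i] <- TRUE
      next
    }
    hits <- which(a[i, ] == mx)
    best <- prio[prio %in% hits][1]
    out$tissue[i] <- cc$tissue[best]
    out$max_abs_log2fc[i] <- mx
    out$peak_day[i] <- cc$day[best]
    out$tie[i] <- length(unique(cc$tissue[hits])) > 1
  }
  out
}

#' Extract tissue-specific sub-networks
#'
#' For each tissue, takes the subgraph induced on the genes assigned to it,
#' then removes nodes with no intra-tissue edge (they are reported as
#' excluded, mirroring the exclusion of genes not directly connected within
#' the main sub-networks). Unassigned genes are excluded up front.
#'
#' @param net Co-expression network ([build_network()]).
#' @param assignment Tissue assignment ([assign_tissue()]).
#' @return List with `subnetworks` (named list of `igraph` per tissue),
#'   `excluded` (genes isolated within their tissue) and `unassigned`.
#' @export
extract_tissue_subnetworks <- function(net, assignment) {
  vt <- node_tissues(net, assignment)
  tissues <- unique(assignment$tissue[!is.na(assignment$tissue)])
  subs <- list()
  excluded <- character(0)
  for (t in tissues) {
    nodes <- igraph::V(net)$name[!is.na(vt) & vt == t]
    sg <- igraph::induced_subgraph(net, nodes)
    iso <- igraph::V(sg)$name[igraph::degree(sg) == 0]
    excluded <- c(excluded, iso)
    subs[[t]] <- igraph::delete_vertices(sg, iso)
  }
  list(subnetworks = subs, excluded = excluded,
       unassigned = igraph::V(net)$name[is.na(vt)])
}

#' Identify bridging genes
#'
#' A bridging gene is a network gene whose direct neighbours are assigned
#' to at least two distinct tissues. Bridging is determined solely by the
#' edge set and the tissue labels of the neighbours; the gene's own label
#' plays no role. Unassigned neighbours are ignored.
#'
#' @inheritParams extract_tissue_subnetworks
#' @return Character vector of bridging gene ids.
#' @export
find_bridging_genes <- function(net, assignment) {
  vt <- node_tissues(net, assignment)
  names(vt) <- igraph::V(net)$name
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  bridging <- vapply(adj, function(nb) {
    ts <- unique(vt[igraph::as_ids(nb)])
    length(ts[!is.na(ts)]) >= 2
  }, logical(1))
  igraph::V(net)$name[bridging]
}

#' Rebuild the core network from the bridging genes
#'
#' The core network is the subgraph induced on the bridging genes; the
#' bridge connectivity is the number of distinct full-network edges with at
#' least one bridging endpoint. Sub-clusters of the core are reported
#' descriptively as its connected components.
#'
#' @param net Co-expression network.
#' @param bridging Character vector of bridging gene ids (subset of nodes).
#' @return List with `core` (igraph), `bridge_connectivity` (edge count)
#'   and `n_subclusters` (connected components of the core).
#' @export
build_core_network <- function(net, bridging) {
  if (!all(bridging %in% igraph::V(net)$name)) {
    stop("bridging genes must be network nodes")
  }
  core <- igraph::induced_subgraph(net, bridging)
  el <- igraph::as_edgelist(net)
  connectivity <- sum(el[, 1] %in% bridging | el[, 2] %in% bridging)
  list(core = core, bridge_connectivity = connectivity,
       n_subclusters = if (igraph::vcount(core)) {
         igraph::components(core)$no
       } else 0L)
}

#' Full network partition: sub-networks, bridging genes, core network
#'
#' Convenience wrapper running [extract_tissue_subnetworks()],
#' [find_bridging_genes()] and [build_core_network()] and collecting the
#' summary counts.
#'
#' @inheritParams extract_tissue_subnetworks
#' @return An object of class `subnetwork_partition`.
#' @export
subnetwork_partition <- function(net, assignment) {
  subs <- extract_tissue_subnetworks(net, assignment)
  bridging <- find_bridging_genes(net, assignment)
  core <- build_core_network(net, bridging)
  graphs <- c(list(full = net), subs$subnetworks, list(core = core$core))
  structure(list(subnetworks = subs$subnetworks,
                 excluded = subs$excluded,
                 unassigned = subs$unassigned,
                 bridging = bridging,
                 core = core$core,
                 bridge_connectivity = core$bridge_connectivity,
                 n_core_subclusters = core$n_subclusters,
                 summary = network_summary(graphs)),
            class = "subnetwork_partition")
}

#' @export
print.subnetwork_partition <- function(x, ...) {
  cat("subnetwork partition:\n")
  print(x$summary)
  cat("bridging genes: ", length(x$bridging),
      " (connectivity ", x$bridge_connectivity, ", ",
      x$n_core_subclusters, " core sub-clusters)\n", sep = "")
  invisible(x)
}

node_tissues <- function(net, assignment) {
  need <- c("gene", "tissue")
  if (!all(need %in% names(assignment))) {
    stop("assignment must have columns gene, tissue")
  }
  vt <- assignment$tissue[match(igraph::V(net)$name, assignment$gene)]
  if ("unassigned" %in% names(assignment)) {
    vt[assignment$unassigned[match(igraph::V(net)$name,
                                   assignment$gene)] %in% TRUE] <-
      NA_character_
  }
  vt
}
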