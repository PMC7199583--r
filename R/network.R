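# Shared-pathway interaction network: two genes are connected when they
# play roles in at least one common enriched pathway; the edge weight is
# the number of pathways they share.

#' Build a shared-pathway network from gene -> pathway memberships
#'
#' @param membership Named list mapping each gene to the character vector
#'   of enriched pathways it belongs to.
#' @return An object of class `pathway_network`: list with `nodes` (sorted
#'   gene identifiers), `edges` (`data.frame` `gene_a`, `gene_b`, `weight`,
#'   canonically ordered with `gene_a < gene_b`), and the `membership`
#'   list (entries de-duplicated, sorted by gene).
#' @examples
#' net <- build_network(list(A = c("P1", "P2"), B = c("P2", "P3"), C = "P4"))
#' net$edges  # single A-B edge of weight 1; C is isolated
#' @export
build_network <- function(membership) {
  stopifnot(is.list(membership))
  if (length(membership) && is.null(names(membership)))
    stop("membership must be a named list (gene -> pathways)")
  membership <- lapply(membership, function(p) unique(as.character(p)))
  genes <- sort(names(membership))
  membership <- membership[genes]
  paths <- sort(unique(unlist(membership, use.names = FALSE)))
  edges <- data.frame(gene_a = character(0), gene_b = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  if (length(genes) >= 2L && length(paths)) {
    inc <- vapply(membership,
                  function(p) as.integer(paths %in% p),
                  integer(length(paths)))
    inc <- matrix(inc, nrow = length(paths),
                  dimnames = list(paths, genes))
    w <- crossprod(inc)  # pairwise shared-pathway counts
    idx <- which(upper.tri(w) & w >= 1, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(gene_a = genes[idx[, 1L]],
                          gene_b = genes[idx[, 2L]],
                          weight = as.integer(w[idx]),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = genes, edges = edges, membership = membership),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("Shared-pathway network: ", length(x$nodes), " genes, ",
      nrow(x$edges), " edges over ",
      length(unique(unlist(x$membership, use.names = FALSE))),
      " pathways\n", sep = "")
  invisible(x)
}

#' Connectivity statistics for one gene in a pathway network
#'
#' Reports how many pathways the gene belongs to, its degree, and the mean
#' and sample standard deviation (n - 1 denominator) of its incident edge
#' weights — i.e. through how many shared pathways, on average, it connects
#' to its neighbours. An isolated node reports mean and sd of 0 with
#' `isolated = TRUE`.
#'
#' @param net A [build_network()] result.
#' @param gene Gene identifier (must be a node).
#' @param sd_type `"sample"` (default, n - 1) or `"population"` (n).
#' @return List with `gene`, `n_pathways`, `degree`, `mean_edge_weight`,
#'   `sd_edge_weight`, `isolated`.
#' @export
node_stats <- function(net, gene, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!gene %in% net$nodes)
    stop("gene '", gene, "' is not a node of the network")
  w <- net$edges$weight[net$edges$gene_a == gene | net$edges$gene_b == gene]
  deg <- length(w)
  if (deg == 0L)
    return(list(gene = gene, n_pathways = length(net$membership[[gene]]),
                degree = 0L, mean_edge_weight = 0, sd_edge_weight = 0,
                isolated = TRUE))
  s <- if (deg < 2L) 0
       else if (sd_type == "sample") stats::sd(w)
       else sqrt(sum((w - mean(w))^2) / deg)
  list(gene = gene, n_pathways = length(net$membership[[gene]]),
       degree = deg, mean_edge_weight = mean(w), sd_edge_weight = s,
       isolated = FALSE)
}

#' Node statistics for every gene in the network, as a table
#' @inheritParams node_stats
#' @return `data.frame`, one row per node.
#' @export
node_stats_table <- function(net, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  do.call(rbind, lapply(net$nodes, function(g) {
    s <- node_stats(net, g, sd_type)
    data.frame(gene = g, n_pathways = s$n_pathways, degree = s$degree,
               mean_edge_weight = s$mean_edge_weight,
               sd_edge_weight = s$sd_edge_weight, isolated = s$isolated,
               stringsAsFactors = FALSE)
  }))
}

#' Write a network as a SIF-style edge list
#'
#' Tab-separated `gene_a <TAB> weight <TAB> gene_b`, canonically sorted.
#'
#' @param net A [build_network()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_network_sif <- function(net, path) {
  lines <- sprintf("%s\t%d\t%s", net$edges$gene_a, net$edges$weight,
                   net$edges$gene_b)
  writeLines(lines, path)
  invisible(path)
}
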