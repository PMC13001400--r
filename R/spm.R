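#' Contact-gated correlation graph for shortest-path-map analysis
#'
#' Nodes are residues; an edge joins residues `i` and `j` when their mean
#' C-alpha distance is below `contact_cutoff` *and* `|C_ij| > 0`, with
#' weight `w_ij = -log|C_ij|` so strongly (anti-)correlated contacts are
#' short.  The absolute value keeps anti-correlated pairs (prominent in
#' e.g. YopH) as communication carriers; the correlation sign is retained
#' as edge metadata.  A contact pair with `C_ij = 0` carries infinite
#' weight and is omitted (logged via message).
#'
#' @param dccm a [compute_dccm()] map (or plain correlation matrix with
#'   residue-id dimnames).
#' @param distances mean C-alpha distance matrix in the same residue order.
#' @param contact_cutoff contact gate on the mean distance (Angstrom,
#'   default 6.0, the published SPM convention).
#' @return an object of class `residue_graph`: `nodes` (residue ids) and
#'   `edges` data.frame (`res_i`, `res_j`, `weight`, `distance`, `corr`).
#' @export
build_graph <- function(dccm, distances, contact_cutoff = 6.0) {
  cmat <- unclass(dccm)
  distances <- as.matrix(distances)
  if (!all(dim(cmat) == dim(distances)))
    stop("correlation and distance matrices differ in size", call. = FALSE)
  resno <- as.integer(rownames(cmat) %||% seq_len(nrow(cmat)))
  n <- nrow(cmat)
  pairs <- which(upper.tri(cmat), arr.ind = TRUE)
  in_contact <- distances[pairs] < contact_cutoff
  pairs <- pairs[in_contact, , drop = FALSE]
  cc <- cmat[pairs]
  dropped <- abs(cc) == 0
  if (any(dropped))
    message(sum(dropped), " contact pair(s) with zero correlation omitted",
            " (infinite weight)")
  pairs <- pairs[!dropped, , drop = FALSE]
  cc <- cc[!dropped]
  edges <- data.frame(res_i = resno[pairs[, 1]], res_j = resno[pairs[, 2]],
                      weight = -log(abs(cc)),
                      distance = distances[pairs], corr = cc)
  structure(list(nodes = resno, edges = edges,
                 contact_cutoff = contact_cutoff),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("residue_graph: %d nodes, %d edges (contact cutoff %.1f A)\n",
              length(x$nodes), nrow(x$edges), x$contact_cutoff))
  invisible(x)
}

# residue_graph -> igraph with residue-id vertex names
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(graph$edges$res_i),
               to = as.character(graph$edges$res_j),
               weight = graph$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = as.character(graph$nodes)))
  g
}

#' Shortest path map (SPM) from a residue graph
#'
#' Computes shortest paths between all node pairs (Dijkstra, per connected
#' component).  Every shortest path between a pair is counted — when ties
#' produce several geodesics, all of them contribute — so edge usage is
#' deterministic, independent of node iteration order.  Per-edge counts are
#' normalised by the maximum count; the SPM keeps edges with normalised
#' usage at or above `usage_threshold`, and the SPM residue set is every
#' node incident to a kept edge.
#'
#' @param graph a [build_graph()] result.
#' @param usage_threshold pruning threshold on normalised usage in `[0, 1]`
#'   (default 0.3; recorded in the result, override freely).
#' @return an object of class `spm_result`: `graph`, `edges` (graph edges
#'   plus `usage` and `in_spm`), `residues` (SPM residue ids) and
#'   `usage_threshold`.
#' @export
shortest_path_map <- function(graph, usage_threshold = 0.3) {
  stopifnot(inherits(graph, "residue_graph"))
  edges <- graph$edges
  if (nrow(edges) == 0) {
    return(structure(list(graph = graph,
                          edges = cbind(edges, usage = numeric(0),
                                        in_spm = logical(0)),
                          residues = integer(0),
                          usage_threshold = usage_threshold),
                     class = "spm_result"))
  }
  g <- as_igraph(graph)
  counts <- numeric(igraph::ecount(g))
  comp <- igraph::components(g)
  verts <- igraph::V(g)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 2) next
    for (a in seq_along(members)[-length(members)]) {
      from <- members[a]
      targets <- members[(a + 1):length(members)]
      asp <- igraph::all_shortest_paths(g, from = verts[from],
                                        to = verts[targets],
                                        weights = igraph::E(g)$weight)
      for (p in asp$vpaths) {
        if (length(p) < 2) next
        eids <- igraph::get_edge_ids(g, rbind(p[-length(p)], p[-1]))
        counts[eids] <- counts[eids] + 1
      }
    }
  }
  usage <- if (max(counts) > 0) counts / max(counts) else counts
  # igraph preserves edge order from the input data.frame
  edges$usage <- usage
  edges$in_spm <- usage >= usage_threshold & usage > 0
  residues <- sort(unique(c(edges$res_i[edges$in_spm],
                            edges$res_j[edges$in_spm])))
  structure(list(graph = graph, edges = edges, residues = residues,
                 usage_threshold = usage_threshold),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf(
    "spm_result: %d/%d edges kept (usage >= %.2f), %d SPM residues\n",
    sum(x$edges$in_spm), nrow(x$edges), x$usage_threshold,
    length(x$residues)))
  invisible(x)
}

#' Conservation of SPM residues between two proteins
#'
#' A residue of SPM A is *conserved* when its alignment partner belongs to
#' SPM B.  The measure is asymmetric by definition, so both directions are
#' reported.  Unmapped SPM-A residues count as non-conserved and are
#' listed.
#'
#' @param spm_a,spm_b [shortest_path_map()] results.
#' @param map an [alignment_map()] from A numbering to B numbering.
#' @return list with elements `a_in_b` and `b_in_a`, each holding
#'   `conserved`, `size`, `fraction` and `unmapped`.
#' @export
spm_conservation <- function(spm_a, spm_b, map) {
  one_way <- function(res_a, res_b, m) {
    mapped <- map_residues(m, res_a)
    unmapped <- res_a[is.na(mapped)]
    conserved <- sum(!is.na(mapped) & mapped %in% res_b)
    list(conserved = conserved, size = length(res_a),
         fraction = if (length(res_a)) conserved / length(res_a) else 0,
         unmapped = unmapped)
  }
  list(a_in_b = one_way(spm_a$residues, spm_b$residues, map),
       b_in_a = one_way(spm_b$residues, spm_a$residues, invert_map(map)))
}

#' Mean C-alpha distance matrix of an ensemble
#'
#' Convenience input for [build_graph()]: the per-pair mean over frames of
#' the C-alpha distances of the selected residues.
#'
#' @param ensemble a [coord_ensemble()].
#' @param selection atom indices (default: all C-alpha atoms).
#' @return symmetric matrix with residue-id dimnames.
#' @export
mean_distance_matrix <- function(ensemble, selection = NULL) {
  sel <- selection %||% which(ensemble$atoms$elety == "CA")
  m <- length(sel)
  acc <- matrix(0, m, m)
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- frame_coords(ensemble, f)[sel, , drop = FALSE]
    acc <- acc + as.matrix(dist(xyz))
  }
  acc <- acc / n_frames(ensemble)
  resno <- ensemble$atoms$resno[sel]
  dimnames(acc) <- list(resno, resno)
  acc
}

#' Write an SPM edge list as CSV
#'
#' Columns `res_i,res_j,weight,usage,in_spm`.
#'
#' @param spm a [shortest_path_map()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_spm_csv <- function(spm, path) {
  write.csv(spm$edges[, c("res_i", "res_j", "weight", "usage", "in_spm")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
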