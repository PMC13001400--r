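# Shared fixtures and independent brute-force oracles.

bead_table <- function(n, chain = "A") {
  data.frame(elety = "CA", resid = "ALA", resno = seq_len(n),
             chain = chain, stringsAsFactors = FALSE)
}

# single-frame bead ensemble from an N x 3 coordinate matrix
bead_frame <- function(coords, chain = "A") {
  coord_ensemble(as.vector(t(coords)), bead_table(nrow(coords), chain))
}

# toy two-loop system: a static 3-residue "P" loop and a mobile
# 3-residue "WPD" loop with distinct open/closed anchor geometries
toy_loops <- function() {
  p <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), ncol = 3, byrow = TRUE)
  closed <- rbind(sweep(p, 2, c(0, 6, 0), "+"), p)
  open <- rbind(sweep(p, 2, c(0, 12, 3), "+"), p)
  list(closed = closed, open = open,
       wpd = loop_definition("WPD", 1:3), p = loop_definition("P", 4:6),
       closed_ens = bead_frame(closed), open_ens = bead_frame(open))
}

# landscape anchors for the toy system, computed from the two references
toy_anchors <- function(tl, ref) {
  list(closed = c(compute_drmsd(tl$closed_ens, ref),
                  compute_com_distance(tl$closed_ens, tl$wpd, tl$p)),
       open = c(compute_drmsd(tl$open_ens, ref),
                compute_com_distance(tl$open_ens, tl$wpd, tl$p)))
}

# exhaustive shortest-path edge-usage oracle: enumerate every simple path
# between every node pair, keep the minimum-weight ones, count edges.
# Only feasible on tiny graphs; this is the reference the Dijkstra-based
# implementation is compared against.
enumerate_usage <- function(graph, tol = 1e-9) {
  edges <- graph$edges
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")
  wt <- stats::setNames(edges$weight, ekey(edges$res_i, edges$res_j))
  nbrs <- list()
  for (k in seq_len(nrow(edges))) {
    i <- as.character(edges$res_i[k]); j <- as.character(edges$res_j[k])
    nbrs[[i]] <- c(nbrs[[i]], edges$res_j[k])
    nbrs[[j]] <- c(nbrs[[j]], edges$res_i[k])
  }
  counts <- stats::setNames(numeric(nrow(edges)),
                            ekey(edges$res_i, edges$res_j))
  nodes <- graph$nodes
  for (a_i in seq_along(nodes)) {
    for (b_i in seq_along(nodes)) {
      if (b_i <= a_i) next
      a <- nodes[a_i]; b <- nodes[b_i]
      paths <- list(); best <- Inf
      walk <- function(cur, visited, w) {
        if (cur == b) {
          if (w < best - tol) { best <<- w; paths <<- list(visited) }
          else if (abs(w - best) <= tol) paths[[length(paths) + 1]] <<- visited
          return(invisible())
        }
        for (nx in nbrs[[as.character(cur)]]) {
          if (nx %in% visited) next
          walk(nx, c(visited, nx), w + wt[[ekey(cur, nx)]])
        }
      }
      walk(a, a, 0)
      if (is.finite(best)) {
        for (p in paths) {
          for (s in seq_len(length(p) - 1)) {
            k <- ekey(p[s], p[s + 1])
            counts[k] <- counts[k] + 1
          }
        }
      }
    }
  }
  if (max(counts) > 0) counts <- counts / max(counts)
  unname(counts[ekey(edges$res_i, edges$res_j)])
}

# brute-force closest-heavy-atom scan for hotspot classification
brute_classify <- function(positions, spm_residues, structure, cutoff,
                           frame = 1) {
  at <- structure$atoms
  xyz <- frame_coords(structure, frame)
  heavy <- !grepl("^[0-9]*H", at$elety)
  vapply(positions, function(pos) {
    if (pos %in% spm_residues) return("on_spm")
    pa <- which(heavy & at$resno == pos)
    sa <- which(heavy & at$resno %in% spm_residues)
    if (length(pa) == 0 || length(sa) == 0) return("unclassifiable")
    dmin <- Inf
    for (i in pa) for (j in sa)
      dmin <- min(dmin, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    if (dmin < cutoff) "near_spm" else "far_spm"
  }, character(1))
}

# block-diagonal residue correlation matrix expanded to 3N displacement
# covariance (each Cartesian component independent, common cross-residue
# correlation), so the expected scalar DCCM entry equals the planted value
planted_covariance <- function(corr_pairs, n_res) {
  rmat <- diag(n_res)
  for (p in corr_pairs) rmat[p[[1]], p[[2]]] <- rmat[p[[2]], p[[1]]] <- p[[3]]
  kronecker(rmat, diag(3))
}
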