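#' Reference cross-loop distance set for the dRMSD metric
#'
#' The dRMSD of a frame is measured against the full cross product of
#' WPD-loop x P-loop C-alpha distances taken from a single closed reference
#' structure (conventionally the PTP1B closed conformation, so all proteins
#' share one scale).
#'
#' @param reference a [coord_ensemble()] holding the reference structure.
#' @param wpd_loop,p_loop [loop_definition()]s resolvable in the reference.
#' @param frame which reference frame to use (default 1).
#' @param source_label free-text provenance label stored with the set.
#' @param intra_loop if `TRUE`, also include all pairs *within* the union
#'   of the two loops (alternative reading of "all combined distances");
#'   default `FALSE` keeps the cross-product definition.
#' @return an object of class `reference_distance_set`: data.frame `pairs`
#'   with columns `res_a`, `res_b`, `d_ref` (Angstrom).
#' @export
build_reference <- function(reference, wpd_loop, p_loop, frame = 1L,
                            source_label = "reference", intra_loop = FALSE) {
  ia <- select_loop(reference, wpd_loop, mode = "calpha")
  ib <- select_loop(reference, p_loop, mode = "calpha")
  xyz <- frame_coords(reference, frame)
  if (intra_loop) {
    all_idx <- c(ia, ib)
    all_res <- c(wpd_loop$residues, p_loop$residues)
    cmb <- utils::combn(seq_along(all_idx), 2)
    pr <- data.frame(res_a = all_res[cmb[1, ]], res_b = all_res[cmb[2, ]],
                     ia = all_idx[cmb[1, ]], ib = all_idx[cmb[2, ]])
  } else {
    g <- expand.grid(i = seq_along(ia), j = seq_along(ib))
    pr <- data.frame(res_a = wpd_loop$residues[g$i],
                     res_b = p_loop$residues[g$j],
                     ia = ia[g$i], ib = ib[g$j])
  }
  d <- sqrt(rowSums((xyz[pr$ia, , drop = FALSE] -
                       xyz[pr$ib, , drop = FALSE])^2))
  structure(list(pairs = data.frame(res_a = pr$res_a, res_b = pr$res_b,
                                    d_ref = d),
                 source = source_label,
                 loops = c(wpd_loop$name, p_loop$name),
                 intra_loop = intra_loop),
            class = "reference_distance_set")
}

#' @export
print.reference_distance_set <- function(x, ...) {
  cat(sprintf("reference_distance_set (%s): %d pairs from '%s'\n",
              paste(x$loops, collapse = " x "), nrow(x$pairs), x$source))
  invisible(x)
}

# resolve one CA atom index per residue id (chain-agnostic)
resolve_ca <- function(ensemble, resno) {
  at <- ensemble$atoms
  vapply(resno, function(r) {
    i <- which(at$resno == r & at$elety == "CA")
    if (length(i) != 1L)
      stop(sprintf("residue %d has no unique CA atom in the trajectory", r),
           call. = FALSE)
    i
  }, integer(1))
}

#' Per-frame distance-RMSD against a reference distance set
#'
#' `dRMSD_t = sqrt(mean over pairs of (d_pair(t) - d_ref)^2)`.  Built from
#' internal distances only, so it is exactly invariant under rigid-body
#' motion of the frame; no superposition is performed.  When the trajectory
#' protein differs from the reference protein, residue ids are translated
#' through an [alignment_map()] (reference ids in `res_a`); any unmapped
#' pair aborts with the full list, because silently dropping pairs would
#' change the metric's scale.
#'
#' @param ensemble a [coord_ensemble()].
#' @param reference a [build_reference()] result.
#' @param map optional [alignment_map()] from reference numbering to
#'   trajectory numbering.
#' @return numeric vector of per-frame dRMSD (Angstrom).
#' @export
compute_drmsd <- function(ensemble, reference, map = NULL) {
  stopifnot(inherits(reference, "reference_distance_set"))
  pr <- reference$pairs
  res_a <- map_residues(map, pr$res_a)
  res_b <- map_residues(map, pr$res_b)
  bad <- is.na(res_a) | is.na(res_b)
  if (any(bad))
    stop("unmapped reference pair(s): ",
         paste(sprintf("%d-%d", pr$res_a[bad], pr$res_b[bad]),
               collapse = ", "), call. = FALSE)
  ia <- resolve_ca(ensemble, res_a)
  ib <- resolve_ca(ensemble, res_b)
  xyz <- ensemble$xyz
  dx <- xyz[, 3 * (ia - 1) + 1, drop = FALSE] -
    xyz[, 3 * (ib - 1) + 1, drop = FALSE]
  dy <- xyz[, 3 * (ia - 1) + 2, drop = FALSE] -
    xyz[, 3 * (ib - 1) + 2, drop = FALSE]
  dz <- xyz[, 3 * ia, drop = FALSE] - xyz[, 3 * ib, drop = FALSE]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  dev <- sweep(d, 2, pr$d_ref)
  sqrt(rowMeans(dev^2))
}

#' Per-frame distance between two loop centres of mass
#'
#' @param ensemble a [coord_ensemble()].
#' @param loop_a,loop_b [loop_definition()]s.
#' @param mass_weighted use atomic masses (default) or plain centroids.
#' @param mode atom selection per loop, `"heavy"` (default) or `"calpha"`.
#' @return numeric vector of per-frame distances (Angstrom).
#' @export
compute_com_distance <- function(ensemble, loop_a, loop_b,
                                 mass_weighted = TRUE,
                                 mode = c("heavy", "calpha")) {
  mode <- match.arg(mode)
  ia <- select_loop(ensemble, loop_a, mode = mode)
  ib <- select_loop(ensemble, loop_b, mode = mode)
  com <- function(idx) {
    w <- if (mass_weighted) ensemble$atoms$mass[idx] else rep(1, length(idx))
    w <- w / sum(w)
    sapply(1:3, function(ax)
      ensemble$xyz[, 3 * (idx - 1) + ax, drop = FALSE] %*% w)
  }
  ca <- com(ia); cb <- com(ib)
  if (is.vector(ca)) { ca <- matrix(ca, nrow = 1); cb <- matrix(cb, nrow = 1) }
  sqrt(rowSums((ca - cb)^2))
}

#' 2D conformational-landscape histogram
#'
#' Bins the per-frame (dRMSD, centre-of-mass distance) series into a 2D
#' occupancy histogram; the total count always equals the number of frames
#' (out-of-range values are clamped into the edge bins).  Anchor points are
#' the (dRMSD, COM) coordinates of the open and closed reference
#' structures, computed with the same two metrics.
#'
#' @param drmsd,com equal-length per-frame series.
#' @param bins either `c(nx, ny)` bin counts (edges span the data plus
#'   anchors) or a list `list(x = edges, y = edges)`.
#' @param anchors optional named list with numeric `closed = c(x, y)` and/or
#'   `open = c(x, y)` anchor coordinates.
#' @return an object of class `landscape_histogram`: `x_edges`, `y_edges`,
#'   `counts` (nx x ny), `anchors`, `n_frames`.
#' @export
build_landscape <- function(drmsd, com, bins = c(50, 50), anchors = NULL) {
  if (length(drmsd) != length(com))
    stop(sprintf("series length mismatch (%d vs %d)", length(drmsd),
                 length(com)), call. = FALSE)
  if (is.list(bins)) {
    xe <- bins$x; ye <- bins$y
  } else {
    pad <- function(v, extra) {
      vals <- c(v, extra)
      if (length(vals) == 0) vals <- c(0, 1)
      r <- range(vals)
      if (diff(r) == 0) r <- r + c(-0.5, 0.5)
      r + c(-1, 1) * 1e-9 * max(1, abs(r))
    }
    ax <- unlist(lapply(anchors, `[`, 1))
    ay <- unlist(lapply(anchors, `[`, 2))
    rx <- pad(drmsd, ax); ry <- pad(com, ay)
    xe <- seq(rx[1], rx[2], length.out = bins[1] + 1)
    ye <- seq(ry[1], ry[2], length.out = bins[2] + 1)
  }
  nx <- length(xe) - 1L; ny <- length(ye) - 1L
  counts <- matrix(0L, nx, ny)
  if (length(drmsd) > 0) {
    bx <- pmin(pmax(findInterval(drmsd, xe, all.inside = TRUE), 1L), nx)
    by <- pmin(pmax(findInterval(com, ye, all.inside = TRUE), 1L), ny)
    for (k in seq_along(bx))
      counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1L
  }
  structure(list(x_edges = xe, y_edges = ye, counts = counts,
                 anchors = anchors, n_frames = length(drmsd)),
            class = "landscape_histogram")
}

#' @export
print.landscape_histogram <- function(x, ...) {
  cat(sprintf("landscape_histogram: %d x %d bins, %d frames\n",
              nrow(x$counts), ncol(x$counts), x$n_frames))
  invisible(x)
}

#' Classify frames as closed / semi-closed / open
#'
#' Each frame's (dRMSD, COM) point is compared, in anchor-normalised
#' coordinates (each axis divided by the absolute closed-open anchor
#' difference), to the two anchors.  A frame within `r_closed` of the
#' closed anchor is `closed`, within `r_open` of the open anchor `open`,
#' otherwise `semi_closed`.  The radii default to 25% of the inter-anchor
#' distance in the normalised space; if a frame falls within both radii the
#' nearer anchor wins.
#'
#' @param drmsd,com per-frame series.
#' @param anchors named list with `closed = c(x, y)` and `open = c(x, y)`.
#' @param r_closed,r_open classification radii in normalised units
#'   (defaults: 0.25 of the normalised inter-anchor distance).
#' @return character vector of per-frame labels.
#' @export
classify_states <- function(drmsd, com, anchors, r_closed = NULL,
                            r_open = NULL) {
  if (is.null(anchors$closed) || is.null(anchors$open))
    stop("'anchors' must provide both 'closed' and 'open'", call. = FALSE)
  cl <- anchors$closed; op <- anchors$open
  sx <- abs(cl[1] - op[1]); sy <- abs(cl[2] - op[2])
  if (sx == 0) sx <- 1
  if (sy == 0) sy <- 1
  d_anchor <- sqrt(((cl[1] - op[1]) / sx)^2 + ((cl[2] - op[2]) / sy)^2)
  r_closed <- r_closed %||% (0.25 * d_anchor)
  r_open <- r_open %||% (0.25 * d_anchor)
  dc <- sqrt(((drmsd - cl[1]) / sx)^2 + ((com - cl[2]) / sy)^2)
  do <- sqrt(((drmsd - op[1]) / sx)^2 + ((com - op[2]) / sy)^2)
  lab <- rep("semi_closed", length(drmsd))
  lab[do < r_open] <- "open"
  lab[dc < r_closed] <- "closed"
  both <- dc < r_closed & do < r_open
  lab[both] <- ifelse(dc[both] <= do[both], "closed", "open")
  lab
}

#' Per-residue RMSF profile
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` over C-alpha atoms, after
#' optional least-squares superposition of every frame onto the iterated
#' ensemble-average structure (2 iterations, standard practice; set
#' `iterations = 1` for a single pass).
#'
#' @param ensemble a [coord_ensemble()] with >= 2 frames.
#' @param superpose remove rigid-body motion first (default `TRUE`).
#' @param fit_selection atom indices used for the fit (default: all
#'   C-alpha atoms).
#' @param iterations average-structure refinement passes.
#' @return an object of class `rmsf_profile`: data.frame with `resno`,
#'   `rmsf` (Angstrom), plus a `superposed` attribute.
#' @export
compute_rmsf <- function(ensemble, superpose = TRUE, fit_selection = NULL,
                         iterations = 2L) {
  if (n_frames(ensemble) < 2L)
    stop("RMSF requires at least 2 frames", call. = FALSE)
  ca <- which(ensemble$atoms$elety == "CA")
  if (length(ca) == 0L) stop("no C-alpha atoms present", call. = FALSE)
  xyz <- ensemble$xyz
  if (superpose)
    xyz <- superpose_ensemble(xyz, fit_selection %||% ca, iterations)
  cols <- atoms2xyz(ca)
  sub <- xyz[, cols, drop = FALSE]
  dev2 <- sweep(sub, 2, colMeans(sub))^2
  per_axis <- colMeans(dev2)
  rmsf <- sqrt(per_axis[seq(1, length(per_axis), 3)] +
                 per_axis[seq(2, length(per_axis), 3)] +
                 per_axis[seq(3, length(per_axis), 3)])
  out <- data.frame(resno = ensemble$atoms$resno[ca], rmsf = unname(rmsf))
  attr(out, "superposed") <- superpose
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

# fit all frames onto the iterated average structure (bio3d Kabsch fit)
superpose_ensemble <- function(xyz, fit_atoms, iterations = 2L) {
  cols <- atoms2xyz(fit_atoms)
  for (it in seq_len(max(1L, iterations))) {
    ref <- colMeans(xyz)
    xyz <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                          fixed.inds = cols, mobile.inds = cols)
  }
  xyz
}

#' Difference RMSF between two systems
#'
#' `delta_i = RMSF_i(a) - RMSF_i(b)`: a positive value indicates more
#' flexibility in the first system.  Residues are matched through an
#' [alignment_map()] when the numberings differ.
#'
#' @param a,b [compute_rmsf()] profiles.
#' @param map optional [alignment_map()] from `a` numbering to `b`
#'   numbering.
#' @return data.frame with `resno_a`, `resno_b`, `delta`.
#' @export
delta_rmsf <- function(a, b, map = NULL) {
  stopifnot(inherits(a, "rmsf_profile"), inherits(b, "rmsf_profile"))
  res_b <- map_residues(map, a$resno)
  keep <- !is.na(res_b) & res_b %in% b$resno
  data.frame(resno_a = a$resno[keep], resno_b = res_b[keep],
             delta = a$rmsf[keep] - b$rmsf[match(res_b[keep], b$resno)])
}

#' Reactive-conformation distance criteria
#'
#' A frame is *reactive* (productive for the chemical step) when every
#' listed atom-pair distance is strictly below its cutoff.
#'
#' @param constraints data.frame with columns `res_a`, `atom_a`, `res_b`,
#'   `atom_b`, `max_dist` (Angstrom, > 0).
#' @return an object of class `reactive_criteria`.
#' @export
reactive_criteria <- function(constraints) {
  constraints <- as.data.frame(constraints, stringsAsFactors = FALSE)
  need <- c("res_a", "atom_a", "res_b", "atom_b", "max_dist")
  miss <- setdiff(need, names(constraints))
  if (length(miss))
    stop("constraints lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(constraints$max_dist <= 0))
    stop("cutoff distances must be > 0", call. = FALSE)
  structure(list(constraints = constraints), class = "reactive_criteria")
}

#' Default PTP hydrolysis-step criteria (SHP-1 numbering)
#'
#' General-acid carboxylate oxygen of Asp419 within 4.5 A of the
#' phosphocysteine (pCys453) phosphorus, and the Gln500 side-chain carbon
#' within 8 A of the same phosphorus, so the glutamine can position the
#' hydrolytic water.
#'
#' @return a [reactive_criteria()].
#' @export
default_reactive_criteria <- function() {
  reactive_criteria(data.frame(
    res_a = c(419L, 500L), atom_a = c("OD1", "CD"),
    res_b = c(453L, 453L), atom_b = c("P", "P"),
    max_dist = c(4.5, 8.0), stringsAsFactors = FALSE))
}

#' Fraction of reactive frames under distance criteria
#'
#' @param ensemble a [coord_ensemble()].
#' @param criteria a [reactive_criteria()] (default:
#'   [default_reactive_criteria()]).
#' @return list with `fraction`, `frames` (indices of reactive frames) and
#'   `pass` (per-frame logical).
#' @export
reactive_fraction <- function(ensemble, criteria = default_reactive_criteria()) {
  stopifnot(inherits(criteria, "reactive_criteria"))
  at <- ensemble$atoms
  resolve <- function(resno, atom) {
    i <- which(at$resno == resno & at$elety == atom)
    if (length(i) != 1L)
      stop(sprintf("cannot resolve atom spec %d:%s", resno, atom),
           call. = FALSE)
    i
  }
  cn <- criteria$constraints
  pass <- rep(TRUE, n_frames(ensemble))
  for (k in seq_len(nrow(cn))) {
    ia <- resolve(cn$res_a[k], cn$atom_a[k])
    ib <- resolve(cn$res_b[k], cn$atom_b[k])
    d <- sqrt((ensemble$xyz[, 3 * ia - 2] - ensemble$xyz[, 3 * ib - 2])^2 +
                (ensemble$xyz[, 3 * ia - 1] - ensemble$xyz[, 3 * ib - 1])^2 +
                (ensemble$xyz[, 3 * ia] - ensemble$xyz[, 3 * ib])^2)
    pass <- pass & (d < cn$max_dist[k])
  }
  list(fraction = mean(pass), frames = which(pass), pass = pass)
}

#' Write a per-frame metric series as CSV
#'
#' @param drmsd,com,state per-frame series (state optional).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_metric_csv <- function(drmsd, com, state = NULL, path) {
  df <- data.frame(frame = seq_along(drmsd), drmsd = drmsd,
                   com_distance = com)
  if (!is.null(state)) df$state <- state
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
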