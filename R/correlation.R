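#' Dynamic cross-correlation map (DCCM)
#'
#' Scalar DCCM over C-alpha displacement vectors:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` with
#' `dr_i = r_i(t) - <r_i>`, computed after optional superposition of every
#' frame onto the iterated average structure (superposition removes
#' rigid-body drift that would otherwise inflate correlations).  Frames may
#' be a concatenation of several replicas; use [concat_ensembles()] to
#' merge replicas after independent superposition.
#'
#' @param ensemble a [coord_ensemble()] with >= 2 frames.
#' @param selection atom indices to correlate (default: all C-alpha atoms).
#' @param superpose fit frames to the average structure first (default
#'   `TRUE`).
#' @param stride keep every `stride`-th frame (default 1, i.e. all).
#' @return an object of class `correlation_map`: the symmetric matrix with
#'   unit diagonal, residue ids as dimnames, and attributes `n_frames` and
#'   `zero_variance` (residue ids whose rows were zeroed, with a warning).
#' @export
compute_dccm <- function(ensemble, selection = NULL, superpose = TRUE,
                         stride = 1L) {
  if (n_frames(ensemble) < 2L)
    stop("DCCM requires at least 2 frames", call. = FALSE)
  sel <- selection %||% which(ensemble$atoms$elety == "CA")
  xyz <- ensemble$xyz
  if (stride > 1L) xyz <- xyz[seq(1, nrow(xyz), by = stride), , drop = FALSE]
  if (superpose) xyz <- superpose_ensemble(xyz, sel)
  sub <- xyz[, atoms2xyz(sel), drop = FALSE]
  d <- sweep(sub, 2, colMeans(sub))
  n <- nrow(d); m <- length(sel)
  ix <- seq(1, 3 * m, 3)
  s <- (crossprod(d[, ix]) + crossprod(d[, ix + 1]) +
          crossprod(d[, ix + 2])) / n
  v <- diag(s)
  zero <- v <= .Machine$double.eps
  v_safe <- ifelse(zero, 1, v)
  cmat <- s / sqrt(outer(v_safe, v_safe))
  if (any(zero)) {
    warning("zero-variance residue(s): ",
            paste(ensemble$atoms$resno[sel][zero], collapse = ", "),
            "; rows/columns set to 0")
    cmat[zero, ] <- 0
    cmat[, zero] <- 0
  }
  diag(cmat) <- 1
  cmat <- (cmat + t(cmat)) / 2
  cmat[cmat > 1] <- 1
  cmat[cmat < -1] <- -1
  resno <- ensemble$atoms$resno[sel]
  dimnames(cmat) <- list(resno, resno)
  structure(cmat, class = c("correlation_map", "matrix"),
            n_frames = n,
            zero_variance = ensemble$atoms$resno[sel][zero])
}

#' Concatenate replica ensembles (independent superposition first)
#'
#' Each replica is superposed onto its own average structure, then the
#' frames are stacked.  Mirrors the evenly-spaced-snapshots-across-
#' concatenated-trajectories convention used for multi-replica DCCMs.
#'
#' @param ensembles list of [coord_ensemble()]s sharing one atom table.
#' @param superpose superpose each replica before stacking.
#' @return a single [coord_ensemble()].
#' @export
concat_ensembles <- function(ensembles, superpose = TRUE) {
  stopifnot(length(ensembles) >= 1)
  at <- ensembles[[1]]$atoms
  for (e in ensembles)
    if (!identical(dim(e$atoms), dim(at)) ||
        !identical(e$atoms$resno, at$resno))
      stop("replicas must share one atom table", call. = FALSE)
  ca <- which(at$elety == "CA")
  xs <- lapply(ensembles, function(e) {
    if (superpose) superpose_ensemble(e$xyz, ca) else e$xyz
  })
  coord_ensemble(do.call(rbind, xs), at)
}

#' Restrict correlation maps to positions shared across proteins
#'
#' Keeps only the anchor-protein residues mapped in *every* protein, in
#' anchor order, and subsets each protein's map to its corresponding
#' residues.  Because only structurally conserved common regions survive,
#' the edges of the restricted maps are generally not the protein termini;
#' the retained residue ids are recorded explicitly.
#'
#' @param maps named list of [compute_dccm()] maps; the first is the
#'   anchor protein.
#' @param align_maps named list of [alignment_map()]s from the anchor
#'   numbering (`res_a`) to each non-anchor protein (`res_b`), one per
#'   non-anchor entry of `maps`.
#' @return named list of restricted `correlation_map`s with attribute
#'   `anchor_residues` (the retained anchor residue ids).  Idempotent.
#' @export
restrict_common <- function(maps, align_maps = NULL) {
  stopifnot(is.list(maps), length(maps) >= 1)
  anchor <- names(maps)[1]
  anchor_res <- as.integer(rownames(maps[[1]]))
  keep <- anchor_res
  per_protein <- list()
  per_protein[[anchor]] <- stats::setNames(anchor_res, anchor_res)
  for (nm in names(maps)[-1]) {
    am <- align_maps[[nm]]
    if (is.null(am))
      stop("no alignment map supplied for protein '", nm, "'",
           call. = FALSE)
    own <- as.integer(rownames(maps[[nm]]))
    mapped <- map_residues(am, anchor_res)
    ok <- !is.na(mapped) & mapped %in% own
    keep <- intersect(keep, anchor_res[ok])
    per_protein[[nm]] <- stats::setNames(mapped, anchor_res)
  }
  if (length(keep) == 0)
    stop("no positions are shared across all proteins", call. = FALSE)
  keep <- anchor_res[anchor_res %in% keep]  # anchor order
  out <- lapply(names(maps), function(nm) {
    own_ids <- unname(per_protein[[nm]][as.character(keep)])
    sub <- maps[[nm]][as.character(own_ids), as.character(own_ids)]
    structure(sub, class = c("correlation_map", "matrix"),
              n_frames = attr(maps[[nm]], "n_frames"))
  })
  names(out) <- names(maps)
  attr(out, "anchor_residues") <- keep
  out
}

#' Dominant modes of C-alpha motion
#'
#' Eigendecomposition of the 3N x 3N displacement covariance after
#' superposition (a principal-component analysis of the selected atoms).
#' Eigenvector signs follow the convention that each vector's
#' largest-magnitude component is positive.
#'
#' @param ensemble a [coord_ensemble()].
#' @param selection atom indices (default: all C-alpha atoms).
#' @param k number of modes to return.
#' @param superpose fit frames to the average structure first.
#' @return an object of class `mode_set`: `values` (eigenvalues, Angstrom^2,
#'   descending), `vectors` (3N x k, orthonormal), `cum_var` (cumulative
#'   variance fractions), `projections` (n_frames x k per-frame scalar
#'   projections) and `trace` (total displacement variance).
#' @export
dominant_modes <- function(ensemble, selection = NULL, k = 2L,
                           superpose = TRUE) {
  sel <- selection %||% which(ensemble$atoms$elety == "CA")
  if (n_frames(ensemble) <= 3L * length(sel))
    warning(sprintf(
      "only %d frames for %d degrees of freedom; modes may be noisy",
      n_frames(ensemble), 3L * length(sel)))
  xyz <- ensemble$xyz
  if (superpose) xyz <- superpose_ensemble(xyz, sel)
  d <- sweep(xyz[, atoms2xyz(sel), drop = FALSE], 2, colMeans(
    xyz[, atoms2xyz(sel), drop = FALSE]))
  cv <- crossprod(d) / nrow(d)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values, 0) * 1e-12)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; truncated", k, rank))
    k <- max(rank, 1L)
  }
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  tot <- sum(pmax(eg$values, 0))
  structure(list(values = eg$values[seq_len(k)], vectors = vec,
                 cum_var = if (tot > 0)
                   cumsum(pmax(eg$values[seq_len(k)], 0)) / tot
                 else rep(0, k),
                 projections = d %*% vec, trace = sum(diag(cv))),
            class = "mode_set")
}

#' Write a correlation map as a CSV matrix
#'
#' Residue ids form the header row and first column.
#'
#' @param map a [compute_dccm()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dccm_csv <- function(map, path) {
  df <- as.data.frame(unclass(map))
  names(df) <- colnames(map)
  df <- cbind(resno = rownames(map), df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dccm_csv
#' @export
read_dccm_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$resno
  structure(m, class = c("correlation_map", "matrix"))
}
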