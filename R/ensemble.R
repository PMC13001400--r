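#' Coordinate ensemble container
#'
#' A light-weight trajectory container: an `n_frames x 3N` coordinate matrix
#' in bio3d `xyz` layout (columns `x1,y1,z1,x2,...`) plus a per-atom table.
#' All frames share the atom table; coordinates must be finite.
#'
#' @param xyz numeric matrix (or vector for a single frame) with 3N columns,
#'   one row per frame, coordinates in Angstrom.
#' @param atoms data.frame with one row per atom and at least the columns
#'   `elety` (atom name), `resid` (residue name), `resno` (author residue
#'   number, 1-based) and `chain`.  Optional columns `mass`, `het`
#'   (heteroatom flag) and `ca_only` (residue lacks side-chain atoms) are
#'   filled with defaults when absent.
#' @param dt optional frame spacing (arbitrary time units).
#' @return an object of class `coord_ensemble`.
#' @examples
#' atoms <- data.frame(elety = "CA", resid = "ALA", resno = 1:2, chain = "A")
#' ens <- coord_ensemble(rbind(c(0, 0, 0, 3.8, 0, 0)), atoms)
#' n_frames(ens)
#' @export
coord_ensemble <- function(xyz, atoms, dt = NULL) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) %% 3 != 0)
    stop("'xyz' must be numeric with 3N columns", call. = FALSE)
  if (!all(is.finite(xyz)))
    stop("coordinates must be finite", call. = FALSE)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("elety", "resid", "resno", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) * 3L != ncol(xyz))
    stop(sprintf("atom table (%d atoms) does not match xyz (%d columns)",
                 nrow(atoms), ncol(xyz)), call. = FALSE)
  if (is.null(atoms$mass)) atoms$mass <- guess_mass(atoms$elety)
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$ca_only)) atoms$ca_only <- flag_ca_only(atoms)
  structure(list(xyz = unname(xyz), atoms = atoms, dt = dt),
            class = "coord_ensemble")
}

# element mass from a PDB atom name; hydrogens matter only through
# exclusion so a first-letter element lookup is sufficient
guess_mass <- function(elety) {
  masses <- c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994,
              P = 30.973762, S = 32.065, F = 18.9984)
  el <- ifelse(is_hydrogen(elety), "H",
               substr(gsub("^[0-9]+", "", elety), 1, 1))
  m <- masses[el]
  m[is.na(m)] <- 12.0107
  unname(m)
}

# a residue is flagged when its only heavy atom record is the C-alpha
flag_ca_only <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno)
  heavy <- !is_hydrogen(atoms$elety)
  per_res <- tapply(seq_len(nrow(atoms)), key, function(i) {
    h <- atoms$elety[i][heavy[i]]
    length(h) > 0 && all(h == "CA")
  })
  as.logical(per_res[key])
}

is_hydrogen <- function(elety) {
  grepl("^[0-9]*H", elety)
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat(sprintf("coord_ensemble: %d frame(s), %d atoms, %d residues\n",
              n_frames(x), n_atoms(x),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble a [coord_ensemble()].
#' @return integer count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) nrow(ensemble$atoms)

#' Extract one frame as an N x 3 coordinate matrix
#' @param ensemble a [coord_ensemble()].
#' @param i frame index.
#' @return numeric matrix with one row per atom.
#' @export
frame_coords <- function(ensemble, i = 1L) {
  if (i < 1L || i > n_frames(ensemble))
    stop(sprintf("frame %d out of range (1..%d)", i, n_frames(ensemble)),
         call. = FALSE)
  matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Named residue selection (loop definition)
#'
#' Anchors every loop-level metric.  Residue ids use the author numbering of
#' the structure they are applied to (1-based, never renumbered).
#'
#' @param name loop name; conventionally one of `"WPD"`, `"P"`, `"Q"`,
#'   `"E"` or a custom label.
#' @param residues strictly increasing vector of residue numbers.
#' @param chain chain identifier, or `NA` to match any chain.
#' @return an object of class `loop_definition`.
#' @export
loop_definition <- function(name, residues, chain = NA_character_) {
  residues <- as.integer(residues)
  if (length(residues) == 0L)
    stop("loop '", name, "': residue list is empty", call. = FALSE)
  if (any(diff(residues) <= 0L))
    stop("loop '", name, "': residue ids must be strictly increasing",
         call. = FALSE)
  structure(list(name = as.character(name), residues = residues,
                 chain = chain), class = "loop_definition")
}

#' @export
print.loop_definition <- function(x, ...) {
  cat(sprintf("loop_definition '%s': residues %s-%s (%d), chain %s\n",
              x$name, min(x$residues), max(x$residues), length(x$residues),
              ifelse(is.na(x$chain), "any", x$chain)))
  invisible(x)
}

#' Resolve a loop definition to atom indices
#'
#' @param ensemble a [coord_ensemble()].
#' @param loop a [loop_definition()].
#' @param mode `"calpha"` (default) returns one C-alpha index per residue;
#'   `"heavy"` returns all non-hydrogen atoms of the loop residues.
#' @return integer vector of atom indices, ordered by residue id.  A residue
#'   that cannot be resolved is an error, never an empty selection.
#' @export
select_loop <- function(ensemble, loop, mode = c("calpha", "heavy")) {
  mode <- match.arg(mode)
  at <- ensemble$atoms
  in_chain <- if (is.na(loop$chain)) rep(TRUE, nrow(at)) else
    at$chain == loop$chain
  idx <- integer(0)
  for (r in loop$residues) {
    sel <- which(at$resno == r & in_chain)
    if (mode == "calpha") {
      sel <- sel[at$elety[sel] == "CA"]
      if (length(sel) != 1L)
        stop(sprintf("loop '%s': residue %d (chain %s) has no unique CA atom",
                     loop$name, r, ifelse(is.na(loop$chain), "any",
                                          loop$chain)), call. = FALSE)
    } else {
      sel <- sel[!is_hydrogen(at$elety[sel])]
      if (length(sel) == 0L)
        stop(sprintf("loop '%s': residue %d (chain %s) not present",
                     loop$name, r, ifelse(is.na(loop$chain), "any",
                                          loop$chain)), call. = FALSE)
    }
    idx <- c(idx, sel)
  }
  idx
}

#' Read a structure or trajectory into a coordinate ensemble
#'
#' Accepts multi-model PDB files (via bio3d) and the package's own
#' plain-text array container (see [write_coords_csv()]), dispatching on the
#' file extension.
#'
#' @param path input file (`.pdb` or `.csv`).
#' @param model_index optional model/frame to extract (1-based).
#' @return a [coord_ensemble()].  Heteroatoms are retained with `het = TRUE`;
#'   residues represented only by their C-alpha are flagged `ca_only`.
#' @export
load_structure <- function(path, model_index = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  ens <- if (ext == "csv") {
    read_coords_csv(path)
  } else {
    pdb <- tryCatch(
      bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
      error = function(e) stop("failed to parse PDB file '", path, "': ",
                               conditionMessage(e), call. = FALSE))
    if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
      stop("failed to parse PDB file '", path, "': no atom records",
           call. = FALSE)
    atoms <- data.frame(elety = pdb$atom$elety, resid = pdb$atom$resid,
                        resno = pdb$atom$resno, chain = pdb$atom$chain,
                        het = pdb$atom$type == "HETATM",
                        stringsAsFactors = FALSE)
    atoms$chain[is.na(atoms$chain)] <- "A"
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
    coord_ensemble(xyz, atoms)
  }
  if (!is.null(model_index)) {
    if (model_index < 1L || model_index > n_frames(ens))
      stop(sprintf("model %d not present (file has %d)", model_index,
                   n_frames(ens)), call. = FALSE)
    ens$xyz <- ens$xyz[model_index, , drop = FALSE]
  }
  ens
}

#' Write an ensemble as a (multi-model) PDB file
#'
#' @param ensemble a [coord_ensemble()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_structure <- function(ensemble, path) {
  at <- ensemble$atoms
  bio3d::write.pdb(file = path, xyz = ensemble$xyz, type =
                     ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid, elety = at$elety,
                   chain = at$chain)
  invisible(path)
}

#' Plain-text array container for coordinate ensembles
#'
#' Long-format CSV with one row per (frame, atom) and columns
#' `frame,elety,resid,resno,chain,het,mass,x,y,z`.  Round trips exactly at
#' the printed precision (6 decimals, tighter than PDB's 3).
#'
#' @param ensemble a [coord_ensemble()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_coords_csv <- function(ensemble, path) {
  nf <- n_frames(ensemble)
  at <- ensemble$atoms
  m <- matrix(t(ensemble$xyz), ncol = 3, byrow = TRUE)  # frame-major atoms
  df <- data.frame(frame = rep(seq_len(nf), each = nrow(at)),
                   elety = rep(at$elety, nf), resid = rep(at$resid, nf),
                   resno = rep(at$resno, nf), chain = rep(at$chain, nf),
                   het = rep(at$het, nf), mass = rep(at$mass, nf),
                   x = round(m[, 1], 6), y = round(m[, 2], 6),
                   z = round(m[, 3], 6))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coords_csv
#' @return `read_coords_csv()` returns a [coord_ensemble()].
#' @export
read_coords_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "elety", "resid", "resno", "chain", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("coordinate CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  frames <- sort(unique(df$frame))
  first <- df[df$frame == frames[1], ]
  xyz <- t(vapply(frames, function(f) {
    sub <- df[df$frame == f, ]
    as.vector(t(as.matrix(sub[, c("x", "y", "z")])))
  }, numeric(3 * nrow(first))))
  if (length(frames) == 1L) xyz <- matrix(xyz, nrow = 1)
  atoms <- data.frame(elety = as.character(first$elety),
                      resid = as.character(first$resid),
                      resno = first$resno,
                      chain = as.character(first$chain),
                      stringsAsFactors = FALSE)
  if (!is.null(first$het)) atoms$het <- as.logical(first$het)
  if (!is.null(first$mass)) atoms$mass <- first$mass
  coord_ensemble(xyz, atoms)
}

# single C-alpha bead table for synthetic ensembles
bead_atom_table <- function(n_res, chain = "A") {
  data.frame(elety = rep("CA", n_res), resid = rep("ALA", n_res),
             resno = seq_len(n_res), chain = rep(chain, n_res),
             stringsAsFactors = FALSE)
}
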