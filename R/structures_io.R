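#' Percent sequence identity between two protein sequences
#'
#' Identity is `100 * identical columns / aligned columns`, where the
#' denominator excludes terminal-gap columns and (by default) counts
#' internal gap columns as mismatches — the convention most aligners report
#' as "identity over alignment length".  In `given_alignment` mode the two
#' strings are used verbatim (they must be equal length, gaps as `-`), so
#' an external aligner's output reproduces that aligner's identity exactly.
#' In `global_alignment` mode an internal Needleman-Wunsch global aligner is
#' used (BLOSUM62, affine gaps, defaults gap open 10 / extend 0.5).
#'
#' @param seq_a,seq_b amino-acid strings (standard alphabet, `X` tolerated;
#'   `-` only in `given_alignment` mode).
#' @param mode `"global_alignment"` or `"given_alignment"`.
#' @param gap_open,gap_extend affine gap penalties for the internal aligner.
#' @param internal_gaps `"mismatch"` (default) keeps internal gap columns in
#'   the denominator; `"exclude"` drops every gapped column.
#' @return percent identity (0..100).
#' @examples
#' pairwise_identity("ACDEF", "ACDEY", mode = "given_alignment")  # 80
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              mode = c("global_alignment",
                                       "given_alignment"),
                              gap_open = 10, gap_extend = 0.5,
                              internal_gaps = c("mismatch", "exclude")) {
  mode <- match.arg(mode)
  internal_gaps <- match.arg(internal_gaps)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty", call. = FALSE)
  ok <- "^[ACDEFGHIKLMNPQRSTVWYX-]+$"
  if (!grepl(ok, seq_a) || !grepl(ok, seq_b))
    stop("sequences contain characters outside the amino-acid alphabet",
         call. = FALSE)
  if (mode == "given_alignment") {
    if (nchar(seq_a) != nchar(seq_b))
      stop(sprintf("given alignment length mismatch (%d vs %d)",
                   nchar(seq_a), nchar(seq_b)), call. = FALSE)
    a <- strsplit(seq_a, "")[[1]]
    b <- strsplit(seq_b, "")[[1]]
  } else {
    if (grepl("-", seq_a, fixed = TRUE) || grepl("-", seq_b, fixed = TRUE))
      stop("ungapped sequences required in global_alignment mode",
           call. = FALSE)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      substitutionMatrix = blosum62_matrix(), gapOpening = gap_open,
      gapExtension = gap_extend, type = "global")
    a <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
    b <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  }
  aligned_identity(a, b, internal_gaps)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# identity over aligned column vectors, excluding terminal-gap columns
aligned_identity <- function(a, b, internal_gaps = "mismatch") {
  n <- length(a)
  lead <- function(x) { r <- rle(x == "-"); if (r$values[1]) r$lengths[1] else 0L }
  from <- 1L + max(lead(a), lead(b))
  to <- n - max(lead(rev(a)), lead(rev(b)))
  if (from > to) return(0)
  a <- a[from:to]; b <- b[from:to]
  keep <- if (internal_gaps == "exclude") a != "-" & b != "-" else
    !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) return(0)
  100 * sum(a == b & a != "-") / length(a)
}

#' One-to-one residue correspondence between two proteins
#'
#' @param pairs data.frame (or 2-column matrix) of aligned residue ids:
#'   column 1 in protein A, column 2 in protein B.  The mapping must be
#'   one-to-one; pairs are stored ordered by A.
#' @param coverage fraction of protein A mapped (computed by
#'   [build_alignment_map()]; defaults to `NA`).
#' @param ids optional character vector naming the two proteins.
#' @return an object of class `alignment_map` with a `pairs` data.frame
#'   (`res_a`, `res_b`).
#' @export
alignment_map <- function(pairs, coverage = NA_real_, ids = c("A", "B")) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) != 2L) stop("'pairs' needs two columns", call. = FALSE)
  names(pairs) <- c("res_a", "res_b")
  pairs$res_a <- as.integer(pairs$res_a)
  pairs$res_b <- as.integer(pairs$res_b)
  if (anyDuplicated(pairs$res_a) || anyDuplicated(pairs$res_b))
    stop("alignment map must be one-to-one", call. = FALSE)
  pairs <- pairs[order(pairs$res_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, coverage = coverage, ids = ids),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf("alignment_map %s -> %s: %d pairs, coverage %.3f\n",
              x$ids[1], x$ids[2], nrow(x$pairs), x$coverage))
  invisible(x)
}

# translate protein-A residue ids through a map (NA where unmapped)
map_residues <- function(map, res_a) {
  if (is.null(map)) return(res_a)
  stopifnot(inherits(map, "alignment_map"))
  map$pairs$res_b[match(res_a, map$pairs$res_a)]
}

# invert an alignment map
invert_map <- function(map) {
  alignment_map(map$pairs[, c("res_b", "res_a")], coverage = NA_real_,
                ids = rev(map$ids))
}

#' Build a residue correspondence map from an aligned FASTA file
#'
#' Scans the alignment columns of two named records; every column where
#' both sequences carry a residue yields a pair.  Residue ids are the
#' 1-based ungapped positions offset by the given start numbers (author
#' numbering support).
#'
#' @param alignment path to an aligned FASTA file, or a named character
#'   vector of gapped sequences.
#' @param id_a,id_b record names (first whitespace-delimited token of the
#'   FASTA header).
#' @param offset_a,offset_b author residue number of the first residue of
#'   each sequence (default 1).
#' @return an [alignment_map()]; coverage is the fraction of A's residues
#'   mapped.  Zero shared columns yields an empty map with a warning.
#' @export
build_alignment_map <- function(alignment, id_a, id_b,
                                offset_a = 1L, offset_b = 1L) {
  seqs <- if (is.character(alignment) && !is.null(names(alignment)))
    alignment
  else if (is.character(alignment) && length(alignment) == 1 &&
           file.exists(alignment)) {
    s <- Biostrings::readAAStringSet(alignment)
    stats::setNames(as.character(s),
                    vapply(strsplit(names(s), "\\s+"), `[`, "", 1))
  } else stop("'alignment' must be a FASTA path or named character vector",
              call. = FALSE)
  for (id in c(id_a, id_b))
    if (!id %in% names(seqs))
      stop("sequence id '", id, "' not found in alignment", call. = FALSE)
  a <- strsplit(toupper(seqs[[id_a]]), "")[[1]]
  b <- strsplit(toupper(seqs[[id_b]]), "")[[1]]
  if (length(a) != length(b))
    stop("aligned sequences differ in length — not a valid alignment",
         call. = FALSE)
  pos_a <- cumsum(a != "-")
  pos_b <- cumsum(b != "-")
  both <- a != "-" & b != "-"
  n_a <- sum(a != "-")
  if (!any(both)) {
    warning("alignment shares no columns between '", id_a, "' and '",
            id_b, "'")
    return(alignment_map(data.frame(res_a = integer(0), res_b = integer(0)),
                         coverage = 0, ids = c(id_a, id_b)))
  }
  pairs <- data.frame(res_a = pos_a[both] + offset_a - 1L,
                      res_b = pos_b[both] + offset_b - 1L)
  alignment_map(pairs, coverage = nrow(pairs) / n_a, ids = c(id_a, id_b))
}

#' Simulation plan container and accounting
#'
#' A simulation plan lists, per system, how many chemical/conformational
#' states were simulated, how many replicas per state, and the replica
#' length in microseconds.  [plan_accounting()] reports per-entry and
#' cumulative totals using integer nanosecond arithmetic, so printed totals
#' carry no floating-point drift.
#'
#' @param entries data.frame with columns `system`, `n_states`,
#'   `n_replicas`, `length_us`.
#' @return an object of class `simulation_plan`.
#' @export
simulation_plan <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("system", "n_states", "n_replicas", "length_us")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("plan lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(entries) > 0) {
    if (any(entries$n_states <= 0) || any(entries$n_replicas <= 0))
      stop("state and replica counts must be positive", call. = FALSE)
    if (any(entries$length_us <= 0))
      stop("replica lengths must be > 0", call. = FALSE)
  }
  structure(list(entries = entries), class = "simulation_plan")
}

#' @rdname simulation_plan
#' @param path CSV file with header `system,n_states,n_replicas,length_us`.
#' @export
read_plan_csv <- function(path) {
  simulation_plan(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname simulation_plan
#' @param plan a `simulation_plan`.
#' @return `plan_accounting()` returns a list with `per_entry` (the entries
#'   plus a `total_us` column) and `cumulative_us`.
#' @export
plan_accounting <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  e <- plan$entries
  if (nrow(e) == 0)
    return(list(per_entry = cbind(e, total_us = numeric(0)),
                cumulative_us = 0))
  ns <- as.integer(round(e$length_us * 1000))  # exact at printed precision
  tot_ns <- as.numeric(e$n_states) * e$n_replicas * ns
  e$total_us <- tot_ns / 1000
  list(per_entry = e, cumulative_us = sum(tot_ns) / 1000)
}

#' Reference MD campaign for the SHP-1/SHP-2/PTP1B/YopH loop-dynamics study
#'
#' Eight catalytic-domain systems (four wild-type PTPs plus four oncogenic
#' variants), each simulated in four states (WPD-loop open/closed crossed
#' with unliganded/phosphoenzyme intermediate) with 8 replicas of 1.5 us,
#' plus three full-length SH2-containing systems (SHP-1 autoinhibited,
#' SHP-1 SH2-open, SHP-2 autoinhibited) with 5 replicas of 1 us each.
#'
#' @return a [simulation_plan()].
#' @export
default_study_plan <- function() {
  cat_dom <- c("PTP1B", "SHP-1", "SHP-2", "YopH",
               "SHP-1-A323T", "SHP-1-T501M", "SHP-2-N308D", "SHP-2-Q506P")
  full_len <- c("SHP-1-FL-autoinhibited", "SHP-1-FL-open",
                "SHP-2-FL-autoinhibited")
  simulation_plan(rbind(
    data.frame(system = cat_dom, n_states = 4L, n_replicas = 8L,
               length_us = 1.5, stringsAsFactors = FALSE),
    data.frame(system = full_len, n_states = 1L, n_replicas = 5L,
               length_us = 1.0, stringsAsFactors = FALSE)))
}

#' EVB sampling-time accounting
#'
#' @param n_windows mapping windows per trajectory.
#' @param window_ps window length in picoseconds.
#' @param n_trajectories independent EVB trajectories per system.
#' @param n_systems number of systems.
#' @return list with `ns_per_trajectory`, `ns_per_system` and
#'   `cumulative_us` (exact picosecond arithmetic).
#' @export
evb_accounting <- function(n_windows, window_ps, n_trajectories,
                           n_systems) {
  stopifnot(n_windows > 0, window_ps > 0, n_trajectories > 0,
            n_systems > 0)
  ps_traj <- as.numeric(n_windows) * window_ps
  list(ns_per_trajectory = ps_traj / 1000,
       ns_per_system = ps_traj * n_trajectories / 1000,
       cumulative_us = ps_traj * n_trajectories * n_systems / 1e6)
}
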