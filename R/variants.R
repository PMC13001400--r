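#' Read a variant table from a minimal COSMIC-style CSV export
#'
#' Expected header `gene,position,wt_aa,alt_aa,count` (`count` optional,
#' defaults to 1).  Positions must be positive integers and amino acids in
#' the standard one-letter alphabet.  Numbering provenance is the caller's
#' responsibility: the variant table and the structure it is overlaid on
#' must share a numbering, which [classify_vs_spm()] can verify through
#' wild-type residue-name agreement.
#'
#' @param path CSV file.
#' @return a `variant_table` data.frame.
#' @export
read_variant_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "position", "wt_aa", "alt_aa")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(df$count)) df$count <- 1L
  if (nrow(df) > 0) {
    if (any(df$position <= 0 | df$position != round(df$position)))
      stop("positions must be positive integers", call. = FALSE)
    aa_ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]$", c(df$wt_aa, df$alt_aa))
    if (!all(aa_ok))
      stop("amino acids must use the standard one-letter alphabet",
           call. = FALSE)
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Write a variant table as CSV (deterministic byte layout)
#'
#' @param table a `variant_table` (e.g. from [gen_variant_table()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variant_csv <- function(table, path) {
  df <- as.data.frame(table)[, c("gene", "position", "wt_aa", "alt_aa",
                                 "count")]
  write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Oncogenic hotspot positions
#'
#' A position is a hotspot when it carries at least `min_distinct`
#' *distinct* amino-acid substitutions (distinct `alt_aa` values — report
#' counts are metadata, not evidence).  The default of 2 follows the usual
#' two-or-more-reported-substitutions selection rule.
#'
#' @param table a `variant_table`.
#' @param min_distinct minimum number of distinct substitutions.
#' @return sorted integer vector of hotspot positions.
#' @export
hotspot_positions <- function(table, min_distinct = 2L) {
  df <- as.data.frame(table)
  if (nrow(df) == 0) return(integer(0))
  n_distinct <- tapply(df$alt_aa, df$position,
                       function(a) length(unique(a)))
  sort(as.integer(names(n_distinct)[n_distinct >= min_distinct]))
}

#' Classify hotspot positions against an SPM by structural proximity
#'
#' Each position is `on_spm` if it is itself an SPM residue (distance 0 by
#' convention); otherwise `near_spm` if the minimum heavy-atom distance to
#' any SPM residue is strictly below `cutoff`; otherwise `far_spm`
#' (distance >= cutoff).  Hydrogens are excluded by default because the
#' crystal structures typically used for such overlays lack them.  A
#' position absent from the structure is reported `unclassifiable`, never
#' silently dropped.
#'
#' @param positions integer vector of residue positions (e.g. from
#'   [hotspot_positions()]).
#' @param spm a [shortest_path_map()] result.
#' @param structure a [coord_ensemble()]; the first frame is used.
#' @param cutoff near/far split (Angstrom, default 4.0, strict `<`).
#' @param heavy_only exclude hydrogens from the distance scan.
#' @param frame structure frame to measure on.
#' @return data.frame `position,class,distance_A,nearest_spm_residue`.
#' @export
classify_vs_spm <- function(positions, spm, structure, cutoff = 4.0,
                            heavy_only = TRUE, frame = 1L) {
  stopifnot(inherits(spm, "spm_result"))
  at <- structure$atoms
  xyz <- frame_coords(structure, frame)
  keep <- if (heavy_only) !is_hydrogen(at$elety) else rep(TRUE, nrow(at))
  spm_res <- spm$residues
  spm_atoms <- which(keep & at$resno %in% spm_res)
  out <- lapply(unique(as.integer(positions)), function(pos) {
    if (pos %in% spm_res)
      return(data.frame(position = pos, class = "on_spm", distance_A = 0,
                        nearest_spm_residue = pos))
    pa <- which(keep & at$resno == pos)
    if (length(pa) == 0 || length(spm_atoms) == 0)
      return(data.frame(position = pos, class = "unclassifiable",
                        distance_A = NA_real_,
                        nearest_spm_residue = NA_integer_))
    dd <- as.matrix(dist(rbind(xyz[pa, , drop = FALSE],
                               xyz[spm_atoms, , drop = FALSE])))
    block <- dd[seq_along(pa), length(pa) + seq_along(spm_atoms),
                drop = FALSE]
    j <- which(block == min(block), arr.ind = TRUE)[1, 2]
    data.frame(position = pos,
               class = if (min(block) < cutoff) "near_spm" else "far_spm",
               distance_A = min(block),
               nearest_spm_residue = at$resno[spm_atoms[j]])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
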