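#' EVB lambda-window energy series
#'
#' Container for per-window, per-frame diabatic energies from empirical
#' valence bond mapping simulations: for each mapping parameter `lambda_m`
#' the sampled frames record the two diabatic energies `(e1, e2)` in
#' kcal/mol.  The diabatic coupling `H12` is constant
#' (geometry-independent) and supplied per system, never baked in.
#'
#' @param lambdas strictly increasing mapping parameters spanning `[0, 1]`.
#' @param frames list (one element per window) of data.frames with columns
#'   `e1`, `e2`; every window must be non-empty.
#' @param H12 constant diabatic coupling (kcal/mol).
#' @param temperature simulation temperature (Kelvin).
#' @return an object of class `evb_window_series`.
#' @export
evb_window_series <- function(lambdas, frames, H12 = 0, temperature = 300) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 2 || any(diff(lambdas) <= 0) ||
      lambdas[1] != 0 || lambdas[length(lambdas)] != 1)
    stop("'lambdas' must be strictly increasing from 0 to 1", call. = FALSE)
  if (length(frames) != length(lambdas))
    stop("need one frame table per window", call. = FALSE)
  for (m in seq_along(frames)) {
    f <- frames[[m]]
    if (!is.data.frame(f) || nrow(f) == 0 ||
        !all(c("e1", "e2") %in% names(f)))
      stop(sprintf("window %d is empty or lacks e1/e2 columns", m),
           call. = FALSE)
  }
  assert_scalar_num(temperature, "temperature", positive = TRUE)
  structure(list(lambdas = lambdas, frames = frames, H12 = H12,
                 temperature = temperature),
            class = "evb_window_series")
}

#' @export
print.evb_window_series <- function(x, ...) {
  cat(sprintf(
    "evb_window_series: %d windows, %d frames/window, H12 = %.3g, T = %g K\n",
    length(x$lambdas), nrow(x$frames[[1]]), x$H12, x$temperature))
  invisible(x)
}

#' Read / write EVB window energies as CSV
#'
#' Long format with header `lambda,frame,e1,e2`.
#'
#' @param series an [evb_window_series()].
#' @param path file path.
#' @param H12,temperature series metadata for [read_evb_csv()].
#' @return `write_evb_csv()` the path invisibly; `read_evb_csv()` an
#'   [evb_window_series()].
#' @export
write_evb_csv <- function(series, path) {
  rows <- lapply(seq_along(series$lambdas), function(m) {
    f <- series$frames[[m]]
    data.frame(lambda = series$lambdas[m], frame = seq_len(nrow(f)),
               e1 = f$e1, e2 = f$e2)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_evb_csv
#' @export
read_evb_csv <- function(path, H12 = 0, temperature = 300) {
  df <- read.csv(path)
  need <- c("lambda", "frame", "e1", "e2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("EVB CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ls <- sort(unique(df$lambda))
  frames <- lapply(ls, function(l) {
    sub <- df[df$lambda == l, ]
    sub[order(sub$frame), c("e1", "e2")]
  })
  evb_window_series(ls, frames, H12 = H12, temperature = temperature)
}

#' Mapping-potential energies of one window
#'
#' `E_m = (1 - lambda_m) e1 + lambda_m e2` per frame.
#'
#' @param series an [evb_window_series()].
#' @param m window index (1-based).
#' @return numeric vector of per-frame mapping energies.
#' @export
mapping_energies <- function(series, m) {
  stopifnot(inherits(series, "evb_window_series"))
  if (m < 1 || m > length(series$lambdas))
    stop(sprintf("window %d does not exist (1..%d)", m,
                 length(series$lambdas)), call. = FALSE)
  l <- series$lambdas[m]
  f <- series$frames[[m]]
  (1 - l) * f$e1 + l * f$e2
}

#' Free-energy increments along the mapping coordinate
#'
#' Forward exponential (free-energy-perturbation) averaging between
#' adjacent windows, the classic EVB mapping estimator:
#' `dG(lambda_{m+1}) = dG(lambda_m) - kT log < exp(-(E_{m+1} - E_m)/kT) >_m`
#' accumulated from `dG(lambda_1) = 0`.  A warning is issued when the
#' effective sample size of the exponential average drops below 10
#' (adjacent windows barely overlap).  The bidirectional variant averages
#' the forward estimate with the sign-flipped reverse estimate of each
#' step, a cheap hysteresis diagnostic.
#'
#' @param series an [evb_window_series()].
#' @param method `"forward"` (default) or `"bidirectional"`.
#' @return numeric vector `dG(lambda_m)` (kcal/mol), one per window,
#'   starting at 0.
#' @export
fep_increments <- function(series, method = c("forward", "bidirectional")) {
  stopifnot(inherits(series, "evb_window_series"))
  method <- match.arg(method)
  kt <- boltzmann_kt(series$temperature)
  nl <- length(series$lambdas)
  dg <- numeric(nl)
  for (m in seq_len(nl - 1)) {
    dl <- series$lambdas[m + 1] - series$lambdas[m]
    f_m <- series$frames[[m]]
    de_fwd <- dl * (f_m$e2 - f_m$e1)       # E_{m+1} - E_m on window m
    ess <- ess_weights(-de_fwd / kt)
    if (ess < 10 && ess < 0.5 * length(de_fwd))
      warning(sprintf(
        "window %d -> %d: effective sample size %.1f < 10; windows overlap poorly",
        m, m + 1, ess))
    inc <- -kt * log_mean_exp(-de_fwd / kt)
    if (method == "bidirectional") {
      f_n <- series$frames[[m + 1]]
      de_rev <- -dl * (f_n$e2 - f_n$e1)    # E_m - E_{m+1} on window m+1
      inc_rev <- -kt * log_mean_exp(-de_rev / kt)
      inc <- 0.5 * (inc - inc_rev)
    }
    dg[m + 1] <- dg[m] + inc
  }
  dg
}

# EVB ground-state (lower adiabatic) energy from the two diabats
evb_ground_energy <- function(e1, e2, H12) {
  0.5 * (e1 + e2) - 0.5 * sqrt((e1 - e2)^2 + 4 * H12^2)
}

#' Free-energy profile along the energy-gap coordinate
#'
#' Assembles the EVB free-energy profile by binning frames on the gap
#' coordinate `x = e1 - e2` and umbrella-correcting each window's
#' contribution onto the ground-state surface:
#' `dg(b) <- dG(lambda_m) - kT log < exp(-(E_g - E_m)/kT) >_{m,b}` with
#' `E_g = (e1 + e2)/2 - sqrt((e1 - e2)^2 + 4 H12^2)/2`.  Multi-window
#' contributions to one bin are combined by sample-count-weighted
#' averaging; the profile is shifted so the reactant-state minimum is 0.
#'
#' Stationary points are read off the 3-bin moving-average smoothed
#' profile: the reactant state (RS) is the outermost local minimum on the
#' low-gap side (sampled by low-lambda windows), the product state (PS)
#' the outermost minimum on the high-gap side, and the transition state
#' (TS) the maximum between them.
#'
#' @param series an [evb_window_series()].
#' @param dg_lambda window free energies from [fep_increments()] (computed
#'   when omitted).
#' @param n_bins number of equal-width gap bins (default 50).
#' @param trim fraction of the gap distribution trimmed at each tail when
#'   choosing the bin range (default 0.005).
#' @return an object of class `free_energy_profile`: data.frame `profile`
#'   (`x`, `dg`, `count`), plus `dg_act`, `dg_rxn`, indices `i_rs`, `i_ts`,
#'   `i_ps`, and the binning metadata.
#' @export
gap_profile <- function(series, dg_lambda = NULL, n_bins = 50,
                        trim = 0.005) {
  stopifnot(inherits(series, "evb_window_series"))
  dg_lambda <- dg_lambda %||% fep_increments(series)
  kt <- boltzmann_kt(series$temperature)
  gap_all <- unlist(lapply(series$frames, function(f) f$e1 - f$e2))
  qr_ <- quantile(gap_all, c(trim, 1 - trim), names = FALSE)
  if (diff(qr_) <= 0)
    stop("gap coordinate is degenerate; no profile can be built",
         call. = FALSE)
  edges <- seq(qr_[1], qr_[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  num <- numeric(n_bins)    # count-weighted sum of window estimates
  cnt <- integer(n_bins)
  for (m in seq_along(series$lambdas)) {
    f <- series$frames[[m]]
    gap <- f$e1 - f$e2
    em <- (1 - series$lambdas[m]) * f$e1 + series$lambdas[m] * f$e2
    eg <- evb_ground_energy(f$e1, f$e2, series$H12)
    b <- findInterval(gap, edges, rightmost.closed = TRUE)
    inside <- b >= 1 & b <= n_bins
    for (bi in unique(b[inside])) {
      sel <- inside & b == bi
      nb <- sum(sel)
      est <- dg_lambda[m] - kt * log_mean_exp(-(eg[sel] - em[sel]) / kt)
      num[bi] <- num[bi] + nb * est
      cnt[bi] <- cnt[bi] + nb
    }
  }
  occupied <- cnt > 0
  if (sum(occupied) < 3)
    stop("fewer than 3 occupied gap bins; cannot locate stationary points",
         call. = FALSE)
  dg <- ifelse(occupied, num / pmax(cnt, 1L), NA_real_)
  first <- min(which(occupied)); last <- max(which(occupied))
  if (anyNA(dg[first:last])) {
    warning("empty interior gap bin(s) interpolated")
    dg[first:last] <- approx(centers[occupied], dg[occupied],
                             xout = centers[first:last])$y
  }
  idx <- first:last
  sm <- smooth_profile(dg[idx], 3)
  minima <- local_minima(sm)
  if (length(minima) >= 2) {
    i_rs <- idx[minima[1]]          # low-gap side: diabat 1 dominant
    i_ps <- idx[minima[length(minima)]]
  } else {
    i_rs <- idx[1]; i_ps <- idx[length(idx)]
  }
  between <- seq(min(i_rs, i_ps), max(i_rs, i_ps))
  i_ts <- between[which.max(dg[between])]
  # refine the RS/PS minima on the raw profile near the smoothed minima
  i_rs <- refine_extremum(dg, i_rs, idx, maximum = FALSE)
  i_ps <- refine_extremum(dg, i_ps, idx, maximum = FALSE)
  dg <- dg - dg[i_rs]
  structure(list(profile = data.frame(x = centers, dg = dg, count = cnt),
                 dg_act = dg[i_ts] - dg[i_rs], dg_rxn = dg[i_ps] - dg[i_rs],
                 i_rs = i_rs, i_ts = i_ts, i_ps = i_ps,
                 n_bins = n_bins, trim = trim,
                 temperature = series$temperature, H12 = series$H12),
            class = "free_energy_profile")
}

smooth_profile <- function(y, w = 3) {
  half <- (w - 1) %/% 2
  vapply(seq_along(y), function(i) {
    j <- max(1, i - half):min(length(y), i + half)
    mean(y[j])
  }, numeric(1))
}

local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(which.min(y))
  out <- integer(0)
  if (y[1] < y[2]) out <- c(out, 1L)
  for (i in 2:(n - 1))
    if (y[i] <= y[i - 1] && y[i] <= y[i + 1] &&
        (y[i] < y[i - 1] || y[i] < y[i + 1]))
      out <- c(out, i)
  if (y[n] < y[n - 1]) out <- c(out, n)
  if (length(out) == 0) out <- which.min(y)
  out
}

# walk downhill (or uphill) from a smoothed extremum to the raw one
refine_extremum <- function(dg, i, idx, maximum = FALSE) {
  rng <- range(idx)
  cmp <- if (maximum) `>` else `<`
  repeat {
    moved <- FALSE
    for (step in c(-1L, 1L)) {
      j <- i + step
      if (j >= rng[1] && j <= rng[2] && !is.na(dg[j]) && cmp(dg[j], dg[i])) {
        i <- j; moved <- TRUE
      }
    }
    if (!moved) return(i)
  }
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf(
    "free_energy_profile: dG_act = %.2f, dG_rxn = %.2f kcal/mol (%d bins)\n",
    x$dg_act, x$dg_rxn, x$n_bins))
  invisible(x)
}

#' Replicate barrier statistics
#'
#' @param replicates named list of numeric vectors: per-system activation
#'   free energies from independent EVB trajectories (>= 2 each).
#' @return data.frame `system,mean,sem,n`.
#' @export
barrier_stats <- function(replicates) {
  check_replicates(replicates)
  out <- data.frame(
    system = names(replicates),
    mean = vapply(replicates, mean, numeric(1)),
    sem = vapply(replicates, function(v) sd(v) / sqrt(length(v)),
                 numeric(1)),
    n = vapply(replicates, length, integer(1)))
  rownames(out) <- NULL
  out
}

check_replicates <- function(replicates) {
  if (!is.list(replicates) || is.null(names(replicates)) ||
      any(names(replicates) == ""))
    stop("'replicates' must be a named list of numeric vectors",
         call. = FALSE)
  short <- names(replicates)[vapply(replicates, length, 1L) < 2]
  if (length(short))
    stop("system(s) with fewer than 2 replicates: ",
         paste(short, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' One-way ANOVA with Tukey HSD post-hoc comparison
#'
#' Standard one-way ANOVA across systems followed by Tukey's Honestly
#' Significant Difference test (studentized-range distribution) on all
#' pairs, with the usual significance stars (`*` p < 0.05, `**` p < 0.01).
#' Unequal group variances are noted, not treated as an error.
#'
#' @param replicates named list of per-system barrier replicates
#'   (>= 2 systems, >= 2 values each).
#' @return list with `f` (ANOVA F statistic), `p` (ANOVA p-value),
#'   `tukey` (data.frame `pair,diff,lwr,upr,p_adj,stars`) and
#'   `variance_note`.
#' @export
anova_tukey <- function(replicates) {
  check_replicates(replicates)
  if (length(replicates) < 2)
    stop("need at least 2 systems", call. = FALSE)
  df <- data.frame(
    value = unlist(replicates, use.names = FALSE),
    system = factor(rep(names(replicates),
                        vapply(replicates, length, 1L))))
  fit <- aov(value ~ system, data = df)
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$system
  stars <- ifelse(tk[, "p adj"] < 0.01, "**",
                  ifelse(tk[, "p adj"] < 0.05, "*", ""))
  vars <- vapply(replicates, var, numeric(1))
  note <- if (max(vars) / max(min(vars), .Machine$double.eps) > 4)
    "group variances differ by more than 4-fold" else "group variances comparable"
  list(f = unname(f), p = unname(p),
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], stars = stars,
                          row.names = NULL),
       variance_note = note)
}

#' Activation free energy from a rate constant (transition state theory)
#'
#' `dG_act = RT log(k_B T / (h k_cat))` with unit transmission coefficient.
#'
#' @param kcat rate constant (s^-1, > 0).
#' @param temperature Kelvin (> 0).
#' @return activation free energy in kcal/mol.
#' @examples
#' tst_barrier(1, 300)    # ~17.4 kcal/mol
#' @export
tst_barrier <- function(kcat, temperature = 300) {
  if (any(kcat <= 0)) stop("'kcat' must be > 0", call. = FALSE)
  assert_scalar_num(temperature, "temperature", positive = TRUE)
  .R_KCAL * temperature * log(.KB_SI * temperature / (.H_SI * kcat))
}

#' Hierarchical clustering of reactive geometries
#'
#' Agglomerative clustering (average linkage by default) on the pairwise
#' RMSD of selected heavy atoms, each pair optimally superposed before the
#' RMSD is taken.  The representative of a cluster is its medoid: the
#' frame with the smallest mean RMSD to the other members.
#'
#' @param ensemble a [coord_ensemble()] with >= 2 frames.
#' @param selection atom indices to cluster on (non-empty; e.g. the
#'   reacting heavy atoms).
#' @param n_clusters number of clusters to cut, or `NULL` to use `height`.
#' @param height RMSD cut height when `n_clusters` is `NULL`.
#' @param linkage linkage method for [stats::hclust()].
#' @return list with `labels` (per-frame cluster id), `representatives`
#'   (frame index per cluster) and `rmsd` (the pairwise matrix).
#' @export
cluster_reactive_geometries <- function(ensemble, selection,
                                        n_clusters = NULL, height = NULL,
                                        linkage = "average") {
  if (n_frames(ensemble) < 2)
    stop("clustering requires at least 2 frames", call. = FALSE)
  if (length(selection) == 0)
    stop("'selection' must be non-empty", call. = FALSE)
  nf <- n_frames(ensemble)
  cols <- atoms2xyz(selection)
  rmat <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      r <- bio3d::rmsd(ensemble$xyz[i, cols], ensemble$xyz[j, cols],
                       fit = TRUE)
      rmat[i, j] <- rmat[j, i] <- r
    }
  }
  if (is.null(n_clusters) && is.null(height))
    n_clusters <- 1L
  hc <- hclust(as.dist(rmat), method = linkage)
  labels <- if (!is.null(n_clusters)) cutree(hc, k = n_clusters)
  else cutree(hc, h = height)
  reps <- vapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    members[which.min(rowMeans(rmat[members, members, drop = FALSE]))]
  }, integer(1))
  list(labels = unname(labels), representatives = reps, rmsd = rmat)
}

#' Write a free-energy profile as CSV plus JSON summary
#'
#' @param profile a [gap_profile()] result.
#' @param path CSV output path; a `.json` summary is written alongside.
#' @return the CSV path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(profile$profile, path, row.names = FALSE, quote = FALSE)
  summary_path <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(dg_act = profile$dg_act, dg_rxn = profile$dg_rxn,
         n_bins = profile$n_bins, trim = profile$trim,
         temperature = profile$temperature, H12 = profile$H12),
    summary_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
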