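#' Specification of a Gaussian positional ensemble
#'
#' Describes per-residue C-alpha bead positions fluctuating about a mean
#' with a prescribed covariance over displacement components, the synthetic
#' stand-in for an equilibrium MD ensemble.
#'
#' @param mean_coordinates N x 3 matrix of mean bead positions (Angstrom).
#' @param covariance symmetric positive-semidefinite 3N x 3N matrix over the
#'   displacement components ordered `(x1, y1, z1, x2, ...)` (Angstrom^2);
#'   alternatively a single scalar `s2` meaning isotropic `s2 * I`.
#' @param n_frames number of frames to draw (>= 2).
#' @param seed integer seed; generation is bit-reproducible and never
#'   touches the global RNG stream.
#' @return an object of class `gaussian_ensemble_spec`.
#' @export
gaussian_ensemble_spec <- function(mean_coordinates, covariance, n_frames,
                                   seed) {
  mean_coordinates <- as.matrix(mean_coordinates)
  if (ncol(mean_coordinates) != 3L)
    stop("'mean_coordinates' must be an N x 3 matrix", call. = FALSE)
  d <- 3L * nrow(mean_coordinates)
  if (length(covariance) == 1L)
    covariance <- diag(as.numeric(covariance), d)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(dim(covariance), c(d, d), check.attributes = FALSE)))
    stop(sprintf("covariance must be %d x %d", d, d), call. = FALSE)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance matrix is not symmetric", call. = FALSE)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf(
      "covariance is not positive semidefinite (eigenvalue %.3e < -1e-8)",
      min(ev)), call. = FALSE)
  if (n_frames < 2L) stop("'n_frames' must be >= 2", call. = FALSE)
  structure(list(mean_coordinates = unname(mean_coordinates),
                 covariance = unname(covariance),
                 n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "gaussian_ensemble_spec")
}

#' Draw a Gaussian coordinate ensemble
#'
#' Samples `n_frames` frames from the multivariate normal defined by the
#' spec.  As `n_frames` grows, the sample mean converges to the spec mean
#' and the sample covariance to the spec covariance.
#'
#' @param spec a [gaussian_ensemble_spec()].
#' @return a [coord_ensemble()] of C-alpha beads, one per residue.
#' @export
gen_gaussian_ensemble <- function(spec) {
  stopifnot(inherits(spec, "gaussian_ensemble_spec"))
  mu <- as.vector(t(spec$mean_coordinates))
  xyz <- withr::with_seed(spec$seed,
    MASS::mvrnorm(n = spec$n_frames, mu = mu, Sigma = spec$covariance,
                  tol = 1e-7))
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  coord_ensemble(xyz, bead_atom_table(nrow(spec$mean_coordinates)))
}

#' Specification of a two-state (open/closed) switching loop
#'
#' The hidden state follows a discrete-time two-state Markov chain with a
#' prescribed stationary closed fraction and mean closed-state dwell time;
#' emitted coordinates are the state's anchor geometry plus isotropic
#' Gaussian jitter.  This is the simplest process with tunable
#' autocorrelation, emulating slow loop interconversion.
#'
#' @param open_coordinates,closed_coordinates N x 3 anchor geometries for
#'   the mobile loop (identical residue counts required).
#' @param occupancy_closed stationary fraction of frames in the closed
#'   state, in `[0, 1]`.
#' @param mean_dwell mean dwell time of the closed state, in frames (>= 1).
#' @param jitter_sd isotropic positional jitter s.d. (Angstrom, >= 0).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return an object of class `two_state_loop_spec`.
#' @export
two_state_loop_spec <- function(open_coordinates, closed_coordinates,
                                occupancy_closed, mean_dwell = 20,
                                jitter_sd = 0.2, n_frames = 1000, seed = 1) {
  open_coordinates <- as.matrix(open_coordinates)
  closed_coordinates <- as.matrix(closed_coordinates)
  if (!identical(dim(open_coordinates), dim(closed_coordinates)))
    stop(sprintf(
      "open (%d residues) and closed (%d residues) coordinate sets differ",
      nrow(open_coordinates), nrow(closed_coordinates)), call. = FALSE)
  if (ncol(open_coordinates) != 3L)
    stop("coordinate sets must be N x 3", call. = FALSE)
  if (occupancy_closed < 0 || occupancy_closed > 1)
    stop("'occupancy_closed' must lie in [0, 1]", call. = FALSE)
  if (mean_dwell < 1) stop("'mean_dwell' must be >= 1 frame", call. = FALSE)
  if (jitter_sd < 0) stop("'jitter_sd' must be >= 0", call. = FALSE)
  p <- occupancy_closed
  if (p > 0 && p < 1) {
    a <- 1 / mean_dwell              # closed -> open exit probability
    b <- a * p / (1 - p)             # open -> closed entry probability
    if (b > 1)
      stop("occupancy/mean_dwell combination implies open-state exit ",
           "probability > 1; increase mean_dwell", call. = FALSE)
  }
  structure(list(open_coordinates = unname(open_coordinates),
                 closed_coordinates = unname(closed_coordinates),
                 occupancy_closed = occupancy_closed,
                 mean_dwell = mean_dwell, jitter_sd = jitter_sd,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "two_state_loop_spec")
}

#' Generate a two-state switching loop trajectory
#'
#' @param spec a [two_state_loop_spec()].
#' @return a list with elements `ensemble` (a [coord_ensemble()]), `labels`
#'   (per-frame character vector, `"open"`/`"closed"` — the ground truth for
#'   recovery tests) and `autocorr` (lag-1 autocorrelation of the state
#'   indicator implied by the chain, for Markov-chain standard errors).
#' @export
gen_two_state_loop <- function(spec) {
  stopifnot(inherits(spec, "two_state_loop_spec"))
  p <- spec$occupancy_closed
  n <- spec$n_frames
  n_res <- nrow(spec$open_coordinates)
  res <- withr::with_seed(spec$seed, {
    if (p == 0 || p == 1) {
      states <- rep(if (p == 1) "closed" else "open", n)
      rho <- 0
    } else {
      a <- 1 / spec$mean_dwell
      b <- a * p / (1 - p)
      rho <- 1 - a - b
      u <- runif(n)
      s <- integer(n)                 # 1 = closed, 0 = open
      s[1] <- as.integer(u[1] < p)    # start from the stationary law
      for (t in 2:n) {
        s[t] <- if (s[t - 1] == 1L) as.integer(u[t] >= a) else
          as.integer(u[t] < b)
      }
      states <- ifelse(s == 1L, "closed", "open")
    }
    anchors <- list(open = as.vector(t(spec$open_coordinates)),
                    closed = as.vector(t(spec$closed_coordinates)))
    xyz <- t(vapply(states, function(st) anchors[[st]],
                    numeric(3 * n_res)))
    if (spec$jitter_sd > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), sd = spec$jitter_sd),
                          nrow = n)
    list(xyz = xyz, states = states, rho = rho)
  })
  list(ensemble = coord_ensemble(res$xyz, bead_atom_table(n_res)),
       labels = unname(res$states), autocorr = res$rho)
}

#' Markov-chain standard error of an occupancy estimate
#'
#' For a two-state chain with stationary fraction `p` and lag-1 state
#' autocorrelation `rho`, the variance of the empirical occupancy over `n`
#' frames is inflated by `(1 + rho) / (1 - rho)` relative to i.i.d.
#' sampling.
#'
#' @param p stationary occupancy.
#' @param n number of frames.
#' @param rho lag-1 autocorrelation (as returned by [gen_two_state_loop()]).
#' @return standard error of the empirical fraction.
#' @export
markov_occupancy_se <- function(p, n, rho = 0) {
  sqrt(p * (1 - p) / n * (1 + rho) / (1 - rho))
}

#' Specification of harmonic diabatic states for synthetic EVB sampling
#'
#' Two harmonic diabats with equal force constants,
#' `e1(x) = k/2 (x - x1)^2` and `e2(x) = k/2 (x - x2)^2 + dG0`, mixed by the
#' EVB mapping potential `E_m = (1 - lambda) e1 + lambda e2`.  Equal force
#' constants make every mapping potential exactly quadratic, so window
#' sampling is exact Gaussian draw — no sampler error enters the oracle.
#'
#' @param k_force force constant (kcal mol^-1 A^-2, > 0).
#' @param x1,x2 diabatic minima positions (Angstrom).
#' @param dG0 reaction free energy offset of diabat 2 (kcal mol^-1).
#' @param H12 constant diabatic coupling (kcal mol^-1, >= 0).
#' @param temperature Kelvin (> 0).
#' @param lambdas strictly increasing mapping-parameter grid from 0 to 1
#'   (default: 51 evenly spaced windows, the standard EVB protocol).
#' @param frames_per_window samples per window.
#' @param seed integer seed.
#' @return an object of class `harmonic_diabat_spec`.
#' @export
harmonic_diabat_spec <- function(k_force, x1, x2, dG0 = 0, H12 = 0,
                                 temperature = 300,
                                 lambdas = seq(0, 1, length.out = 51),
                                 frames_per_window = 1000, seed = 1) {
  assert_scalar_num(k_force, "k_force", positive = TRUE)
  assert_scalar_num(temperature, "temperature", positive = TRUE)
  if (x1 == x2) stop("'x1' and 'x2' must differ", call. = FALSE)
  if (H12 < 0) stop("'H12' must be >= 0", call. = FALSE)
  if (length(lambdas) < 2 || any(diff(lambdas) <= 0) ||
      lambdas[1] != 0 || lambdas[length(lambdas)] != 1)
    stop("'lambdas' must be strictly increasing from 0 to 1", call. = FALSE)
  if (frames_per_window < 1)
    stop("'frames_per_window' must be >= 1", call. = FALSE)
  structure(list(k_force = k_force, x1 = x1, x2 = x2, dG0 = dG0, H12 = H12,
                 temperature = temperature, lambdas = as.numeric(lambdas),
                 frames_per_window = as.integer(frames_per_window),
                 seed = as.integer(seed)),
            class = "harmonic_diabat_spec")
}

# diabatic energies at position x
diabat_energies <- function(spec, x) {
  list(e1 = 0.5 * spec$k_force * (x - spec$x1)^2,
       e2 = 0.5 * spec$k_force * (x - spec$x2)^2 + spec$dG0)
}

# lower adiabatic (ground-state) surface at position x
adiabat_lower <- function(spec, x) {
  e <- diabat_energies(spec, x)
  0.5 * (e$e1 + e$e2) - 0.5 * sqrt((e$e1 - e$e2)^2 + 4 * spec$H12^2)
}

#' Analytic stationary points of the lower adiabatic surface
#'
#' Locates the reactant-state minimum, transition-state maximum and
#' product-state minimum of the ground-state surface implied by a
#' [harmonic_diabat_spec()], by bracketed 1D optimisation (the surface is
#' smooth except for the `H12 = 0` cusp, which the bracketing still
#' resolves).  Also reports the Marcus quantities: reorganisation energy
#' `lambda_reorg = k/2 (x2 - x1)^2` and the diabatic crossing barrier
#' `(lambda_reorg + dG0)^2 / (4 lambda_reorg)`.
#'
#' @param spec a [harmonic_diabat_spec()].
#' @return list with `x_rs`, `x_ts`, `x_ps`, `dg_act`, `dg_rxn`,
#'   `lambda_reorg`, `diabatic_barrier`.
#' @export
analytic_adiabatic_profile <- function(spec) {
  stopifnot(inherits(spec, "harmonic_diabat_spec"))
  lo <- min(spec$x1, spec$x2)
  hi <- max(spec$x1, spec$x2)
  span <- hi - lo
  f <- function(x) adiabat_lower(spec, x)
  # diabatic crossing point (equal-k parabolas cross exactly once)
  xc <- (spec$x1 + spec$x2) / 2 + spec$dG0 / (spec$k_force * (spec$x2 - spec$x1))
  rs <- stats::optimize(f, interval = c(spec$x1 - span, xc), tol = 1e-10)
  ps <- stats::optimize(f, interval = c(xc, spec$x2 + span), tol = 1e-10)
  ts <- stats::optimize(f, interval = c(rs$minimum, ps$minimum),
                        maximum = TRUE, tol = 1e-10)
  lam <- 0.5 * spec$k_force * (spec$x2 - spec$x1)^2
  list(x_rs = rs$minimum, x_ts = ts$maximum, x_ps = ps$minimum,
       dg_act = ts$objective - rs$objective,
       dg_rxn = ps$objective - rs$objective,
       lambda_reorg = lam,
       diabatic_barrier = (lam + spec$dG0)^2 / (4 * lam))
}

#' Generate synthetic EVB window energies
#'
#' For each mapping window the mapping potential
#' `E_m(x) = (1 - lambda_m) e1(x) + lambda_m e2(x)` is quadratic with the
#' common force constant, so its Boltzmann distribution is the exact
#' Gaussian `N(x_m, kT / k)` with `x_m = (1 - lambda_m) x1 + lambda_m x2`.
#' Frames are drawn from it directly and the two diabatic energies recorded
#' per frame.
#'
#' @param spec a [harmonic_diabat_spec()].
#' @return an [evb_window_series()] carrying an `analytic` attribute (the
#'   output of [analytic_adiabatic_profile()]) and a `positions` attribute
#'   with the sampled x per window, for oracle tests.
#' @export
gen_evb_windows <- function(spec) {
  stopifnot(inherits(spec, "harmonic_diabat_spec"))
  kt <- boltzmann_kt(spec$temperature)
  sd_x <- sqrt(kt / spec$k_force)
  res <- withr::with_seed(spec$seed, {
    lapply(spec$lambdas, function(l) {
      xm <- (1 - l) * spec$x1 + l * spec$x2
      x <- rnorm(spec$frames_per_window, mean = xm, sd = sd_x)
      e <- diabat_energies(spec, x)
      data.frame(e1 = e$e1, e2 = e$e2, x = x)
    })
  })
  series <- evb_window_series(
    lambdas = spec$lambdas,
    frames = lapply(res, function(d) d[, c("e1", "e2")]),
    H12 = spec$H12, temperature = spec$temperature)
  attr(series, "analytic") <- analytic_adiabatic_profile(spec)
  attr(series, "positions") <- lapply(res, function(d) d$x)
  series
}

#' Generate a synthetic oncogenic-variant table
#'
#' Emulates a minimal COSMIC-style export of somatic amino-acid
#' substitutions: rows of `(gene, position, wt_aa, alt_aa, count)` with a
#' known ground-truth hotspot set (positions receiving two or more distinct
#' substitutions).
#'
#' @param seed integer seed (fixed seed gives a byte-identical table and
#'   CSV).
#' @param n_positions number of mutated positions (>= 0).
#' @param substitution_rate probability weight controlling how often a
#'   position receives additional distinct substitutions.
#' @param positions optional vector of residue positions to use (defaults
#'   to a sample from a catalytic-domain-like range 245..540).
#' @param hotspot_positions positions forced to receive >= 2 distinct
#'   substitutions (planted hotspots; must be among `positions` if both are
#'   given).
#' @param gene gene label for all rows.
#' @return a `variant_table` data.frame with attributes `hotspots` (ground
#'   truth) and `gene`.
#' @export
gen_variant_table <- function(seed, n_positions, substitution_rate = 0.3,
                              positions = NULL, hotspot_positions = NULL,
                              gene = "SYNTH") {
  if (n_positions < 0) stop("'n_positions' must be >= 0", call. = FALSE)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (n_positions == 0) {
    tab <- data.frame(gene = character(0), position = integer(0),
                      wt_aa = character(0), alt_aa = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
    attr(tab, "hotspots") <- integer(0)
    attr(tab, "gene") <- gene
    class(tab) <- c("variant_table", "data.frame")
    return(tab)
  }
  tab <- withr::with_seed(as.integer(seed), {
    if (is.null(positions))
      positions <- sort(sample(245:540, n_positions))
    else {
      positions <- sort(unique(as.integer(positions)))
      if (length(positions) != n_positions)
        stop("'positions' must supply n_positions distinct values",
             call. = FALSE)
    }
    if (!is.null(hotspot_positions) &&
        !all(hotspot_positions %in% positions))
      stop("'hotspot_positions' must be a subset of 'positions'",
           call. = FALSE)
    rows <- lapply(positions, function(pos) {
      wt <- sample(aa, 1)
      n_sub <- 1L + rbinom(1, size = 3, prob = substitution_rate)
      if (pos %in% hotspot_positions) n_sub <- max(2L, n_sub)
      alts <- sample(setdiff(aa, wt), n_sub)
      data.frame(gene = gene, position = pos, wt_aa = wt, alt_aa = alts,
                 count = 1L + rpois(n_sub, 2), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rownames(tab) <- NULL
  n_distinct <- tapply(tab$alt_aa, tab$position, function(a)
    length(unique(a)))
  attr(tab, "hotspots") <- sort(as.integer(names(n_distinct)[n_distinct >= 2]))
  attr(tab, "gene") <- gene
  class(tab) <- c("variant_table", "data.frame")
  tab
}
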