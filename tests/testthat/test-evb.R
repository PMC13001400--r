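const_series <- function(e1, e2, lambdas = c(0, 0.5, 1), n = 5) {
  evb_window_series(lambdas, lapply(lambdas, function(l)
    data.frame(e1 = rep(e1, n), e2 = rep(e2, n))), H12 = 0,
    temperature = 300)
}

test_that("mapping energies interpolate the diabats", {
  s <- const_series(10, 4)
  expect_equal(mapping_energies(s, 1), rep(10, 5))   # lambda = 0 -> e1
  expect_equal(mapping_energies(s, 3), rep(4, 5))    # lambda = 1 -> e2
  expect_equal(mapping_energies(s, 2), rep(7, 5))    # midpoint
  expect_error(mapping_energies(s, 4), "window 4")
  expect_error(evb_window_series(c(0, 1), list(data.frame(e1 = 1, e2 = 1))),
               "one frame table per window")
  expect_error(evb_window_series(c(0.2, 1),
                                 rep(list(data.frame(e1 = 1, e2 = 1)), 2)),
               "increasing from 0 to 1")
})

test_that("FEP increments reproduce constant and Gaussian closed forms", {
  # constant energy difference c per step accumulates exactly
  s <- const_series(10, 4, lambdas = seq(0, 1, 0.25), n = 3)
  dg <- fep_increments(s)
  expect_equal(dg, 0.25 * (4 - 10) * (0:4))
  # degenerate diabats: profile flat at zero
  s0 <- const_series(5, 5)
  expect_equal(fep_increments(s0), rep(0, 3))

  # Gaussian energy gap: increment -> mu - sigma^2 / (2 kT)
  kt <- boltzmann_kt(300)
  mu <- 1.2; sigma <- 0.6; n <- 20000
  de <- withr::with_seed(101, rnorm(n, mu, sigma))
  # build a 2-window series whose step difference is exactly de
  s_g <- evb_window_series(c(0, 1), list(
    data.frame(e1 = rep(0, n), e2 = de), data.frame(e1 = 0, e2 = 0)),
    H12 = 0, temperature = 300)
  inc <- fep_increments(s_g)[2]
  expected <- mu - sigma^2 / (2 * kt)
  w <- exp(-(de - mean(de)) / kt)
  se <- kt * stats::sd(w) / (mean(w) * sqrt(n))
  expect_lt(abs(inc - expected), 2 * se)
})

test_that("forward and reverse FEP are antisymmetric on symmetric data", {
  spec <- harmonic_diabat_spec(k_force = 80, x1 = 0, x2 = 1, dG0 = 0,
                               H12 = 0, lambdas = seq(0, 1, 0.05),
                               frames_per_window = 3000, seed = 7)
  s <- gen_evb_windows(spec)
  fwd <- fep_increments(s)
  # swapping e1 <-> e2 and reversing the window order retraces the path
  rev_frames <- rev(lapply(s$frames, function(f)
    data.frame(e1 = f$e2, e2 = f$e1)))
  s_rev <- evb_window_series(rev(1 - s$lambdas), rev_frames, H12 = 0,
                             temperature = 300)
  bwd <- fep_increments(s_rev)
  # total forward + total reverse ~ 0 within combined statistical error
  expect_lt(abs(fwd[length(fwd)] + bwd[length(bwd)]), 0.2)
  # bidirectional estimator stays close to the forward one here
  bi <- fep_increments(s, method = "bidirectional")
  expect_lt(abs(bi[length(bi)] - fwd[length(fwd)]), 0.2)
})

test_that("poorly overlapping windows trigger the sample-size warning", {
  spec <- harmonic_diabat_spec(k_force = 400, x1 = 0, x2 = 4, dG0 = 0,
                               H12 = 0, lambdas = c(0, 0.5, 1),
                               frames_per_window = 50, seed = 8)
  suppressWarnings(expect_warning(fep_increments(gen_evb_windows(spec)),
                                  "effective sample size"))
})

test_that("gap profiles recover analytic barriers from the generator", {
  spec <- harmonic_diabat_spec(k_force = 100, x1 = 0, x2 = 1, dG0 = -2,
                               H12 = 1, frames_per_window = 2000, seed = 9)
  an <- analytic_adiabatic_profile(spec)
  prof <- gap_profile(gen_evb_windows(spec), n_bins = 200)
  expect_lt(abs(prof$dg_act - an$dg_act), 0.3)
  expect_lt(abs(prof$dg_rxn - an$dg_rxn), 0.3)
  expect_lt(abs(prof$dg_rxn - spec$dG0), 0.35)  # H12 shifts minima slightly
  # RS minimum pinned at zero by convention
  expect_equal(prof$profile$dg[prof$i_rs], 0)
  expect_true(prof$i_rs < prof$i_ts && prof$i_ts < prof$i_ps)
  # profile CSV + JSON summary
  tf <- tempfile(fileext = ".csv")
  write_profile_csv(prof, tf)
  js <- jsonlite::read_json(sub("csv$", "json", tf))
  expect_equal(js$dg_act, prof$dg_act, tolerance = 1e-9)
  back <- read.csv(tf)
  expect_named(back, c("x", "dg", "count"))
})

test_that("degenerate gap input fails loudly", {
  expect_error(gap_profile(const_series(5, 5)), "degenerate")
})

test_that("EVB CSV round trips through the documented dialect", {
  spec <- harmonic_diabat_spec(k_force = 50, x1 = 0, x2 = 1, dG0 = -1,
                               H12 = 0.5, lambdas = c(0, 0.5, 1),
                               frames_per_window = 20, seed = 10)
  s <- gen_evb_windows(spec)
  tf <- tempfile(fileext = ".csv")
  write_evb_csv(s, tf)
  expect_identical(readLines(tf)[1], "lambda,frame,e1,e2")
  back <- read_evb_csv(tf, H12 = 0.5, temperature = 300)
  expect_equal(back$lambdas, s$lambdas)
  expect_equal(back$frames[[2]]$e1, s$frames[[2]]$e1, tolerance = 1e-9)
})

test_that("replicate statistics: ANOVA F matches the hand formula", {
  reps <- list(wt = c(14.2, 14.8, 14.5, 14.9, 14.1),
               mutA = c(16.1, 15.7, 16.4, 15.9, 16.2),
               mutB = c(14.6, 15.0, 14.3, 14.8, 14.7))
  bs <- barrier_stats(reps)
  expect_equal(bs$mean, vapply(reps, mean, numeric(1)),
               ignore_attr = TRUE)
  expect_equal(bs$sem[1], sd(reps$wt) / sqrt(5))

  out <- anova_tukey(reps)
  # independent oracle: one-way ANOVA F from the textbook sums of squares
  all_v <- unlist(reps); k <- length(reps); n <- length(all_v)
  ss_between <- sum(vapply(reps, function(g)
    length(g) * (mean(g) - mean(all_v))^2, numeric(1)))
  ss_within <- sum(vapply(reps, function(g)
    sum((g - mean(g))^2), numeric(1)))
  f_hand <- (ss_between / (k - 1)) / (ss_within / (n - k))
  expect_equal(out$f, f_hand, tolerance = 1e-9)
  expect_equal(out$p, stats::pf(f_hand, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(nrow(out$tukey), choose(k, 2))
})

test_that("Tukey HSD: k = 2 groups reduce to the sqrt(2) t identity", {
  withr::with_seed(112, {
    reps <- list(a = rnorm(12, 10, 0.5), b = rnorm(12, 10.6, 0.5))
  })
  out <- anova_tukey(reps)
  tt <- stats::t.test(reps$a, reps$b, var.equal = TRUE)
  q_obs <- sqrt(2) * abs(unname(tt$statistic))
  p_tukey <- stats::ptukey(q_obs, nmeans = 2, df = 22, lower.tail = FALSE)
  expect_equal(out$tukey$p_adj, p_tukey, tolerance = 1e-6)
  expect_equal(out$p, tt$p.value, tolerance = 1e-9)
})

test_that("star annotations follow the p-value bands", {
  same <- list(a = c(10, 10.01, 9.99, 10), b = c(10, 10.02, 9.98, 10))
  out_same <- anova_tukey(same)
  expect_equal(out_same$tukey$stars, "")
  far <- list(a = rep(c(0, 0.1), 15) + rnorm(30, sd = 0.1),
              b = rep(c(10, 10.1), 15) + rnorm(30, sd = 0.1))
  out_far <- anova_tukey(far)
  expect_equal(out_far$tukey$stars, "**")
  expect_lt(out_far$tukey$p_adj, 0.01)
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "fewer than 2")
  expect_error(anova_tukey(list(a = c(1, 2))), "at least 2 systems")
})

test_that("TST conversion satisfies its identities", {
  kb <- 1.380649e-23; h <- 6.62607015e-34
  expect_equal(tst_barrier(kb * 300 / h, 300), 0, tolerance = 1e-12)
  # closed form at kcat = 1/s
  rt <- 0.0019872041 * 300
  expect_equal(tst_barrier(1, 300), rt * log(kb * 300 / h),
               tolerance = 1e-12)
  # doubling kcat lowers the barrier by RT ln 2
  expect_equal(tst_barrier(1, 300) - tst_barrier(2, 300), rt * log(2),
               tolerance = 1e-12)
  expect_error(tst_barrier(-1, 300), "> 0")
  expect_error(tst_barrier(1, -5), "temperature")
})

test_that("reactive-geometry clustering separates planted conformers", {
  tl <- toy_loops()
  withr::with_seed(120, {
    frames <- rbind(
      t(vapply(1:6, function(i) as.vector(t(tl$closed)) +
                 rnorm(18, sd = 0.05), numeric(18))),
      t(vapply(1:6, function(i) as.vector(t(tl$open)) +
                 rnorm(18, sd = 0.05), numeric(18))))
  })
  ens <- coord_ensemble(frames, bead_table(6))
  cl <- cluster_reactive_geometries(ens, selection = 1:6, n_clusters = 2)
  truth <- rep(1:2, each = 6)
  # 100% purity up to label permutation
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_equal(agree, 1)
  expect_length(cl$representatives, 2)
  # all-identical frames collapse to one cluster
  same <- coord_ensemble(frames[c(1, 1, 1), ], bead_table(6))
  cl1 <- cluster_reactive_geometries(same, selection = 1:6, n_clusters = 1)
  expect_equal(unique(cl1$labels), 1L)
  # n_clusters = n_frames gives singletons
  cln <- cluster_reactive_geometries(ens, selection = 1:6,
                                     n_clusters = 12)
  expect_equal(sort(unique(cln$labels)), 1:12)
  expect_error(cluster_reactive_geometries(ens, integer(0)), "non-empty")
})
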