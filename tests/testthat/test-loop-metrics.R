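test_that("reference distance sets are full cross products", {
  tl <- toy_loops()
  ref <- build_reference(tl$closed_ens, tl$wpd, tl$p)
  expect_equal(nrow(ref$pairs), 9)  # 3 x 3
  r1 <- build_reference(tl$closed_ens, loop_definition("w", 1),
                        loop_definition("p", 4:5))
  expect_equal(nrow(r1$pairs), 2)
  # 10-residue x 8-residue loops -> 80 pairs
  big <- bead_frame(matrix(rnorm(54, sd = 6), 18, 3))
  r80 <- build_reference(big, loop_definition("w", 1:10),
                         loop_definition("p", 11:18))
  expect_equal(nrow(r80$pairs), 80)
  # residue lacking a CA is an error naming it
  no_ca <- coord_ensemble(matrix(rnorm(18), 1), within(bead_table(6), {
    elety[3] <- "CB"
  }))
  expect_error(build_reference(no_ca, tl$wpd, tl$p), "3")
  # intra-loop variant covers all pairs within the union
  r_all <- build_reference(tl$closed_ens, tl$wpd, tl$p, intra_loop = TRUE)
  expect_equal(nrow(r_all$pairs), choose(6, 2))
})

test_that("dRMSD matches hand arithmetic and vanishes on self-reference", {
  # toy: 2 pairs, d_ref = {5, 7}, frame distances {6, 7} -> sqrt(1/2)
  ref_geom <- matrix(c(0, 0, 0, 0, 0, 5, 0, 7, 0), 3, 3, byrow = TRUE)
  frame_geom <- matrix(c(0, 0, 0, 0, 0, 6, 0, 7, 0), 3, 3, byrow = TRUE)
  w <- loop_definition("w", 1); p <- loop_definition("p", 2:3)
  ref <- build_reference(bead_frame(ref_geom), w, p)
  expect_equal(ref$pairs$d_ref, c(5, 7))
  expect_equal(compute_drmsd(bead_frame(frame_geom), ref),
               sqrt((1^2 + 0^2) / 2), tolerance = 1e-9)
  # self-reference -> exactly 0
  tl <- toy_loops()
  ref_tl <- build_reference(tl$closed_ens, tl$wpd, tl$p)
  expect_equal(compute_drmsd(tl$closed_ens, ref_tl), 0)
  # unmapped pair aborts with the pair list
  am <- alignment_map(data.frame(res_a = 1:5, res_b = 1:5))
  expect_error(compute_drmsd(tl$closed_ens, ref_tl, map = am),
               "unmapped.*6")
})

test_that("dRMSD and COM distance are rigid-motion invariant", {
  tl <- toy_loops()
  ref <- build_reference(tl$closed_ens, tl$wpd, tl$p)
  base <- as.vector(t(tl$open))
  withr::with_seed(21, {
    for (rep in 1:25) {
      rot <- random_rotation()
      moved <- bead_frame(matrix(
        apply_rigid(base, rot, rnorm(3, sd = 20)), ncol = 3, byrow = TRUE))
      expect_equal(compute_drmsd(moved, ref),
                   compute_drmsd(bead_frame(tl$open), ref),
                   tolerance = 1e-9)
      expect_equal(compute_com_distance(moved, tl$wpd, tl$p),
                   compute_com_distance(bead_frame(tl$open), tl$wpd, tl$p),
                   tolerance = 1e-9)
    }
  })
})

test_that("centre-of-mass distances follow centroid arithmetic", {
  two <- bead_frame(matrix(c(0, 0, 0, 3, 4, 0), 2, 3, byrow = TRUE))
  a <- loop_definition("a", 1); b <- loop_definition("b", 2)
  expect_equal(compute_com_distance(two, a, b), 5)
  expect_equal(compute_com_distance(two, a, a), 0)
  four <- bead_frame(matrix(c(0, 0, 0, 2, 0, 0, 5, 0, 0, 7, 0, 0),
                            4, 3, byrow = TRUE))
  expect_equal(compute_com_distance(four, loop_definition("a", 1:2),
                                    loop_definition("b", 3:4)), 5)
  expect_error(compute_com_distance(two, loop_definition("c", 9), b), "9")
})

test_that("landscape histograms conserve frames", {
  # identical frames occupy a single bin
  ls1 <- build_landscape(rep(1.5, 40), rep(9, 40), bins = c(10, 10))
  expect_equal(sum(ls1$counts), 40)
  expect_equal(sum(ls1$counts > 0), 1)
  expect_equal(max(ls1$counts), 40)
  # empty series
  ls0 <- build_landscape(numeric(0), numeric(0), bins = c(5, 5))
  expect_equal(sum(ls0$counts), 0)
  # random series incl. values outside the anchor-extended range
  withr::with_seed(3, {
    d <- rexp(500); cm <- rnorm(500, 10)
    ls <- build_landscape(d, cm, bins = c(12, 7),
                          anchors = list(closed = c(0, 8),
                                         open = c(3, 14)))
    expect_equal(sum(ls$counts), 500)
    edges <- list(x = c(0, 1, 2), y = c(0, 10, 20))
    ls_e <- build_landscape(d, cm, bins = edges)
    expect_equal(sum(ls_e$counts), 500)  # clamped into edge bins
  })
  expect_error(build_landscape(1:3, 1:4), "length mismatch")
})

test_that("state classification recovers anchors and generator occupancy", {
  tl <- toy_loops()
  ref <- build_reference(tl$closed_ens, tl$wpd, tl$p)
  anch <- toy_anchors(tl, ref)
  expect_equal(classify_states(anch$closed[1], anch$closed[2], anch),
               "closed")
  expect_equal(classify_states(anch$open[1], anch$open[2], anch), "open")
  mid <- (anch$closed + anch$open) / 2
  expect_equal(classify_states(mid[1], mid[2], anch), "semi_closed")

  run <- gen_two_state_loop(two_state_loop_spec(
    tl$open, tl$closed, 0.6, mean_dwell = 15, jitter_sd = 0.15,
    n_frames = 4000, seed = 8))
  dr <- compute_drmsd(run$ensemble, ref)
  cm <- compute_com_distance(run$ensemble, tl$wpd, tl$p)
  lab <- classify_states(dr, cm, anch)
  acc <- mean((lab == "closed") == (run$labels == "closed"))
  expect_gte(acc, 0.99)
})

test_that("RMSF matches closed forms and superposition lowers it", {
  # static trajectory -> all zeros
  tl <- toy_loops()
  static <- coord_ensemble(rbind(as.vector(t(tl$closed)),
                                 as.vector(t(tl$closed))), bead_table(6))
  expect_equal(compute_rmsf(static, superpose = FALSE)$rmsf, rep(0, 6))
  expect_error(compute_rmsf(bead_frame(tl$closed)), "2 frames")

  # one atom alternating between (0,0,0) and (2,0,0): RMSF 1
  alt <- coord_ensemble(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 0, 0),
                              c(2, 0, 0)), bead_table(1))
  expect_equal(compute_rmsf(alt, superpose = FALSE)$rmsf, 1)

  # rigid drift plus internal noise: fitted RMSF never exceeds unfitted
  withr::with_seed(14, {
    n <- 200
    drift <- matrix(cumsum(rnorm(3 * n, sd = 0.3)), n, 3)
    base <- matrix(rnorm(24, sd = 4), 8, 3)
    xyz <- t(vapply(seq_len(n), function(i) {
      as.vector(t(sweep(base + matrix(rnorm(24, sd = 0.1), 8, 3),
                        2, drift[i, ], "+")))
    }, numeric(24)))
    ens <- coord_ensemble(xyz, bead_table(8))
    with_fit <- compute_rmsf(ens, superpose = TRUE)
    without <- compute_rmsf(ens, superpose = FALSE)
    expect_lt(sum(with_fit$rmsf^2), sum(without$rmsf^2) + 1e-9)
  })
})

test_that("delta RMSF uses the more-flexible-in-first sign convention", {
  withr::with_seed(15, {
    wide <- gen_gaussian_ensemble(gaussian_ensemble_spec(
      matrix(0, 2, 3), 4, 2000, 1))
    narrow <- gen_gaussian_ensemble(gaussian_ensemble_spec(
      matrix(0, 2, 3), 1, 2000, 2))
  })
  a <- compute_rmsf(wide, superpose = FALSE)
  b <- compute_rmsf(narrow, superpose = FALSE)
  d <- delta_rmsf(a, b)
  expect_true(all(d$delta > 0))
  expect_equal(d$delta, a$rmsf - b$rmsf)
  # mapped numbering
  am <- alignment_map(data.frame(res_a = 1:2, res_b = 11:12))
  b2 <- b; b2$resno <- 11:12
  expect_equal(delta_rmsf(a, b2, map = am)$delta, d$delta)
})

test_that("reactive-fraction filtering enforces strict cutoffs", {
  # atoms: acid O (res 419), Q-loop C (res 500), phosphorus (res 453)
  mk_frame <- function(d1, d2) {
    atoms <- data.frame(elety = c("OD1", "CD", "P"),
                        resid = c("ASP", "GLN", "CYX"),
                        resno = c(419L, 500L, 453L), chain = "A",
                        stringsAsFactors = FALSE)
    coord_ensemble(c(0, 0, d1, 0, 0, -d2, 0, 0, 0), atoms)$xyz
  }
  atoms <- data.frame(elety = c("OD1", "CD", "P"),
                      resid = c("ASP", "GLN", "CYX"),
                      resno = c(419L, 500L, 453L), chain = "A",
                      stringsAsFactors = FALSE)
  combos <- list(c(4.4, 7.9), c(4.6, 7.9), c(4.4, 8.1), c(4.6, 8.1))
  xyz <- do.call(rbind, lapply(combos, function(cc) mk_frame(cc[1], cc[2])))
  ens <- coord_ensemble(xyz, atoms)
  res <- reactive_fraction(ens)   # default 4.5 / 8.0 criteria
  expect_equal(res$fraction, 0.25)
  expect_equal(res$frames, 1L)
  # brute-force re-check frame by frame
  brute <- vapply(seq_len(4), function(f) {
    x <- frame_coords(ens, f)
    sqrt(sum((x[1, ] - x[3, ])^2)) < 4.5 &&
      sqrt(sum((x[2, ] - x[3, ])^2)) < 8.0
  }, logical(1))
  expect_identical(res$pass, brute)
  # boundary: exactly at the cutoff fails (strict <)
  at_cut <- coord_ensemble(mk_frame(4.5, 8.0), atoms)
  expect_equal(reactive_fraction(at_cut)$fraction, 0)
  # all pass
  all_in <- coord_ensemble(mk_frame(3.0, 5.0), atoms)
  expect_equal(reactive_fraction(all_in)$fraction, 1)
  # unresolvable spec named in the error
  bad <- reactive_criteria(data.frame(res_a = 1, atom_a = "ZZ", res_b = 453,
                                      atom_b = "P", max_dist = 5))
  expect_error(reactive_fraction(ens, bad), "1:ZZ")
  expect_error(reactive_criteria(data.frame(res_a = 1, atom_a = "A",
                                            res_b = 2, atom_b = "B",
                                            max_dist = 0)), "> 0")
})
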