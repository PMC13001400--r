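test_that("PDB reading handles single and multi-model files", {
  tl <- toy_loops()
  single <- tempfile(fileext = ".pdb")
  write_structure(tl$closed_ens, single)
  got <- load_structure(single)
  expect_equal(n_frames(got), 1)
  expect_equal(got$atoms$resno, 1:6)

  multi <- tempfile(fileext = ".pdb")
  frames <- t(vapply(1:5, function(i) as.vector(t(tl$closed)) + i * 0.1,
                     numeric(18)))
  write_structure(coord_ensemble(frames, bead_table(6)), multi)
  got5 <- load_structure(multi)
  expect_equal(n_frames(got5), 5)
  expect_equal(n_frames(load_structure(multi, model_index = 3)), 1)
  expect_error(load_structure(multi, model_index = 6), "not present")

  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", bad)
  expect_error(load_structure(bad), "parse|PDB")
})

test_that("PDB round trip preserves coordinates to PDB precision", {
  xyz <- rbind(rnorm(18, sd = 8), rnorm(18, sd = 8))
  ens <- coord_ensemble(round(xyz, 3), bead_table(6))
  tf <- tempfile(fileext = ".pdb")
  write_structure(ens, tf)
  back <- load_structure(tf)
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3 + 1e-9)
})

test_that("coordinate-CSV container round trips and flags CA-only residues", {
  atoms <- data.frame(
    elety = c("N", "CA", "C", "O", "CB", "CA"),
    resid = c(rep("ALA", 5), "GLY"),
    resno = c(rep(1L, 5), 2L), chain = "A", stringsAsFactors = FALSE)
  ens <- coord_ensemble(rbind(rnorm(18), rnorm(18)), atoms)
  expect_identical(ens$atoms$ca_only, c(rep(FALSE, 5), TRUE))
  tf <- tempfile(fileext = ".csv")
  write_coords_csv(ens, tf)
  back <- load_structure(tf)
  expect_equal(back$xyz, ens$xyz, tolerance = 1e-5)
  expect_identical(back$atoms$resno, ens$atoms$resno)
})

test_that("select_loop resolves C-alpha and heavy-atom selections", {
  atoms <- data.frame(
    elety = c("N", "CA", "C", "O",                    # GLY: 4 heavy
              "N", "CA", "C", "O", "CB",              # ALA: 5 heavy
              "N", "CA", "C", "O", "CB", "OG", "HG"), # SER: 6 heavy + 1 H
    resid = c(rep("GLY", 4), rep("ALA", 5), rep("SER", 7)),
    resno = c(rep(10L, 4), rep(11L, 5), rep(12L, 7)),
    chain = "A", stringsAsFactors = FALSE)
  ens <- coord_ensemble(matrix(rnorm(48), 1), atoms)
  loop <- loop_definition("toy", 10:12)
  expect_length(select_loop(ens, loop, mode = "calpha"), 3)
  expect_length(select_loop(ens, loop, mode = "heavy"), 15)
  expect_error(select_loop(ens, loop_definition("x", 10:13)), "13")
  expect_error(loop_definition("x", c(5, 5, 6)), "strictly increasing")
  expect_error(loop_definition("x", integer(0)), "empty")
})

test_that("pairwise identity follows the aligned-column convention", {
  expect_equal(pairwise_identity("ACDEF", "ACDEF",
                                 mode = "given_alignment"), 100)
  expect_equal(pairwise_identity("ACDEF", "ACDEY",
                                 mode = "given_alignment"), 80)
  # symmetric in its arguments
  expect_equal(pairwise_identity("AC-DE", "ACXDE", mode = "given_alignment"),
               pairwise_identity("ACXDE", "AC-DE", mode = "given_alignment"))
  # terminal gaps excluded from the denominator
  expect_equal(pairwise_identity("-CDEF", "ACDEF",
                                 mode = "given_alignment"), 100)
  # internal gap column counts as mismatch by default, droppable
  expect_equal(pairwise_identity("AC-DE", "ACXDE",
                                 mode = "given_alignment"), 80)
  expect_equal(pairwise_identity("AC-DE", "ACXDE", mode = "given_alignment",
                                 internal_gaps = "exclude"), 100)
  expect_error(pairwise_identity("ACD", "ACDE", mode = "given_alignment"),
               "mismatch")
  expect_error(pairwise_identity("", "A", mode = "given_alignment"),
               "non-empty")
  # internal global aligner reproduces the ungapped toy
  expect_equal(pairwise_identity("ACDEF", "ACDEY"), 80)
})

test_that("alignment maps pair non-gap columns and report coverage", {
  am <- build_alignment_map(c(sA = "ACDEF", sB = "ACDEF"), "sA", "sB")
  expect_equal(nrow(am$pairs), 5)
  expect_equal(am$coverage, 1)
  am2 <- build_alignment_map(c(sA = "AC-DE", sB = "ACXDE"), "sA", "sB")
  expect_equal(nrow(am2$pairs), 4)
  expect_equal(am2$pairs$res_b, c(1L, 2L, 4L, 5L))
  expect_warning(
    am0 <- build_alignment_map(c(sA = "AB--", sB = "--CD"), "sA", "sB"),
    "no columns")
  expect_equal(nrow(am0$pairs), 0)
  expect_equal(am0$coverage, 0)
  expect_error(build_alignment_map(c(sA = "AC"), "sA", "sZ"), "sZ")
  # author-numbering offsets shift residue ids
  am3 <- build_alignment_map(c(sA = "ACD", sB = "ACD"), "sA", "sB",
                             offset_a = 100, offset_b = 200)
  expect_equal(am3$pairs$res_a, 100:102)
  expect_equal(am3$pairs$res_b, 200:202)
})

test_that("plan accounting is exact and additive", {
  empty <- simulation_plan(data.frame(system = character(0),
                                      n_states = integer(0),
                                      n_replicas = integer(0),
                                      length_us = numeric(0)))
  expect_equal(plan_accounting(empty)$cumulative_us, 0)
  one <- simulation_plan(data.frame(system = "s", n_states = 1,
                                    n_replicas = 1, length_us = 2.5))
  expect_identical(plan_accounting(one)$cumulative_us, 2.5)

  p1 <- simulation_plan(data.frame(system = c("a", "b"),
                                   n_states = c(4, 1), n_replicas = c(8, 5),
                                   length_us = c(1.5, 1)))
  p2 <- simulation_plan(data.frame(system = "c", n_states = 2,
                                   n_replicas = 3, length_us = 0.7))
  both <- simulation_plan(rbind(p1$entries, p2$entries))
  expect_identical(plan_accounting(both)$cumulative_us,
                   plan_accounting(p1)$cumulative_us +
                     plan_accounting(p2)$cumulative_us)
  expect_error(simulation_plan(data.frame(system = "x", n_states = 0,
                                          n_replicas = 1, length_us = 1)),
               "positive")
  # CSV round trip
  tf <- tempfile(fileext = ".csv")
  write.csv(p1$entries, tf, row.names = FALSE, quote = FALSE)
  expect_identical(plan_accounting(read_plan_csv(tf))$cumulative_us,
                   plan_accounting(p1)$cumulative_us)
  # bundled campaign CSV agrees with the built-in plan
  bundled <- system.file("extdata", "simulation_plan.csv",
                         package = "ptpdyn")
  expect_identical(plan_accounting(read_plan_csv(bundled))$cumulative_us,
                   plan_accounting(default_study_plan())$cumulative_us)
})
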