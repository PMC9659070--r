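# The synthetic generators: known ground truth, reproducibility, and
# end-to-end round trips through the analysis modules.

test_that("a noiseless dose series round-trips to the exact planted PF", {
  p <- synth_dose_series(data.frame(residue = 57, residue_type = "K",
                                    pf = 1),
                         sigma = 0, seed = 7, dir = tempfile())
  at <- match_and_aggregate(parse_identifications(p$ids),
                            parse_peak_table(p$peaks))
  fit <- suppressWarnings(fit_decay(oxidized_fraction(at, residue = 57)))
  pf <- protection_factor(fit, "K")
  expect_equal(pf$PF, 1, tolerance = 1e-6)
  truth <- utils::read.csv(p$truth)
  expect_equal(truth$S, 2.2)
})

test_that("multi-site peptides round-trip under the conditional convention", {
  tp <- data.frame(residue = c(55, 57, 59), residue_type = c("K", "K", "D"),
                   pf = c(0.5, 1, 2))
  p <- synth_dose_series(tp, sigma = 0, seed = 7,
                         doses = seq(0, 0.2, length.out = 8),
                         dir = tempfile())
  at <- match_and_aggregate(parse_identifications(p$ids),
                            parse_peak_table(p$peaks))
  truth <- utils::read.csv(p$truth)
  for (r in tp$residue) {
    fit <- suppressWarnings(fit_decay(oxidized_fraction(at, residue = r)))
    expect_equal(fit$S, truth$S[truth$residue == r], tolerance = 1e-6)
  }
})

test_that("a zero-dose-only series fails downstream with too few points", {
  p <- synth_dose_series(data.frame(residue = 5, residue_type = "K", pf = 1),
                         doses = 0, sigma = 0, seed = 1, dir = tempfile())
  at <- match_and_aggregate(parse_identifications(p$ids),
                            parse_peak_table(p$peaks))
  expect_error(fit_decay(oxidized_fraction(at, residue = 5)),
               "fewer than 3")
})

test_that("generators are byte-identical under a fixed seed", {
  tp <- data.frame(residue = c(12, 57), residue_type = c("D", "K"),
                   pf = c(0.5, 2))
  p1 <- synth_dose_series(tp, sigma = 0.05, seed = 11, dir = tempfile())
  p2 <- synth_dose_series(tp, sigma = 0.05, seed = 11, dir = tempfile())
  for (f in c("ids", "peaks", "truth")) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])))
  }
  m1 <- synth_msa(16, c(0.2, 1, 2.5), seed = 8, dir = tempfile())
  m2 <- synth_msa(16, c(0.2, 1, 2.5), seed = 8, dir = tempfile())
  expect_identical(unname(tools::md5sum(m1$fasta)),
                   unname(tools::md5sum(m2$fasta)))
  expect_identical(unname(tools::md5sum(m1$newick)),
                   unname(tools::md5sum(m2$newick)))
  s1 <- synth_toy_structure(toy_structure_plan("bridge"))
  s2 <- synth_toy_structure(toy_structure_plan("bridge"))
  expect_identical(readLines(s1)[-1], readLines(s2)[-1])
})

test_that("generator input validation rejects impossible specifications", {
  expect_error(synth_dose_series(data.frame(residue = 1, residue_type = "K",
                                            pf = -1), dir = tempfile()),
               "PF")
  expect_error(synth_dose_series(data.frame(residue = 1, residue_type = "K",
                                            pf = 1),
                                 doses = c(1, 1), dir = tempfile()),
               "increasing")
  expect_error(synth_msa(8, c(5)), "out of")
  expect_error(synth_msa(4, c(log(20))), "infeasible")
  # steric overlap aborts structure writing
  clash <- list(residues = data.frame(
    type = c("A", "A"), resno = c(1, 2), chain = "A",
    x = c(0, 0.2), y = 0, z = 0, theta = 0), waters = NULL)
  expect_error(synth_toy_structure(clash), "steric overlap")
})

test_that("planted structural features are recovered by the graph modules", {
  # a plan with 5 placed waters counts 5
  five <- list(residues = data.frame(type = "A", resno = 1, chain = "A",
                                     x = 0, y = 0, z = 0, theta = 0),
               waters = data.frame(resno = 101:105, chain = "A",
                                   x = 10 * (1:5), y = 8, z = 0))
  expect_equal(count_waters(synth_toy_structure(five)), 5)
  # hub plan: n_waters inner + n_waters outer, arginine on top
  p5 <- synth_toy_structure(toy_structure_plan("hub", n_waters = 5))
  expect_equal(count_waters(p5), 10)
  g <- build_hbond_graph(p5)
  expect_equal(names(which.max(betweenness_centrality(g))), "A:1:R")
})

test_that("realized column entropies track their targets", {
  targets <- c(0, 0.35, log(2), 1.5, 2.2, log(20))
  msa <- synth_msa(200, targets, seed = 21, tree_shape = "caterpillar")
  realized <- vapply(seq_along(targets),
                     function(i) position_entropy(msa$aln, i), 0)
  expect_true(all(abs(realized - targets) < 0.05))
  truth <- utils::read.csv(msa$truth)
  expect_equal(truth$target_entropy, targets, tolerance = 1e-9)
})

test_that("a clade-split column maps to exactly the root-edge substitution", {
  msa <- synth_msa(8, list(0, list(type = "clade_split", left = "R",
                                   right = "I")),
                   seed = 5, tree_shape = "balanced")
  sub <- branch_substitutions(msa$aln, msa$tree, 2)
  expect_equal(nrow(sub), 1)
  root <- ape::Ntip(msa$tree) + 1L
  expect_equal(sub$parent_node, root)
  expect_false(sub$child_is_tip)
})
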