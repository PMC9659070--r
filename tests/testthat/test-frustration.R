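# Native contacts and the decoy frustration z-score.

test_that("contacts form within the centroid cutoff and respect |i-j| >= 2", {
  at <- rbind(place_residue("A", 1, c(0, 0, 0)),
              place_residue("A", 2, c(2, 2, 0)),    # adjacent in sequence
              place_residue("A", 3, c(5, 0, 0)),
              place_residue("A", 10, c(30, 0, 0)))  # 25 A away
  f <- tempfile(fileext = ".pdb")
  write_pdb_file(at, f, check_clash = 0)
  ct <- native_contacts(f, cutoff = 6.5)
  expect_equal(nrow(ct), 1)                         # only 1-3
  expect_equal(c(ct$resno_i, ct$resno_j), c(1, 3))
  expect_equal(ct$distance, 5, tolerance = 1e-6)
  # single residue: empty contact list
  one <- tempfile(fileext = ".pdb")
  write_pdb_file(place_residue("A", 1, c(0, 0, 0)), one, check_clash = 0)
  expect_equal(nrow(native_contacts(one)), 0)
})

test_that("burial density separates direct from water-mediated contacts", {
  path <- synth_toy_structure(toy_structure_plan("contacts"))
  ct <- native_contacts(path)
  buried <- ct[ct$resno_i == 1 & ct$resno_j == 3, ]
  surface <- ct[ct$resno_i == 50 & ct$resno_j == 52, ]
  expect_equal(buried$distance, surface$distance, tolerance = 1e-9)
  expect_identical(buried$contact_class, "direct")
  expect_identical(surface$contact_class, "water_mediated")
  # beyond direct_cutoff contacts class as long
  lg <- native_contacts(path, cutoff = 9, direct_cutoff = 5)
  expect_true("long" %in% lg$contact_class)
})

test_that("the frustration score is the z-score against the decoy set", {
  # symmetric two-level potential whose analytic decoy mean is easy: K-K
  # pairs score 1, everything else 0
  pot <- function(a, b) as.numeric(a == "K" && b == "K")
  ex <- decoy_frustration_index("K", "K", potential = pot, exhaustive = TRUE)
  m <- 1 / 400
  s <- sqrt(m * (1 - m))
  expect_equal(ex$decoy_mean, m, tolerance = 1e-12)
  expect_equal(ex$decoy_sd, s, tolerance = 1e-12)
  expect_equal(ex$delta_e_fr, (1 - m) / s, tolerance = 1e-12)
  # a native pair scoring exactly the decoy mean has dEfr 0
  pot0 <- function(a, b) 0.5
  expect_error(decoy_frustration_index("A", "A", potential = pot0,
                                       exhaustive = TRUE), "degenerate")
  potm <- default_contact_potential()
  grid <- expand.grid(a = amino_acids(), b = amino_acids(),
                      stringsAsFactors = FALSE)
  e <- mapply(potm, grid$a, grid$b)
  mid <- which.min(abs(e - mean(e)))
  r0 <- decoy_frustration_index(grid$a[mid], grid$b[mid], exhaustive = TRUE)
  expect_equal(r0$delta_e_fr, unname(e[mid] - mean(e)) / r0$decoy_sd,
               tolerance = 1e-12)
})

test_that("feeding the decoy set back through the score gives mean 0 / SD 1", {
  pot <- default_contact_potential()
  grid <- expand.grid(a = amino_acids(), b = amino_acids(),
                      stringsAsFactors = FALSE)
  z <- vapply(seq_len(nrow(grid)), function(k) {
    decoy_frustration_index(grid$a[k], grid$b[k], potential = pot,
                            exhaustive = TRUE)$delta_e_fr
  }, 0)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-10)
})

test_that("sampled decoys agree with exhaustive enumeration within 3 SE", {
  ex <- decoy_frustration_index("K", "D", exhaustive = TRUE)
  sm <- decoy_frustration_index("K", "D", n_decoys = 10000, seed = 17)
  se <- 1 / sqrt(10000)   # SE of a standardized mean
  expect_lt(abs(sm$delta_e_fr - ex$delta_e_fr),
            3 * se * max(1, abs(ex$delta_e_fr)))
  # deterministic under a fixed seed
  sm2 <- decoy_frustration_index("K", "D", n_decoys = 10000, seed = 17)
  expect_identical(sm$delta_e_fr, sm2$delta_e_fr)
  expect_error(decoy_frustration_index("K", "D", n_decoys = 50, seed = 1),
               ">= 100")
})

test_that("the score is invariant under affine rescaling of the potential", {
  pot <- default_contact_potential()
  pot2 <- function(a, b) 7 * pot(a, b) - 3
  r1 <- decoy_frustration_index("E", "R", potential = pot, exhaustive = TRUE)
  r2 <- decoy_frustration_index("E", "R", potential = pot2, exhaustive = TRUE)
  expect_equal(r1$delta_e_fr, r2$delta_e_fr, tolerance = 1e-10)
})

test_that("classification thresholds the index and ranks stressed residues", {
  res <- data.frame(resno_i = 1:3, type_i = "A", resno_j = 11:13,
                    type_j = "A", delta_e_fr = c(0, 0, 0))
  cl <- classify_frustration(res, hi = 0.78, lo = -1)
  expect_true(all(cl$contacts$label == "neutral"))
  res$delta_e_fr <- c(3, -2, 0.5)
  cl2 <- classify_frustration(res)
  expect_identical(cl2$contacts$label, c("highly", "minimally", "neutral"))
  expect_error(classify_frustration(res, hi = -2, lo = 0), "hi > lo")
  # a ring of stressed contacts puts the hub residue on top
  ring <- data.frame(resno_i = 57, type_i = "D",
                     resno_j = c(18, 34, 35, 37, 38, 94),
                     type_j = "R", delta_e_fr = 3)
  other <- data.frame(resno_i = 100, type_i = "A", resno_j = 103,
                      type_j = "A", delta_e_fr = 3)
  cl3 <- classify_frustration(rbind(ring, other))
  expect_equal(cl3$per_residue$residue[1], 57)
  expect_equal(cl3$per_residue$n_highly[1], 6)
})

test_that("frustration maps are reproducible and attach per-contact scores", {
  path <- synth_toy_structure(toy_structure_plan("contacts"))
  ct <- native_contacts(path)
  m1 <- frustration_map(ct, n_decoys = 200, seed = 5)
  m2 <- frustration_map(ct, n_decoys = 200, seed = 5)
  expect_identical(m1$delta_e_fr, m2$delta_e_fr)
  expect_true(all(is.finite(m1$delta_e_fr)))
})
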