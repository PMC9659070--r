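# SASA computation and the SASA - log(PF) calibration / ALPF calling.

test_that("an isolated atom's SASA equals the inflated-sphere closed form", {
  s <- atom_sasa(matrix(0, 1, 3), radii = 1.52, probe = 1.4)
  expect_equal(s, 4 * pi * (1.52 + 1.4)^2, tolerance = 1e-9)
  s2 <- atom_sasa(matrix(0, 1, 3), radii = 2, probe = 0.5)
  expect_equal(s2, 4 * pi * 2.5^2, tolerance = 1e-9)
})

test_that("an isolated residue matches its free reference value", {
  path <- synth_toy_structure(
    list(residues = data.frame(type = "A", resno = 1, chain = "A",
                               x = 0, y = 0, z = 0, theta = 0),
         waters = NULL))
  s <- residue_sasa(path)
  expect_equal(s$sasa, free_reference_sasa("A"), tolerance = 0.02)
})

test_that("three-residue SASA agrees with the Monte-Carlo surface oracle", {
  path <- synth_toy_structure(toy_structure_plan("trimer"))
  tab <- pdb_atom_table(path)
  mc <- oracle_sasa_mc(tab$xyz, tab$radii, probe = 1.4, n_mc = 1e5,
                       seed = 99)
  got <- atom_sasa(tab$xyz, tab$radii, probe = 1.4)
  # compare per residue (sidechain = CB for alanine)
  for (r in unique(tab$at$resno)) {
    sel <- tab$at$resno == r & !(tab$at$elety %in% c("N", "CA", "C", "O"))
    expect_equal(sum(got[sel]), sum(mc[sel]), tolerance = 0.03)
  }
  res <- residue_sasa(path)
  sel <- !(tab$at$elety %in% c("N", "CA", "C", "O"))
  expect_equal(sum(res$sasa), sum(got[sel]), tolerance = 1e-9)
})

test_that("occlusion only lowers SASA and chains are validated", {
  path <- synth_toy_structure(toy_structure_plan("trimer"))
  res <- residue_sasa(path)
  free <- free_reference_sasa("A")
  expect_true(all(res$sasa <= free * 1.0001))
  expect_error(residue_sasa(path, chain = "B"), "available: A")
  # whole-residue mode includes the backbone
  all_mode <- residue_sasa(path, mode = "all")
  expect_true(all(all_mode$sasa > res$sasa))
})

test_that("collinear calibration points fit exactly with a vanishing band", {
  fit <- fit_sasa_logpf(c(0, 10, 20), c(0, -1, -2))
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_equal(fit$pearson_r, -1, tolerance = 1e-12)
  band <- predict(fit, c(5, 15))
  expect_equal(band$upr - band$lwr, c(0, 0), tolerance = 1e-9)
  expect_error(fit_sasa_logpf(c(0, 10), c(0, -1)), "at least 3")
  expect_error(fit_sasa_logpf(rep(5, 5), 1:5), "degenerate")
})

test_that("the fitted slope's confidence interval has near-nominal coverage", {
  set.seed(2024)
  hits <- 0
  for (i in 1:100) {
    x <- runif(30, 0, 100)
    y <- 1 - 0.05 * x + rnorm(30, 0, 0.2)
    fit <- fit_sasa_logpf(x, y)
    ci <- confint(fit$lm, "sasa", level = 0.95)
    if (ci[1] <= -0.05 && -0.05 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("regression responds to shifts only through the intercept", {
  set.seed(5)
  x <- runif(20, 0, 50)
  y <- -0.04 * x + rnorm(20, 0, 0.1)
  f1 <- fit_sasa_logpf(x, y)
  f2 <- fit_sasa_logpf(x, y + 3)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f2$intercept - f1$intercept, 3, tolerance = 1e-9)
})

test_that("planted outliers below the band are called anomalous, exactly", {
  # 23-point fixture: 20 calibration points exactly on the relation (the
  # band collapses onto the line) plus 3 planted outliers 5 sigma below
  n <- 20
  x <- seq(5, 100, length.out = n)
  sigma <- 0.15
  y <- 2 - 0.03 * x
  fit <- fit_sasa_logpf(x, y)
  planted <- data.frame(residue = 101:103, sasa = c(20, 50, 80))
  planted$logPF <- (2 - 0.03 * planted$sasa) - 5 * sigma
  normals <- data.frame(residue = seq_len(n), sasa = x, logPF = y)
  calls <- classify_alpf(rbind(normals, planted), fit)
  expect_identical(calls$status[calls$residue %in% 101:103],
                   rep("anomalous_low", 3))
  # on-line points are never strictly below the band
  expect_equal(sum(calls$status == "anomalous_low"), 3)
  # order invariance
  set.seed(1)
  shuffled <- classify_alpf(rbind(planted, normals)[sample(n + 3), ], fit)
  expect_equal(sort(shuffled$residue[shuffled$status == "anomalous_low"]),
               101:103)
  # with noisy calibration, narrowing the band level only grows the set
  set.seed(7)
  yn <- y + rnorm(n, 0, sigma)
  fitn <- fit_sasa_logpf(x, yn)
  pts <- rbind(data.frame(residue = seq_len(n), sasa = x, logPF = yn),
               planted)
  calls95 <- classify_alpf(pts, fitn, level = 0.95)
  calls80 <- classify_alpf(pts, fitn, level = 0.80)
  expect_true(all(calls95$residue[calls95$status == "anomalous_low"] %in%
                    calls80$residue[calls80$status == "anomalous_low"]))
  # a point ten band-widths below the line is anomalous under the noisy fit
  bw <- predict(fitn, 50)
  deep <- data.frame(residue = 300, sasa = 50,
                     logPF = bw$fit - 10 * (bw$fit - bw$lwr))
  expect_identical(classify_alpf(deep, fitn)$status, "anomalous_low")
  # records without SASA stay unclassified
  suppressMessages(
    nc <- classify_alpf(data.frame(residue = 1, sasa = NA, logPF = 0), fit))
  expect_identical(nc$status, "not_classified")
})

test_that("state deltas recover planted shifts and flag substitutions", {
  a <- data.frame(residue = 1:6, residue_type = c("D", "D", "E", "K", "M", "F"),
                  logPF = c(1, 2, 3, 4, 5, 6), sasa = 10 * (1:6))
  expect_error(delta_metrics(a, data.frame(residue = 100:101)), "shared")
  same <- delta_metrics(a, a)
  expect_true(all(same$per_residue$delta_logpf == 0))
  b <- a
  b$logPF <- a$logPF - 0.3
  b$residue_type[1] <- "K"   # position-matched substitution (13D/K style)
  d <- delta_metrics(a, b, groups = list(polar = 1:4, nonpolar = 5:6))
  expect_true(all(abs(d$per_residue$delta_logpf - 0.3) < 1e-12))
  expect_true(d$per_residue$substituted[1])
  gs <- d$group_summary
  expect_equal(gs$mean[gs$group == "polar" & gs$metric == "delta_logpf"], 0.3)
  expect_equal(gs$sd[gs$group == "polar" & gs$metric == "delta_logpf"], 0)
  # planted per-group shifts recovered exactly
  b2 <- a
  b2$logPF[1:4] <- a$logPF[1:4] - 1.5
  b2$logPF[5:6] <- a$logPF[5:6] + 0.25
  d2 <- delta_metrics(a, b2, groups = list(polar = 1:4, nonpolar = 5:6))
  g2 <- d2$group_summary
  expect_equal(g2$mean[g2$group == "polar" & g2$metric == "delta_logpf"], 1.5)
  expect_equal(g2$mean[g2$group == "nonpolar" & g2$metric == "delta_logpf"],
               -0.25)
})
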