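# Protein-water hydrogen-bond network construction and centrality.

two_waters_pdb <- function(sep) {
  at <- rbind(place_water(1, c(0, 0, 0)), place_water(2, c(sep, 0, 0)))
  f <- tempfile(fileext = ".pdb")
  write_pdb_file(at, f)
  f
}

test_that("water counting handles toy structures and chain assignment", {
  at <- rbind(place_residue("A", 1, c(0, 0, 0), chain = "A"),
              place_residue("A", 1, c(40, 0, 0), chain = "B"),
              place_water(101, c(3, 3, 3), chain = "A"),
              place_water(102, c(4, -3, 0), chain = "A"),
              place_water(103, c(43, 0, 3), chain = "W"))  # nearest chain B
  f <- tempfile(fileext = ".pdb")
  write_pdb_file(at, f)
  expect_equal(count_waters(f), 3)
  expect_equal(count_waters(f, chain = "A"), 2)
  expect_equal(count_waters(f, chain = "B"), 1)
  expect_error(count_waters(f, chain = "Z"), "available")
  # waterless structure
  dry <- synth_toy_structure(toy_structure_plan("trimer"))
  expect_equal(count_waters(dry), 0)
})

test_that("hydrogen bonds form within 3.5 A and not beyond", {
  g1 <- build_hbond_graph(two_waters_pdb(2.8))
  expect_equal(igraph::ecount(g1), 1)
  expect_equal(igraph::E(g1)$distance, 2.8, tolerance = 1e-6)
  g2 <- suppressWarnings(build_hbond_graph(two_waters_pdb(3.6)))
  expect_equal(igraph::ecount(g2), 0)
  # raising d_max never removes edges
  g3 <- build_hbond_graph(two_waters_pdb(3.6), d_max = 4.5)
  expect_equal(igraph::ecount(g3), 1)
})

test_that("a planted Ser-water-Asp bridge is recovered as a 2-edge path", {
  path <- synth_toy_structure(toy_structure_plan("bridge"))
  g <- build_hbond_graph(path)
  ed <- igraph::as_data_frame(g, "edges")
  expect_equal(nrow(ed), 2)
  expect_true("HOH:101" %in% c(ed$from, ed$to))
  sp <- igraph::distances(g, v = "A:1:S", to = "A:3:D")
  expect_equal(as.numeric(sp), 2)
  expect_equal(sort(ed$distance), c(2.9, 3.0), tolerance = 1e-6)
  # spectator lysine is present but unconnected
  expect_true("A:20:K" %in% igraph::V(g)$name)
  expect_equal(igraph::degree(g, "A:20:K"), c("A:20:K" = 0))
})

test_that("graph construction is invariant to atom order in the file", {
  plan <- toy_structure_plan("hub", n_waters = 4)
  p1 <- synth_toy_structure(plan)
  # rewrite with atom records shuffled
  lines <- readLines(p1)
  atoms <- grep("^(ATOM|HETATM)", lines)
  set.seed(3)
  lines[atoms] <- lines[sample(atoms)]
  # serial numbers must stay ordered for bio3d; renumber
  lines[atoms] <- sprintf("%s%5d%s", substr(lines[atoms], 1, 6),
                          seq_along(atoms), substr(lines[atoms], 12, 100))
  p2 <- tempfile(fileext = ".pdb")
  writeLines(lines, p2)
  g1 <- build_hbond_graph(p1)
  g2 <- build_hbond_graph(p2)
  e1 <- igraph::as_data_frame(g1, "edges")
  e2 <- igraph::as_data_frame(g2, "edges")
  canon <- function(e) {
    key <- ifelse(e$from < e$to, paste(e$from, e$to), paste(e$to, e$from))
    e <- e[order(key), c("from", "to", "distance")]
    rownames(e) <- NULL
    e
  }
  expect_equal(canon(e1), canon(e2), tolerance = 1e-6)
})

test_that("betweenness matches hand counts on a path and a star", {
  path3 <- igraph::make_graph(~ A - B - C)
  bc <- betweenness_centrality(path3)
  expect_equal(bc[["B"]], 1)
  expect_equal(bc[["A"]], 0)
  expect_equal(bc[["C"]], 0)
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  expect_equal(betweenness_centrality(star)[1], 6)  # C(4,2) leaf pairs
  expect_error(betweenness_centrality(igraph::make_empty_graph(0)), "empty")
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, p = 0.4)
    got <- betweenness_centrality(adj_to_igraph(adj))
    expect_equal(unname(got), oracle_betweenness(adj), tolerance = 1e-9)
  }
})

test_that("tree betweenness totals match the pair-path count", {
  # on a tree every connected pair has exactly one path; summing Cbw over
  # nodes counts each pair once per intermediate node
  tree <- igraph::make_tree(9, children = 2, mode = "undirected")
  bc <- betweenness_centrality(tree)
  adj <- as.matrix(igraph::as_adjacency_matrix(tree))
  oracle <- oracle_betweenness(adj)
  expect_equal(unname(bc), oracle, tolerance = 1e-9)
  expect_equal(sum(bc), sum(oracle))
})

test_that("the planted hub dominates betweenness and group ratios exceed 1", {
  path <- synth_toy_structure(toy_structure_plan("hub", n_waters = 6))
  g <- build_hbond_graph(path)
  bc <- betweenness_centrality(g)
  expect_equal(names(which.max(bc)), "A:1:R")
  # detected residue at the hub vs undetected serines on the arms
  groups <- data.frame(
    node = c("A:1:R", paste0("A:", 11:16, ":S")),
    label = c("low", rep("not_detected", 6)))
  st <- group_centrality_stats(bc, groups)
  expect_gt(st$ratio, 1)
})

test_that("group statistics average correctly and propagate ratio error", {
  prof <- c(a = 4, b = 6, c = 1, d = 3)
  st <- group_centrality_stats(prof, c(a = "low", b = "normal",
                                       c = "not_detected",
                                       d = "not_detected"))
  expect_equal(st$by_group$mean[st$by_group$label == "not_detected"], 2)
  expect_equal(st$ratio, 5 / 2)
  # constant profile: ratio 1, zero SDs
  prof2 <- c(a = 5, b = 5, c = 5, d = 5)
  st2 <- group_centrality_stats(prof2, c(a = "low", b = "normal",
                                         c = "not_detected",
                                         d = "not_detected"))
  expect_equal(st2$ratio, 1)
  expect_equal(st2$ratio_se, 0)
  # absent nodes are logged, not imputed
  suppressMessages(
    st3 <- group_centrality_stats(prof, c(a = "low", zz = "not_detected")))
  expect_equal(st3$missing, "zz")
  expect_true(is.na(st3$ratio))
  # merged-network mode averages ratios across structures
  m <- merged_ratio(list(st, st2))
  expect_equal(m$ratio, mean(c(5 / 2, 1)))
})
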