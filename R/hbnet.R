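# Protein-water hydrogen-bond network analysis. Nodes are residue
# sidechains and crystallographic waters; edges are donor/acceptor
# heavy-atom pairs within the distance cutoff (3.5 A default). Crystal
# structures usually lack hydrogens, so the angular criterion (60 deg)
# applies only when hydrogen positions are present in the file.

# sidechain donor/acceptor heavy atoms (N and O) per residue type,
# plus the water oxygen
.polar_sidechain_atoms <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = c("NZ"),
  HIS = c("ND1", "NE2"),
  SER = c("OG"),
  THR = c("OG1"),
  TYR = c("OH"),
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  ASN = c("OD1", "ND2"),
  GLN = c("OE1", "NE2"),
  TRP = c("NE1"),
  MET = character(0),
  CYS = character(0))

#' Count crystallographic waters in a structure
#'
#' Counts HOH residues. When a protein chain is given, each water is
#' assigned to the protein chain owning its nearest protein atom
#' (crystallographic water chain labels are unreliable) and only the
#' requested chain's waters are counted.
#'
#' @param structure Path to a PDB file or a `bio3d` `pdb` object.
#' @param chain Protein chain id, or `NULL` (default) for all waters.
#' @return Integer water count (0 for waterless structures).
#' @export
count_waters <- function(structure, chain = NULL) {
  pdb <- .load_structure(structure)
  at <- pdb$atom
  wat <- at[toupper(at$resid) %in% c("HOH", "WAT"), , drop = FALSE]
  wat <- wat[grepl("^O", wat$elety), , drop = FALSE]  # one record per water
  if (nrow(wat) == 0) return(0L)
  key <- paste(wat$chain, wat$resno, wat$insert)
  wat <- wat[!duplicated(key), , drop = FALSE]
  if (is.null(chain)) return(nrow(wat))
  prot <- .protein_atoms(pdb)
  if (nrow(prot) == 0) stop("no protein atoms for chain assignment",
                            call. = FALSE)
  if (!chain %in% prot$chain) {
    stop("chain '", chain, "' not found; available: ",
         paste(sort(unique(prot$chain)), collapse = ", "), call. = FALSE)
  }
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  wxyz <- as.matrix(wat[, c("x", "y", "z")])
  owner <- vapply(seq_len(nrow(wat)), function(i) {
    d2 <- colSums((t(pxyz) - wxyz[i, ])^2)
    prot$chain[which.min(d2)]
  }, "")
  sum(owner == chain)
}

#' Build the protein-water hydrogen-bond graph
#'
#' An undirected edge joins every pair of donor/acceptor heavy atoms
#' (sidechain N/O, water O) within `d_max`, collapsed to one edge per
#' node pair (minimum distance kept). Backbone atoms are excluded. When
#' hydrogen positions exist in the file, an edge additionally requires some
#' donor hydrogen within `angle_max` of the donor-acceptor axis; otherwise
#' the distance criterion alone applies. Only model 1 of multi-model files
#' is used (bio3d default). Isolated water nodes are dropped from the
#' graph (they still count in [count_waters()]).
#'
#' @param structure Path to a PDB file or `bio3d` `pdb` object.
#' @param d_max Donor-acceptor heavy-atom distance cutoff (A), default 3.5.
#' @param angle_max Donor-H-acceptor deviation cutoff in degrees (default
#'   60); applied only when hydrogens are present.
#' @param chain Optional chain restriction for the protein residues.
#' @return An `igraph` graph (class also `hb_graph`) whose vertices carry
#'   `name` ("A:57:D" style for residues, "HOH:203" for waters), `kind`
#'   ("residue"/"water"), `chain`, `resno`, `residue_type`; edges carry
#'   `distance`, `atom1`, `atom2`.
#' @export
build_hbond_graph <- function(structure, d_max = 3.5, angle_max = 60,
                              chain = NULL) {
  stopifnot(d_max > 0)
  pdb <- .load_structure(structure)
  prot <- .protein_atoms(pdb, chain)
  polar <- if (nrow(prot) == 0) prot else
    prot[mapply(function(res, ety) {
      ety %in% (.polar_sidechain_atoms[[toupper(res)]] %||% character(0))
    }, prot$resid, prot$elety), , drop = FALSE]
  at <- pdb$atom
  wat <- at[toupper(at$resid) %in% c("HOH", "WAT") & grepl("^O", at$elety), ,
            drop = FALSE]
  nodes_atoms <- rbind(
    if (nrow(polar)) data.frame(
      node = paste(polar$chain, polar$resno, aa3to1(polar$resid), sep = ":"),
      kind = "residue", chain = polar$chain, resno = polar$resno,
      residue_type = aa3to1(polar$resid), atom = polar$elety,
      x = polar$x, y = polar$y, z = polar$z, stringsAsFactors = FALSE),
    if (nrow(wat)) data.frame(
      node = paste("HOH", wat$resno, sep = ":"),
      kind = "water", chain = wat$chain, resno = wat$resno,
      residue_type = "HOH", atom = "O",
      x = wat$x, y = wat$y, z = wat$z, stringsAsFactors = FALSE))
  if (is.null(nodes_atoms) || nrow(nodes_atoms) == 0) {
    warning("no polar atoms found; returning empty graph")
    g <- igraph::make_empty_graph(directed = FALSE)
    class(g) <- c("hb_graph", class(g))
    return(g)
  }
  # hydrogens (if any) attached to polar atoms, for the angle criterion
  hyd <- at[at$type %in% c("ATOM", "HETATM") &
              (toupper(at$elesy) %in% "H" | grepl("^[0-9]*H", at$elety)), ,
            drop = FALSE]
  use_angle <- nrow(hyd) > 0

  xyz <- as.matrix(nodes_atoms[, c("x", "y", "z")])
  n <- nrow(nodes_atoms)
  edges <- list()
  d <- as.matrix(stats::dist(xyz))
  ord <- nodes_atoms$node
  for (i in seq_len(n - 1)) {
    js <- which(d[i, ] <= d_max)
    js <- js[js > i & nodes_atoms$node[js] != nodes_atoms$node[i]]
    for (j in js) {
      if (use_angle && !.hb_angle_ok(nodes_atoms[i, ], nodes_atoms[j, ],
                                     hyd, angle_max)) next
      edges[[length(edges) + 1L]] <- data.frame(
        from = nodes_atoms$node[i], to = nodes_atoms$node[j],
        distance = d[i, j], atom1 = nodes_atoms$atom[i],
        atom2 = nodes_atoms$atom[j], stringsAsFactors = FALSE)
    }
  }
  nd <- nodes_atoms[!duplicated(nodes_atoms$node),
                    c("node", "kind", "chain", "resno", "residue_type")]
  if (length(edges) == 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = character(), to = character()),
      directed = FALSE, vertices = nd)
  } else {
    ed <- do.call(rbind, edges)
    # collapse parallel atom-pair edges: keep the shortest per node pair
    pair <- ifelse(ed$from < ed$to, paste(ed$from, ed$to),
                   paste(ed$to, ed$from))
    ed <- ed[order(pair, ed$distance), ]
    ed <- ed[!duplicated(ifelse(ed$from < ed$to, paste(ed$from, ed$to),
                                paste(ed$to, ed$from))), ]
    g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nd)
  }
  # drop isolated waters
  iso <- igraph::V(g)[igraph::degree(g) == 0 &
                        igraph::V(g)$kind == "water"]
  g <- igraph::delete_vertices(g, iso)
  class(g) <- c("hb_graph", class(g))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.hb_angle_ok <- function(a1, a2, hyd, angle_max) {
  # accept the bond if either endpoint has an attached hydrogen within
  # angle_max of the donor->acceptor axis (or if neither has hydrogens)
  for (swap in list(c(1, 2), c(2, 1))) {
    don <- if (swap[1] == 1) a1 else a2
    acc <- if (swap[1] == 1) a2 else a1
    hs <- hyd[hyd$chain == don$chain & hyd$resno == don$resno, , drop = FALSE]
    if (nrow(hs) == 0) next
    dv <- c(acc$x - don$x, acc$y - don$y, acc$z - don$z)
    for (k in seq_len(nrow(hs))) {
      hv <- c(hs$x[k] - don$x, hs$y[k] - don$y, hs$z[k] - don$z)
      if (sqrt(sum(hv^2)) > 1.6) next   # not covalently attached
      cosang <- sum(dv * hv) / sqrt(sum(dv^2) * sum(hv^2))
      if (acos(pmin(pmax(cosang, -1), 1)) * 180 / pi <= angle_max) {
        return(TRUE)
      }
    }
  }
  # no attached hydrogens found on either side: fall back to distance-only
  no_h <- nrow(hyd[hyd$chain == a1$chain & hyd$resno == a1$resno, ]) == 0 &&
    nrow(hyd[hyd$chain == a2$chain & hyd$resno == a2$resno, ]) == 0
  no_h
}

#' Betweenness centrality of the hydrogen-bond network
#'
#' For each node n, the sum over unordered node pairs (excluding n) of the
#' fraction of shortest paths between the pair that pass through n, with
#' unit edge weights and no normalization. Disconnected pairs contribute 0;
#' leaves score 0.
#'
#' @param graph An `hb_graph` (any undirected `igraph` works).
#' @param normalized Divide by the number of node pairs (for cross-graph
#'   comparison); default `FALSE` (raw counts).
#' @return Named numeric vector, one value per node.
#' @export
betweenness_centrality <- function(graph, normalized = FALSE) {
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  # edges carry a "distance" attribute but no "weight": unit edge weights
  igraph::betweenness(graph, directed = FALSE, normalized = normalized)
}

#' Group statistics of centrality values over XFMS residue groups
#'
#' Summarizes node centrality by residue group (typically low-PF / normal /
#' not-detected). "Detected" is the union of the `low` and `normal`
#' groups; the detected/undetected ratio is the ratio of group means with
#' error propagated from the standard errors of the means.
#'
#' @param profile Named centrality vector from [betweenness_centrality()].
#' @param groups Named character vector or data frame (`node`, `label`)
#'   mapping node names to labels in {`low`, `normal`, `not_detected`}.
#'   Nodes absent from the graph are logged and excluded (no zero
#'   imputation).
#' @return List with `by_group` (label, mean, sd, n),
#'   `ratio` (detected/undetected mean ratio), `ratio_se` (propagated),
#'   and `missing` (group nodes absent from the graph).
#' @export
group_centrality_stats <- function(profile, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$label), groups$node)
  }
  missing <- setdiff(names(groups), names(profile))
  if (length(missing)) {
    message(length(missing), " group node(s) absent from graph: ",
            paste(missing, collapse = ", "))
  }
  groups <- groups[names(groups) %in% names(profile)]
  labs <- sort(unique(groups))
  by_group <- do.call(rbind, lapply(labs, function(l) {
    v <- profile[names(groups)[groups == l]]
    data.frame(label = l, mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  det <- profile[names(groups)[groups %in% c("low", "normal")]]
  und <- profile[names(groups)[groups == "not_detected"]]
  if (length(det) && length(und) && mean(und) > 0) {
    m_d <- mean(det); m_u <- mean(und)
    se_d <- if (length(det) > 1) stats::sd(det) / sqrt(length(det)) else 0
    se_u <- if (length(und) > 1) stats::sd(und) / sqrt(length(und)) else 0
    ratio <- m_d / m_u
    ratio_se <- ratio * sqrt((se_d / m_d)^2 + (se_u / m_u)^2)
  } else {
    ratio <- NA_real_; ratio_se <- NA_real_
  }
  list(by_group = by_group, ratio = ratio, ratio_se = ratio_se,
       missing = missing)
}

#' Merged detected/undetected ratio across several structures
#'
#' Averages the detected/undetected centrality ratio over the networks of
#' several structures (e.g. the two inactive-state crystal forms), with the
#' spread across structures as the uncertainty.
#'
#' @param stats_list List of results from [group_centrality_stats()].
#' @return List with `ratio` (mean across structures) and `ratio_sd`.
#' @export
merged_ratio <- function(stats_list) {
  r <- vapply(stats_list, function(s) s$ratio, 0)
  list(ratio = mean(r), ratio_sd = if (length(r) > 1) stats::sd(r) else 0)
}
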