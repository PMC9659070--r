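# Synthetic inputs with known ground truth for every stage of the
# toolkit: dose-response tables (MASCOT-style identifications + LC-MS peak
# lists), toy PDB structures with planted hydrogen-bond geometry, and
# alignments/trees with planted column entropies. One seed threads every
# generator; outputs are canonically ordered so identical calls are
# byte-identical.

.default_dose_grid <- c(0, 0.01, 0.025, 0.06, 0.15, 0.4, 1, 2.5)

#' Synthetic dose-response study (identification + peak tables)
#'
#' Generates a MASCOT-style identification table, an LC-MS peak list per
#' dose point and a ground-truth table, consistent with per-residue
#' oxidized fractions F = 1 - exp(-PF * IR * dose) plus optional Gaussian
#' noise on F. Nearby target residues share a tryptic-style peptide (so
#' multi-site oxidation aggregation is exercised); each peptide form gets a
#' distinct m/z, charge-state duplicates included for the first form.
#'
#' @param true_pf Data frame with columns `residue` (1-based index),
#'   `residue_type` (one-letter) and `pf` (> 0), or a named numeric vector
#'   of PFs with names like `"57K"`.
#' @param ir Named IR vector covering all residue types in `true_pf`.
#' @param doses Increasing numeric dose grid (default: the package's
#'   8-point log-spaced study grid).
#' @param sigma Gaussian SD added to each F (>= 0; F is clamped to [0, 1]).
#' @param seed Integer seed (all randomness is local to the call).
#' @param dir Output directory (created if needed).
#' @param total_area Total peptide-form area per dose (arbitrary units).
#' @return Invisibly, list of file paths: `ids`, `peaks`, `truth`.
#' @export
synth_dose_series <- function(true_pf, ir = ir_table(),
                              doses = .default_dose_grid,
                              sigma = 0, seed = 1, dir = tempfile("doseset"),
                              total_area = 1000) {
  if (is.numeric(true_pf) && !is.null(names(true_pf))) {
    true_pf <- data.frame(
      residue = as.integer(gsub("[A-Z]", "", names(true_pf))),
      residue_type = gsub("[0-9]", "", names(true_pf)),
      pf = unname(true_pf), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(true_pf),
            all(c("residue", "residue_type", "pf") %in% names(true_pf)))
  if (any(true_pf$pf <= 0)) stop("PF values must be > 0", call. = FALSE)
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  miss <- setdiff(true_pf$residue_type, names(ir))
  if (length(miss)) stop("no IR for residue type(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)

  tp <- true_pf[order(true_pf$residue), , drop = FALSE]
  # group residues within 8 positions into one peptide
  pep_id <- cumsum(c(1, diff(tp$residue) > 8))
  ids_rows <- list(); peak_rows <- list(); truth_rows <- list()
  for (p in unique(pep_id)) {
    sub <- tp[pep_id == p, , drop = FALSE]
    start <- min(sub$residue) - 2L
    end <- max(sub$residue) + 2L
    if (start < 1) { end <- end + (1L - start); sub$residue <- sub$residue +
      (1L - start); start <- 1L }
    pep <- rep("A", end - start + 1L)
    pep[sub$residue - start + 1L] <- sub$residue_type
    pep <- paste(pep, collapse = "")
    rt <- 5 + 2 * p
    base_mz <- 300 + 50 * p
    # unoxidized form (two charge states to exercise summation)
    ids_rows[[length(ids_rows) + 1L]] <- data.frame(
      peptide = pep, start = start, mod_residue = NA_integer_,
      rt = rt, mz = base_mz, charge = 2)
    ids_rows[[length(ids_rows) + 1L]] <- data.frame(
      peptide = pep, start = start, mod_residue = NA_integer_,
      rt = rt, mz = base_mz + 20, charge = 3)
    for (k in seq_len(nrow(sub))) {
      ids_rows[[length(ids_rows) + 1L]] <- data.frame(
        peptide = pep, start = start, mod_residue = sub$residue[k],
        rt = rt, mz = base_mz + 2 * k, charge = 2)
    }
    s_true <- unname(unlist(ir[sub$residue_type])) * sub$pf
    for (d in doses) {
      f <- 1 - exp(-s_true * d)
      if (sigma > 0) f <- pmin(pmax(f + stats::rnorm(length(f), 0, sigma), 0), 1)
      if (sum(f) > 1 + 1e-12) {
        stop("infeasible: summed oxidized fractions exceed 1 within one ",
             "peptide; lower doses or PFs", call. = FALSE)
      }
      a_ox <- f * total_area
      a_unox <- max(total_area - sum(a_ox), 0)
      # unoxidized area split over the two charge states
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        dose_id = d, rt = rt, mz = base_mz, area = 0.6 * a_unox)
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        dose_id = d, rt = rt, mz = base_mz + 20, area = 0.4 * a_unox)
      for (k in seq_len(nrow(sub))) {
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          dose_id = d, rt = rt, mz = base_mz + 2 * k, area = a_ox[k])
      }
    }
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      residue = sub$residue, residue_type = sub$residue_type,
      pf = sub$pf, S = s_true, peptide = pep, start = start)
  }
  ids <- do.call(rbind, ids_rows)
  peaks <- do.call(rbind, peak_rows)
  truth <- do.call(rbind, truth_rows)
  paths <- list(ids = file.path(dir, "ids.csv"),
                peaks = file.path(dir, "peaks.csv"),
                truth = file.path(dir, "truth.csv"))
  utils::write.csv(ids, paths$ids, row.names = FALSE, quote = FALSE)
  utils::write.csv(peaks, paths$peaks, row.names = FALSE, quote = FALSE)
  utils::write.csv(truth, paths$truth, row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Geometry plans for synthetic toy structures
#'
#' Prebuilt placement plans for [synth_toy_structure()]:
#' \describe{
#'   \item{`bridge`}{Ser and Asp sidechains bridged by one water
#'     (Ser OG - 2.9 A - HOH - 3.0 A - Asp OD1), plus a distant spectator
#'     lysine: plants a 2-edge path through the water node.}
#'   \item{`hub`}{A central arginine whose guanidinium contacts
#'     `n_waters` waters; each of those waters hydrogen-bonds onward to a
#'     peripheral serine which in turn bonds a second, outer water
#'     (2 * n_waters waters in total). Plants the arginine as the
#'     top-betweenness node, with every non-leaf arm node scoring > 0.}
#'   \item{`contacts`}{A buried leucine pair inside a shell of alanines and
#'     an isolated surface leucine pair at the same separation: plants the
#'     burial-dependent direct / water-mediated contact classes.}
#'   \item{`trimer`}{Three alanines in a row (SASA fixtures).}
#' }
#'
#' @param name One of `"bridge"`, `"hub"`, `"contacts"`, `"trimer"`.
#' @param n_waters Number of waters for the `hub` plan (default 6).
#' @return A plan list understood by [synth_toy_structure()]: elements
#'   `residues` (data frame: type, resno, chain, x, y, z, theta) and
#'   `waters` (data frame: resno, chain, x, y, z).
#' @export
toy_structure_plan <- function(name = c("bridge", "hub", "contacts",
                                        "trimer"),
                               n_waters = 6) {
  name <- match.arg(name)
  res <- function(type, resno, x, y, z, theta = 0, chain = "A") {
    data.frame(type = type, resno = resno, chain = chain,
               x = x, y = y, z = z, theta = theta, stringsAsFactors = FALSE)
  }
  wat <- function(resno, x, y, z, chain = "A") {
    data.frame(resno = resno, chain = chain, x = x, y = y, z = z)
  }
  og <- .template_offset("SER", "OG")
  if (name == "bridge") {
    # plant Ser OG -- 2.9 A -- water -- 3.0 A -- Asp OD1 exactly, with the
    # aspartate rotated so OD2 points away from the water
    w <- c(20, 0, 0)
    ca_ser <- w - c(2.9, 0, 0) - og
    rot <- .rotation_z(pi)
    od1_rot <- as.numeric(rot %*% .template_offset("ASP", "OD1"))
    ca_asp <- w + c(3.0, 0, 0) - od1_rot
    plan <- list(
      residues = rbind(res("S", 1, ca_ser[1], ca_ser[2], ca_ser[3]),
                       res("D", 3, ca_asp[1], ca_asp[2], ca_asp[3],
                           theta = pi),
                       res("K", 20, 20, 25, 0)),
      waters = wat(101, w[1], w[2], w[3]))
    return(c(plan, list(name = name)))
  }
  if (name == "hub") {
    if (n_waters > 6) stop("hub plan supports at most 6 waters",
                           call. = FALSE)
    # inner waters on octahedron directions around the arginine NH1 tip
    # at 3.3 A (adjacent waters 4.7 A apart: no water-water bonds); one
    # serine behind each water at 2.8 A along the same direction, and an
    # outer water 2.8 A beyond each serine OG so that every arm is the
    # 4-node chain R - water - Ser - water
    nh1 <- .template_offset("ARG", "NH1")
    s2 <- sqrt(0.5)
    dirs <- list(c(s2, s2, 0), c(-s2, s2, 0), c(s2, -s2, 0),
                 c(-s2, -s2, 0), c(0, 0, 1), c(0, 0, -1))
    w <- do.call(rbind, lapply(seq_len(n_waters), function(i) {
      p <- nh1 + 3.3 * dirs[[i]]
      q <- nh1 + (3.3 + 2.8 + 2.8) * dirs[[i]]
      rbind(wat(100 + i, p[1], p[2], p[3]),
            wat(200 + i, q[1], q[2], q[3]))
    }))
    sers <- do.call(rbind, lapply(seq_len(n_waters), function(i) {
      ogp <- nh1 + (3.3 + 2.8) * dirs[[i]]
      ca <- ogp - og
      res("S", 10 + i, ca[1], ca[2], ca[3])
    }))
    return(list(residues = rbind(res("R", 1, 0, 0, 0), sers),
                waters = w, name = name))
  }
  if (name == "contacts") {
    # buried pair: two leucines (sidechain centroids exactly 6 A apart)
    # ringed by 8 alanines whose CB centroids sit 6.5 A from the contact
    # midpoint; surface pair: identical geometry, no shell
    leu_cen <- Reduce(`+`, lapply(c("CB", "CG", "CD1", "CD2"),
                                  function(a) .template_offset("LEU", a))) / 4
    mid <- c(3, 0, 0) + leu_cen
    cb <- .template_offset("ALA", "CB")
    shell <- do.call(rbind, lapply(seq_len(8), function(i) {
      a <- 2 * pi * (i - 1) / 8
      ca <- mid + 6.5 * c(cos(a), sin(a), 0) - cb
      res("A", 30 + i, ca[1], ca[2], ca[3])
    }))
    plan <- list(
      residues = rbind(res("L", 1, 0, 0, 0),          # buried pair
                       res("L", 3, 6, 0, 0),
                       shell,
                       res("L", 50, 60, 0, 0),        # surface pair
                       res("L", 52, 66, 0, 0)),
      waters = NULL, name = name)
    return(plan)
  }
  list(residues = rbind(res("A", 1, 0, 0, 0), res("A", 2, 6, 0, 0),
                        res("A", 3, 12, 0, 0)),
       waters = NULL, name = name)
}

#' Write a synthetic toy structure as a PDB file
#'
#' Realizes a geometry plan (residue templates at planted positions, water
#' oxygens) as a valid PDB file, aborting on steric overlap (< 1 A between
#' atoms of different residues).
#'
#' @param plan A plan from [toy_structure_plan()], or any list with
#'   `residues` / `waters` data frames in that format.
#' @param path Output PDB path (default: a tempfile).
#' @param seed Unused by the deterministic plans; kept so all generators
#'   share a calling convention.
#' @return The path, invisibly.
#' @export
synth_toy_structure <- function(plan, path = tempfile(fileext = ".pdb"),
                                seed = 1) {
  at <- do.call(rbind, lapply(seq_len(nrow(plan$residues)), function(i) {
    r <- plan$residues[i, ]
    rot <- if (!is.null(r$theta) && r$theta != 0) .rotation_z(r$theta) else NULL
    place_residue(r$type, r$resno, origin = c(r$x, r$y, r$z),
                  chain = r$chain, rot = rot)
  }))
  if (!is.null(plan$waters) && nrow(plan$waters) > 0) {
    at <- rbind(at, do.call(rbind, lapply(seq_len(nrow(plan$waters)),
      function(i) {
        w <- plan$waters[i, ]
        place_water(w$resno, c(w$x, w$y, w$z), chain = w$chain)
      })))
  }
  write_pdb_file(at, path)
  invisible(path)
}

#' Synthetic multiple sequence alignment with planted column entropies
#'
#' Draws alignment columns to hit target Shannon entropies: for each
#' column, a letter-frequency distribution with the requested entropy is
#' constructed (a two-level distribution over the smallest sufficient
#' alphabet, solved numerically), realized as deterministic letter counts,
#' and assigned to sequences in a seeded random order. Special plan
#' entries plant clade-specific columns consistent with the tree.
#'
#' @param n_seq Number of sequences.
#' @param entropy_plan Either a numeric vector of per-column target
#'   entropies in `[0, log(20)]` nats, or a list whose elements are
#'   numbers (targets) or `list(type = "clade_split", left = "R",
#'   right = "I")` for a column that separates the two halves of the tree.
#' @param tree_shape `"balanced"` (n_seq a power of 2) or `"caterpillar"`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Invisibly, list of paths: `fasta`, `newick`, `truth`, plus the
#'   realized alignment matrix (`aln`) and tree (`tree`).
#' @export
synth_msa <- function(n_seq, entropy_plan, tree_shape = c("balanced",
                                                          "caterpillar"),
                      seed = 1, dir = tempfile("msa")) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_seq >= 2)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  if (is.numeric(entropy_plan)) entropy_plan <- as.list(entropy_plan)
  ids <- sprintf("seq%03d", seq_len(n_seq))
  tree <- if (tree_shape == "balanced") {
    if (bitwAnd(n_seq, n_seq - 1L) != 0) {
      stop("balanced tree requires n_seq to be a power of 2", call. = FALSE)
    }
    ape::stree(n_seq, type = "balanced")
  } else {
    ape::stree(n_seq, type = "left")
  }
  tree$tip.label <- ids
  tree$edge.length <- rep(1, nrow(tree$edge))
  nc <- length(entropy_plan)
  aln <- matrix("", n_seq, nc, dimnames = list(ids, NULL))
  truth <- data.frame(column = seq_len(nc), target_entropy = NA_real_,
                      kind = "entropy", stringsAsFactors = FALSE)
  half <- seq_len(floor(n_seq / 2))
  for (j in seq_len(nc)) {
    e <- entropy_plan[[j]]
    if (is.list(e) && identical(e$type, "clade_split")) {
      aln[half, j] <- e$left
      aln[-half, j] <- e$right
      truth$kind[j] <- "clade_split"
      truth$target_entropy[j] <- .column_entropy(aln[, j])
      next
    }
    target <- as.numeric(e)
    if (target < 0 || target > log(20)) {
      stop("entropy target out of [0, log(20)] at column ", j, call. = FALSE)
    }
    counts <- .entropy_counts(target, n_seq)
    if (is.null(counts)) {
      stop("infeasible entropy ", signif(target, 4), " for n_seq = ", n_seq,
           " at column ", j, call. = FALSE)
    }
    letters20 <- .aa1[seq_along(counts)]
    col <- rep(letters20, counts)
    aln[, j] <- col[sample.int(n_seq)]
    truth$target_entropy[j] <- target
  }
  paths <- list(fasta = file.path(dir, "alignment.fasta"),
                newick = file.path(dir, "tree.nwk"),
                truth = file.path(dir, "truth.csv"))
  lines <- as.vector(rbind(paste0(">", ids),
                           apply(aln, 1, paste, collapse = "")))
  writeLines(lines, paths$fasta)
  ape::write.tree(tree, paths$newick)
  utils::write.csv(truth, paths$truth, row.names = FALSE, quote = FALSE)
  invisible(c(paths, list(aln = aln, tree = tree)))
}

# integer letter counts over the smallest sufficient alphabet whose
# realized (plug-in) entropy approximates the target; returns NULL when
# infeasible (fewer sequences than needed distinct letters)
.entropy_counts <- function(target, n) {
  if (target == 0) return(n)
  k <- max(2L, ceiling(exp(target) - 1e-9))
  if (k > 20 || k > n) return(NULL)
  # distribution family: p on letter 1, (1-p)/(k-1) on the rest
  h <- function(p) {
    q <- (1 - p) / (k - 1)
    -(p * log(p) + (1 - p) * ifelse(q > 0, log(q), 0))
  }
  p <- if (abs(target - log(k)) < 1e-12) 1 / k else
    stats::uniroot(function(p) h(p) - target, c(1 / k, 1 - 1e-9))$root
  probs <- c(p, rep((1 - p) / (k - 1), k - 1))
  counts <- round(probs * n)
  counts[counts == 0] <- 1L
  # fix rounding so counts sum to n (adjust the largest class)
  counts[1] <- counts[1] + (n - sum(counts))
  if (counts[1] < 1) return(NULL)
  counts
}
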