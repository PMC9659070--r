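# Decoy-based contact frustration. Each native residue-residue contact is
# scored by a pairwise contact potential and compared, as a z-score, with
# the distribution of energies obtained by randomizing the identities of
# the two residues while keeping the geometry fixed:
#
#   dEfr = (E_native - mean(E_decoy)) / sd(E_decoy)
#
# Note the sign: positive means the native pair is LESS favorable than a
# typical decoy (an energetically stressed contact). The canonical
# Frustratometer index uses the opposite sign.

#' Default pairwise contact potential
#'
#' A simple documented statistical stand-in: the negative product of
#' Kyte-Doolittle hydropathy values (favoring hydrophobic-hydrophobic
#' pairs, as burial-driven contact potentials do) plus a same-charge
#' penalty / opposite-charge reward for the ionizable types (D, E vs K, R;
#' H treated as neutral). Units are arbitrary; the frustration z-score is
#' invariant to affine rescaling of the potential, and any user potential
#' can be supplied to [decoy_frustration_index()].
#'
#' @return A function `f(type_i, type_j)` returning a scalar energy,
#'   defined for all 400 ordered one-letter type pairs and symmetric.
#' @export
default_contact_potential <- function() {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  q <- c(D = -1, E = -1, K = 1, R = 1)
  function(a, b) {
    e <- -kd[[a]] * kd[[b]] / 10
    qa <- if (a %in% names(q)) q[[a]] else 0
    qb <- if (b %in% names(q)) q[[b]] else 0
    e + qa * qb
  }
}

#' Native residue contacts of a structure
#'
#' Contacts are residue pairs whose sidechain heavy-atom centroids (CA for
#' glycine) lie within `cutoff`, at least 2 apart in sequence. Each contact
#' is classed by distance and local burial: within `direct_cutoff` the pair
#' is `direct` when buried (at least `density_threshold` other residue
#' centroids within `density_radius` of the contact midpoint, leaving no
#' room for an intervening water) and `water_mediated` when exposed;
#' between `direct_cutoff` and `cutoff` it is `long`.
#'
#' @param structure Path to a PDB file or `bio3d` `pdb` object.
#' @param cutoff Centroid-centroid cutoff (A), default 6.5.
#' @param chain Optional chain restriction.
#' @param direct_cutoff Distance bound for short-range contacts (default
#'   equal to `cutoff`, i.e. all in-cutoff contacts are short-range).
#' @param density_threshold Burial threshold: number of neighboring
#'   centroids within `density_radius` of the midpoint (default 6).
#' @param density_radius Radius for the burial count (A), default 8.
#' @return Data frame of class `contact_pairs`: `resno_i`, `type_i`,
#'   `resno_j`, `type_j` (i < j), `distance`, `burial`, `contact_class`.
#' @export
native_contacts <- function(structure, cutoff = 6.5, chain = NULL,
                            direct_cutoff = cutoff, density_threshold = 6,
                            density_radius = 8) {
  stopifnot(cutoff > 0)
  pdb <- .load_structure(structure)
  at <- .protein_atoms(pdb, chain)
  if (nrow(at) == 0) stop("no protein atoms in structure", call. = FALSE)
  key <- paste(at$chain, at$resno, sep = "|")
  cen <- lapply(split(seq_len(nrow(at)), key), function(idx) {
    sub <- at[idx, , drop = FALSE]
    side <- !(sub$elety %in% .backbone_atoms) |
      (toupper(sub$resid[1]) == "GLY" & sub$elety == "CA")
    use <- if (any(side)) sub[side, , drop = FALSE] else sub
    c(x = mean(use$x), y = mean(use$y), z = mean(use$z),
      resno = sub$resno[1])
  })
  first <- match(names(cen), key)
  cdf <- data.frame(resno = at$resno[first], chain = at$chain[first],
                    type = aa3to1(at$resid[first]),
                    do.call(rbind, cen)[, c("x", "y", "z"), drop = FALSE],
                    stringsAsFactors = FALSE)
  cdf <- cdf[order(cdf$chain, cdf$resno), ]
  n <- nrow(cdf)
  if (n < 2) {
    return(structure(data.frame(resno_i = integer(), type_i = character(),
                                resno_j = integer(), type_j = character(),
                                distance = numeric(), burial = integer(),
                                contact_class = character()),
                     class = c("contact_pairs", "data.frame")))
  }
  xyz <- as.matrix(cdf[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (cdf$chain[i] == cdf$chain[j] &&
          abs(cdf$resno[i] - cdf$resno[j]) < 2) next
      if (d[i, j] > cutoff) next
      mid <- (xyz[i, ] + xyz[j, ]) / 2
      others <- setdiff(seq_len(n), c(i, j))
      burial <- sum(sqrt(colSums((t(xyz[others, , drop = FALSE]) - mid)^2))
                    <= density_radius)
      cls <- if (d[i, j] > direct_cutoff) {
        "long"
      } else if (burial >= density_threshold) "direct" else "water_mediated"
      rows[[length(rows) + 1L]] <- data.frame(
        resno_i = cdf$resno[i], type_i = cdf$type[i],
        resno_j = cdf$resno[j], type_j = cdf$type[j],
        distance = d[i, j], burial = burial, contact_class = cls,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(resno_i = integer(), type_i = character(),
               resno_j = integer(), type_j = character(),
               distance = numeric(), burial = integer(),
               contact_class = character())
  class(out) <- c("contact_pairs", class(out))
  out
}

#' Decoy frustration index of one contact
#'
#' Draws decoys by substituting both residue identities uniformly at
#' random over the 20 amino-acid types (geometry fixed) and returns the
#' z-score of the native energy against the decoy distribution (population
#' standard deviation, so feeding the decoy set back through the score
#' gives mean 0, SD 1). `exhaustive = TRUE` enumerates all 400 ordered
#' pairs instead of sampling and is seed-independent.
#'
#' @param type_i,type_j Native one-letter residue types.
#' @param potential Pairwise energy function `f(a, b)`; default
#'   [default_contact_potential()].
#' @param n_decoys Number of sampled decoys (>= 100), default 1000.
#' @param seed Integer seed for the decoy draw (required when sampling).
#' @param exhaustive Enumerate all 400 type pairs instead of sampling.
#' @return List of class `frustration_result`: `type_i`, `type_j`,
#'   `e_native`, `decoy_mean`, `decoy_sd`, `delta_e_fr`, `n_decoys`,
#'   `seed`.
#' @export
decoy_frustration_index <- function(type_i, type_j,
                                    potential = default_contact_potential(),
                                    n_decoys = 1000, seed = NULL,
                                    exhaustive = FALSE) {
  e_native <- potential(type_i, type_j)
  if (exhaustive) {
    grid <- expand.grid(a = .aa1, b = .aa1, stringsAsFactors = FALSE)
    e_dec <- mapply(potential, grid$a, grid$b)
    n_used <- nrow(grid)
  } else {
    if (n_decoys < 100) stop("n_decoys must be >= 100", call. = FALSE)
    if (is.null(seed)) stop("seed required for sampled decoys", call. = FALSE)
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old))
    set.seed(seed)
    a <- sample(.aa1, n_decoys, replace = TRUE)
    b <- sample(.aa1, n_decoys, replace = TRUE)
    e_dec <- mapply(potential, a, b)
    n_used <- n_decoys
  }
  m <- mean(e_dec)
  s <- sqrt(mean((e_dec - m)^2))   # population SD (Eq. z-score self-test)
  if (s == 0) stop("degenerate decoy distribution (constant potential)",
                   call. = FALSE)
  out <- list(type_i = type_i, type_j = type_j, e_native = e_native,
              decoy_mean = m, decoy_sd = s,
              delta_e_fr = (e_native - m) / s,
              n_decoys = n_used, seed = if (exhaustive) NA_integer_ else seed)
  class(out) <- "frustration_result"
  out
}

#' @export
print.frustration_result <- function(x, ...) {
  cat(sprintf("contact %s-%s: E_native = %.4g, decoys %.4g +/- %.4g (n=%d), dEfr = %.3f\n",
              x$type_i, x$type_j, x$e_native, x$decoy_mean, x$decoy_sd,
              x$n_decoys, x$delta_e_fr))
  invisible(x)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Frustration index for every native contact of a structure
#'
#' @param contacts A `contact_pairs` data frame from [native_contacts()].
#' @param potential Pairwise energy function.
#' @param n_decoys,seed,exhaustive As in [decoy_frustration_index()];
#'   sampled mode uses `seed + k` for the k-th contact so contacts are
#'   independent but the whole run is reproducible.
#' @return `contacts` with added columns `e_native`, `decoy_mean`,
#'   `decoy_sd`, `delta_e_fr`.
#' @export
frustration_map <- function(contacts,
                            potential = default_contact_potential(),
                            n_decoys = 1000, seed = NULL,
                            exhaustive = FALSE) {
  res <- lapply(seq_len(nrow(contacts)), function(k) {
    decoy_frustration_index(contacts$type_i[k], contacts$type_j[k],
                            potential = potential, n_decoys = n_decoys,
                            seed = if (is.null(seed)) NULL else seed + k,
                            exhaustive = exhaustive)
  })
  contacts$e_native <- vapply(res, `[[`, 0, "e_native")
  contacts$decoy_mean <- vapply(res, `[[`, 0, "decoy_mean")
  contacts$decoy_sd <- vapply(res, `[[`, 0, "decoy_sd")
  contacts$delta_e_fr <- vapply(res, `[[`, 0, "delta_e_fr")
  contacts
}

#' Classify contacts by frustration index
#'
#' Thresholds the z-score: `highly` (stressed) above `hi`, `minimally`
#' below `lo`, `neutral` between. The defaults (hi = 0.78, lo = -1) are
#' the conventional frustration cutoffs adjusted for this package's sign
#' convention (native minus decoy mean); they are configuration, not
#' values from any one study.
#'
#' @param results Data frame with a `delta_e_fr` column (e.g. from
#'   [frustration_map()]).
#' @param hi,lo Thresholds, `hi > lo`.
#' @return List with `contacts` (input plus `label`) and `per_residue`
#'   (residue, n_highly, n_minimally, n_neutral), ranked by the count of
#'   stressed contacts.
#' @export
classify_frustration <- function(results, hi = 0.78, lo = -1) {
  stopifnot(hi > lo)
  lab <- ifelse(results$delta_e_fr > hi, "highly",
                ifelse(results$delta_e_fr < lo, "minimally", "neutral"))
  results$label <- lab
  res_ids <- sort(unique(c(results$resno_i, results$resno_j)))
  per <- do.call(rbind, lapply(res_ids, function(r) {
    sel <- results$resno_i == r | results$resno_j == r
    data.frame(residue = r,
               n_highly = sum(lab[sel] == "highly"),
               n_minimally = sum(lab[sel] == "minimally"),
               n_neutral = sum(lab[sel] == "neutral"))
  }))
  if (!is.null(per)) per <- per[order(-per$n_highly, per$residue), ]
  list(contacts = results, per_residue = per)
}
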