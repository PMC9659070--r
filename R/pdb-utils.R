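# Minimal idealized residue geometries and fixed-width PDB writing.
# Templates carry heavy atoms only, with ~1.5 A bonds and clash-free local
# geometry; they exist so synthetic structures with planted properties
# (H-bond bridges, buried contacts, water counts) can be generated in code.

# offsets (A) relative to CA at the origin; backbone in the z = 0 plane,
# sidechain extending into -z
.bb <- list(N = c(-0.74, 1.20, 0.00), CA = c(0, 0, 0),
            C = c(1.52, 0.00, 0.00), O = c(2.20, 1.00, 0.00))
.cb <- c(-0.54, -0.78, -1.20)

.chain_from_cb <- function(n) {
  # zigzag extension of n atoms beyond CB, step ~1.5 A
  dirs <- list(c(0.45, -0.70, -1.23), c(-0.45, -0.75, -1.20))
  pos <- list()
  cur <- .cb
  for (i in seq_len(n)) {
    cur <- cur + dirs[[(i - 1) %% 2 + 1]]
    pos[[i]] <- cur
  }
  pos
}

.templates <- local({
  t <- list()
  t$GLY <- .bb
  t$ALA <- c(.bb, list(CB = .cb))
  sc <- .chain_from_cb(4)
  t$SER <- c(.bb, list(CB = .cb, OG = sc[[1]]))
  t$CYS <- c(.bb, list(CB = .cb, SG = sc[[1]]))
  t$THR <- c(.bb, list(CB = .cb, OG1 = sc[[1]],
                       CG2 = .cb + c(-1.25, -0.60, -0.55)))
  t$VAL <- c(.bb, list(CB = .cb, CG1 = sc[[1]],
                       CG2 = .cb + c(-1.25, -0.60, -0.55)))
  t$LEU <- c(.bb, list(CB = .cb, CG = sc[[1]],
                       CD1 = sc[[1]] + c(1.10, -0.55, -0.75),
                       CD2 = sc[[1]] + c(-1.10, -0.55, -0.75)))
  t$ILE <- c(.bb, list(CB = .cb, CG1 = sc[[1]],
                       CG2 = .cb + c(-1.25, -0.60, -0.55),
                       CD1 = sc[[2]]))
  t$ASP <- c(.bb, list(CB = .cb, CG = sc[[1]],
                       OD1 = sc[[1]] + c(1.05, -0.45, -0.55),
                       OD2 = sc[[1]] + c(-1.05, -0.45, -0.55)))
  t$ASN <- c(.bb, list(CB = .cb, CG = sc[[1]],
                       OD1 = sc[[1]] + c(1.05, -0.45, -0.55),
                       ND2 = sc[[1]] + c(-1.05, -0.45, -0.55)))
  t$GLU <- c(.bb, list(CB = .cb, CG = sc[[1]], CD = sc[[2]],
                       OE1 = sc[[2]] + c(1.05, -0.45, -0.55),
                       OE2 = sc[[2]] + c(-1.05, -0.45, -0.55)))
  t$GLN <- c(.bb, list(CB = .cb, CG = sc[[1]], CD = sc[[2]],
                       OE1 = sc[[2]] + c(1.05, -0.45, -0.55),
                       NE2 = sc[[2]] + c(-1.05, -0.45, -0.55)))
  t$MET <- c(.bb, list(CB = .cb, CG = sc[[1]], SD = sc[[2]], CE = sc[[3]]))
  t$LYS <- c(.bb, list(CB = .cb, CG = sc[[1]], CD = sc[[2]], CE = sc[[3]],
                       NZ = sc[[4]]))
  t$ARG <- c(.bb, list(CB = .cb, CG = sc[[1]], CD = sc[[2]], NE = sc[[3]],
                       CZ = sc[[4]],
                       NH1 = sc[[4]] + c(1.10, -0.40, -0.55),
                       NH2 = sc[[4]] + c(-1.10, -0.40, -0.55)))
  # flat six-ring for the aromatics, hanging off CG
  ring <- function(cg) {
    u <- c(0.0, -0.62, -1.08)   # ring plane axis 1 (step 1.25 A-ish)
    v <- c(1.20, -0.25, 0.12)   # ring plane axis 2
    list(CG = cg, CD1 = cg + u + v, CD2 = cg + u - v,
         CE1 = cg + 2 * u + v, CE2 = cg + 2 * u - v, CZ = cg + 3 * u)
  }
  t$PHE <- c(.bb, list(CB = .cb), ring(sc[[1]]))
  rt <- ring(sc[[1]])
  t$TYR <- c(.bb, list(CB = .cb), rt, list(OH = rt$CZ + c(0, -0.75, -1.18)))
  t$HIS <- c(.bb, list(CB = .cb, CG = sc[[1]],
                       ND1 = sc[[1]] + c(1.10, -0.45, -0.60),
                       CD2 = sc[[1]] + c(-1.10, -0.45, -0.60),
                       CE1 = sc[[1]] + c(0.72, -1.20, -1.45),
                       NE2 = sc[[1]] + c(-0.72, -1.20, -1.45)))
  t$TRP <- c(.bb, list(CB = .cb, CG = sc[[1]],
                       CD1 = sc[[1]] + c(1.15, -0.45, -0.55),
                       CD2 = sc[[1]] + c(-1.00, -0.55, -0.70),
                       NE1 = sc[[1]] + c(1.05, -1.25, -1.35),
                       CE2 = sc[[1]] + c(-0.25, -1.40, -1.55),
                       CE3 = sc[[1]] + c(-2.30, -0.65, -0.80),
                       CZ2 = sc[[1]] + c(-0.85, -2.45, -2.30),
                       CZ3 = sc[[1]] + c(-2.90, -1.70, -1.60),
                       CH2 = sc[[1]] + c(-2.15, -2.55, -2.35)))
  t$PRO <- c(.bb, list(CB = .cb, CG = sc[[1]],
                       CD = .bb$N + c(-0.80, -0.85, -1.05)))
  t
})

.template_offset <- function(type3, atom) {
  tpl <- .templates[[toupper(type3)]]
  if (is.null(tpl) || is.null(tpl[[atom]])) {
    stop("no template offset for ", type3, " ", atom, call. = FALSE)
  }
  tpl[[atom]]
}

.element_of <- function(atom_name) {
  # heavy-atom element from a PDB atom name (first non-digit character)
  substr(gsub("[0-9]", "", atom_name), 1, 1)
}

#' Place an idealized residue in space
#'
#' @param type One- or three-letter residue type.
#' @param resno Residue number.
#' @param origin Numeric xyz of the CA position.
#' @param chain Chain identifier.
#' @param rot Optional 3x3 rotation matrix applied to the template.
#' @return Data frame of atoms: `resno`, `resid`, `chain`, `elety`,
#'   `elesy`, `x`, `y`, `z`, `hetatm`.
#' @export
place_residue <- function(type, resno, origin = c(0, 0, 0), chain = "A",
                          rot = NULL) {
  type3 <- if (nchar(type) == 1) aa1to3(type) else toupper(type)
  tpl <- .templates[[type3]]
  if (is.null(tpl)) stop("no geometry template for residue type ", type,
                         call. = FALSE)
  xyz <- do.call(rbind, tpl)
  if (!is.null(rot)) xyz <- xyz %*% t(rot)
  xyz <- sweep(xyz, 2, origin, "+")
  data.frame(resno = resno, resid = type3, chain = chain,
             elety = names(tpl), elesy = .element_of(names(tpl)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             hetatm = FALSE, stringsAsFactors = FALSE)
}

#' Place a water molecule (oxygen only, as in typical crystal structures)
#'
#' @param resno Water residue number.
#' @param origin xyz of the oxygen.
#' @param chain Chain identifier.
#' @return One-row atom data frame as in [place_residue()].
#' @export
place_water <- function(resno, origin, chain = "A") {
  data.frame(resno = resno, resid = "HOH", chain = chain,
             elety = "O", elesy = "O",
             x = origin[1], y = origin[2], z = origin[3],
             hetatm = TRUE, stringsAsFactors = FALSE)
}

.rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Write an atom table as a PDB file
#'
#' @param atoms Data frame as produced by [place_residue()] /
#'   [place_water()] (rows are concatenated with `rbind`).
#' @param path Output path.
#' @param check_clash Minimum allowed inter-residue heavy-atom distance (A);
#'   closer pairs abort with a steric-overlap error. Set to 0 to skip.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(atoms, path, check_clash = 1.0) {
  if (check_clash > 0 && nrow(atoms) > 1) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    same <- outer(paste(atoms$chain, atoms$resno),
                  paste(atoms$chain, atoms$resno), "==")
    d[same] <- Inf
    if (any(d < check_clash)) {
      stop(sprintf("steric overlap: inter-residue atom distance %.2f A < %.2f A",
                   min(d), check_clash), call. = FALSE)
    }
  }
  rec <- ifelse(atoms$hetatm, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(atoms$elety) >= 4, atoms$elety,
                  sprintf(" %-3s", atoms$elety))
  lines <- sprintf("%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(atoms)), name4, atoms$resid, atoms$chain,
                   atoms$resno, atoms$x, atoms$y, atoms$z, 1.00, 0.00,
                   atoms$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
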