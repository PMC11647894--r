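#' @title Cellulose nanocrystal construction and PDB I/O
#' @name crystal
#' @description Builds idealized cellulose Ibeta and II nanocrystals of
#'   configurable size from packaged unit-cell templates, reads and writes
#'   PDB files, selects central chains, and classifies chain parity
#'   (origin vs center).
NULL

#' Unit-cell template for a cellulose polymorph
#'
#' Lattice constants follow the experimentally determined unit cells of
#' cellulose Ibeta (monoclinic, two parallel chains per cell) and cellulose II
#' (monoclinic, origin and center chains antiparallel).  The atomic content of
#' the template is an idealized, synthetic anhydroglucose geometry generated
#' by \code{\link{glucose_template}}; it reproduces the connectivity, chain
#' packing, screw symmetry, and chain-direction pattern of the polymorphs,
#' not the experimental atomic coordinates.
#'
#' @param form \code{"Ibeta"} or \code{"II"}.
#' @return A list with lattice constants \code{a}, \code{b}, \code{c}
#'   (Angstrom), \code{gamma} (degrees), the per-residue rise \code{c/2},
#'   the chain-direction rule (\code{antiparallel}), and a provenance note.
#' @export
unit_cell_template <- function(form = c("Ibeta", "II")) {
  form <- match.arg(form)
  if (form == "Ibeta") {
    list(form = "Ibeta", a = 7.784, b = 8.201, c = 10.380, gamma = 96.5,
         rise = 10.380 / 2, antiparallel = FALSE,
         setting_deg = c(origin = 30, center = 0),
         provenance = paste("Synthetic idealized template; lattice constants",
                            "from the published Ibeta crystal structure."))
  } else {
    list(form = "II", a = 8.10, b = 9.03, c = 10.31, gamma = 117.1,
         rise = 10.31 / 2, antiparallel = TRUE,
         setting_deg = c(origin = 30, center = 30),
         provenance = paste("Synthetic idealized template; lattice constants",
                            "from the published cellulose II crystal",
                            "structure."))
  }
}

#' Idealized local geometry of one anhydroglucose unit
#'
#' Constructs a synthetic beta-glucose residue in a local frame whose z axis
#' is the chain axis: a puckered six-membered ring (C1, C2, C3, C4, C5, O5),
#' the hydroxyl branches O2/O3/O6 with their hydrogens, the glycosidic O4
#' placed to bridge C4 of this residue and C1 of the preceding residue at the
#' given rise, and aliphatic hydrogens.  Cap atoms for chain termini (HO4 at
#' the non-reducing end; O1 and HO1 at the reducing end) are returned
#' separately.  The geometry is an idealization with standard bond lengths;
#' it is not an experimental structure.
#'
#' @param rise Per-residue translation along the chain axis in Angstrom
#'   (half the c lattice constant).
#' @return List with data frames \code{interior} (21 atoms) and \code{caps}
#'   (HO4, O1, HO1).
#' @export
glucose_template <- function(rise = 5.19) {
  p <- 0.25            # ring pucker amplitude (A)
  rad <- 1.45          # ring circumradius (A)
  unit <- function(v) v / sqrt(sum(v^2))

  ring_names <- c("C1", "C2", "C3", "C4", "C5", "O5")
  th <- (0:5) * pi / 3
  ring <- cbind(x = p * (-1)^(0:5), y = rad * sin(th), z = rad * cos(th))
  rownames(ring) <- ring_names
  u <- cbind(0, sin(th), cos(th))      # radial unit vectors at ring positions
  rownames(u) <- ring_names
  sx <- sign(ring[, "x"])              # pucker side of each ring atom

  place <- function(base, dir, len) base + len * unit(dir)

  # hydroxyl branches O2 and O3: roughly equatorial
  O2 <- place(ring["C2", ], u["C2", ] + c(-sx["C2"] * 0.4, 0, 0), 1.43)
  O3 <- place(ring["C3", ], u["C3", ] + c(-sx["C3"] * 0.4, 0, 0), 1.43)
  HO3 <- place(O3, 0.5 * u["C3", ] + c(0, 0, -0.87), 0.96)

  # exocyclic arm: O6 is placed so that the screw-related next residue's O6
  # sits ~2.8 A from this residue's O2, emulating the O2-H...O6 intrachain
  # hydrogen bond of the crystal; HO2 points along that bond
  u_hb <- unit(c(0.1, 0.3, 0.95))
  o6_img <- O2 + 2.8 * u_hb - c(0, 0, rise)   # next-residue frame image
  O6 <- c(-o6_img[1], -o6_img[2], o6_img[3])  # undo the screw flip
  HO2 <- O2 + 0.96 * u_hb
  # C6 closes the C5-C6-O6 triangle with standard bond lengths
  v <- O6 - ring["C5", ]
  dvo <- sqrt(sum(v^2))
  cosb <- (1.52^2 + dvo^2 - 1.43^2) / (2 * 1.52 * dvo)
  cosb <- min(1, max(-1, cosb))
  u0 <- v / dvo
  perp <- c(1, 0, 0) - sum(c(1, 0, 0) * u0) * u0
  perp <- unit(perp)
  C6 <- ring["C5", ] + 1.52 * (cosb * u0 + sqrt(1 - cosb^2) * perp)
  HO6 <- place(O6, c(-0.2, -0.85, -0.5), 0.96)

  # glycosidic O4 bridges C4 of this residue and C1 of the previous residue
  c1_prev <- c(-ring["C1", "x"], -ring["C1", "y"], ring["C1", "z"] - rise)
  mid <- (ring["C4", ] + c1_prev) / 2
  half <- sqrt(sum((ring["C4", ] - c1_prev)^2)) / 2
  if (half >= 1.43)
    stop("rise too large for glycosidic bridge geometry")
  O4 <- mid + c(0, -sqrt(1.43^2 - half^2), 0)

  H1 <- place(ring["C1", ], c(sx["C1"], 0, 0), 1.10)
  H2 <- place(ring["C2", ], c(sx["C2"], 0, 0), 1.10)
  H3 <- place(ring["C3", ], c(sx["C3"], 0, 0), 1.10)
  H4 <- place(ring["C4", ], c(sx["C4"], 0, 0), 1.10)
  H5 <- place(ring["C5", ], c(sx["C5"], 0, 0), 1.10)
  H61 <- place(C6, c(0.9, -0.2, 0.25), 1.10)
  H62 <- place(C6, c(-0.9, -0.2, 0.25), 1.10)

  coords <- rbind(ring, O2 = O2, HO2 = HO2, O3 = O3, HO3 = HO3,
                  C6 = C6, O6 = O6, HO6 = HO6, O4 = O4,
                  H1 = H1, H2 = H2, H3 = H3, H4 = H4, H5 = H5,
                  H61 = H61, H62 = H62)
  interior <- data.frame(name = rownames(coords),
                         element = substr(rownames(coords), 1, 1),
                         x = coords[, 1], y = coords[, 2], z = coords[, 3],
                         row.names = NULL, stringsAsFactors = FALSE)

  HO4 <- O4 + c(0, -0.96, 0)
  O1 <- place(ring["C1", ], c(-sx["C1"] * 0.3, 0, 1), 1.43)
  HO1 <- O1 + c(0, 0.96, 0)
  caps <- data.frame(name = c("HO4", "O1", "HO1"),
                     element = c("H", "O", "H"),
                     x = c(HO4[1], O1[1], HO1[1]),
                     y = c(HO4[2], O1[2], HO1[2]),
                     z = c(HO4[3], O1[3], HO1[3]),
                     stringsAsFactors = FALSE)
  list(interior = interior, caps = caps)
}

# pool of single-character chain identifiers (PDB chain column)
.chain_id_pool <- function(n) {
  single <- c(LETTERS, letters, as.character(0:9))
  if (n <= length(single)) return(single[seq_len(n)])
  # two-character scheme for large crystals; full id is carried in the PDB
  # segid field and restored on read
  two <- as.vector(outer(LETTERS, LETTERS, function(a, b) paste0(a, b)))
  c(single, two)[seq_len(n)]
}

#' Build an idealized cellulose nanocrystal
#'
#' Places \code{n_chains} cellulose chains of \code{dp} glucose units each on
#' the two-chain lattice of the requested polymorph.  Chains occupy origin
#' and center lattice sites; center chains are shifted by a quarter cell
#' along the chain axis and, for cellulose II, run antiparallel to the origin
#' chains.  The lateral habit is compact: of all candidate lattice sites, the
#' \code{n_chains} closest to the lattice centroid are used, which for 52
#' chains yields the roughly rectangular cross-section of a nanocrystal.
#'
#' @param form \code{"Ibeta"} (all chains parallel) or \code{"II"}
#'   (origin/center antiparallel).
#' @param n_chains Number of chains (>= 1).
#' @param dp Degree of polymerization: glucose units per chain (>= 2).
#' @return A \code{cellulose_crystal}: list with an atom table
#'   (\code{serial}, \code{chain}, \code{resno}, \code{resid}, \code{name},
#'   \code{element}, \code{x}, \code{y}, \code{z}), a chain table
#'   (\code{chain_id}, \code{parity}, direction components, \code{dp}),
#'   the form and the template.
#' @examples
#' cr <- build_crystal("Ibeta", n_chains = 4, dp = 2)
#' cr$chains
#' @export
build_crystal <- function(form = c("Ibeta", "II"), n_chains = 52, dp = 6) {
  form <- match.arg(form)
  if (!is.numeric(n_chains) || n_chains < 1 || n_chains != round(n_chains))
    stop("n_chains must be a positive integer")
  if (!is.numeric(dp) || dp < 2 || dp != round(dp))
    stop("dp must be an integer >= 2 (a single glucose is not a chain)")
  tpl <- unit_cell_template(form)
  g <- glucose_template(tpl$rise)

  # candidate lattice sites: origin and center positions of a grid of cells
  ga <- tpl$gamma * pi / 180
  va <- c(tpl$a, 0)
  vb <- c(tpl$b * cos(ga), tpl$b * sin(ga))
  m <- ceiling(sqrt(n_chains / 2)) + 2
  idx <- expand.grid(i = seq(-m, m), j = seq(-m, m))
  sites <- rbind(
    data.frame(x = idx$i * va[1] + idx$j * vb[1],
               y = idx$i * va[2] + idx$j * vb[2], parity = "origin",
               stringsAsFactors = FALSE),
    data.frame(x = (idx$i + 0.5) * va[1] + (idx$j + 0.5) * vb[1],
               y = (idx$i + 0.5) * va[2] + (idx$j + 0.5) * vb[2],
               parity = "center", stringsAsFactors = FALSE))
  ctr <- c(mean(sites$x), mean(sites$y))
  d <- sqrt((sites$x - ctr[1])^2 + (sites$y - ctr[2])^2)
  ord <- order(round(d, 6), sites$parity, sites$x, sites$y)
  sites <- sites[ord[seq_len(n_chains)], , drop = FALSE]

  ids <- .chain_id_pool(n_chains)
  atoms_list <- vector("list", n_chains)
  chain_rows <- vector("list", n_chains)
  serial0 <- 0L
  for (k in seq_len(n_chains)) {
    parity <- sites$parity[k]
    phase <- if (parity == "center") tpl$rise / 2 else 0
    down <- tpl$antiparallel && parity == "center"
    at <- .build_chain_atoms(g, dp, tpl$rise, down,
                             setting = tpl$setting_deg[[parity]])
    at$x <- at$x + sites$x[k]
    at$y <- at$y + sites$y[k]
    at$z <- at$z + phase
    at$chain <- ids[k]
    at$serial <- serial0 + seq_len(nrow(at))
    serial0 <- serial0 + nrow(at)
    atoms_list[[k]] <- at
    chain_rows[[k]] <- data.frame(
      chain_id = ids[k], parity = parity,
      dir_x = 0, dir_y = 0, dir_z = if (down) -1 else 1,
      dp = dp, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms_list)
  atoms <- atoms[, c("serial", "chain", "resno", "resid", "name", "element",
                     "x", "y", "z")]
  rownames(atoms) <- NULL
  structure(list(form = form, atoms = atoms,
                 chains = do.call(rbind, chain_rows),
                 template = tpl, central_chain_ids = NULL),
            class = "cellulose_crystal")
}

# one chain of dp residues in local coordinates (chain axis = z); `setting`
# is the chain's rotation about its own axis in degrees (the setting angle,
# chosen per polymorph and parity for clash-free packing)
.build_chain_atoms <- function(g, dp, rise, down = FALSE, setting = 0) {
  sth <- setting * pi / 180
  Rz <- matrix(c(cos(sth), sin(sth), 0, -sin(sth), cos(sth), 0, 0, 0, 1),
               3, 3)
  res_list <- vector("list", dp)
  for (r in seq_len(dp)) {
    at <- g$interior
    if (r == 1) at <- rbind(at, g$caps[g$caps$name == "HO4", ])
    if (r == dp) at <- rbind(at, g$caps[g$caps$name %in% c("O1", "HO1"), ])
    xyz <- as.matrix(at[, c("x", "y", "z")])
    if (down) xyz <- xyz %*% diag(c(1, -1, -1))  # flip chain direction
    if (r %% 2 == 0) xyz[, 1:2] <- -xyz[, 1:2]   # two-fold screw about z
    xyz <- xyz %*% t(Rz)
    shift <- (r - 1) * rise * (if (down) -1 else 1)
    at$x <- xyz[, 1]
    at$y <- xyz[, 2]
    at$z <- xyz[, 3] + shift
    at$resno <- r
    at$resid <- "BGC"
    res_list[[r]] <- at
  }
  do.call(rbind, res_list)
}

#' Write a crystal to a PDB file
#'
#' Standard PDB columns via \pkg{bio3d}.  Chain identifiers beyond the 62
#' single characters of the chain column are carried in the segid field,
#' which \code{\link{read_pdb}} uses to restore them.
#'
#' @param crystal A \code{cellulose_crystal}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_pdb <- function(crystal, path) {
  stopifnot(inherits(crystal, "cellulose_crystal"))
  a <- crystal$atoms
  if (nrow(a) == 0) stop("cannot write an empty crystal")
  chain1 <- substr(a$chain, 1, 1)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = a$serial, elety = a$name,
                   chain = chain1, segid = a$chain, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   print.segid = TRUE)
  invisible(path)
}

#' Read a crystal from a PDB file
#'
#' Reconstructs the chain table (degree of polymerization and chain
#' direction) from the coordinates; parity is assigned geometrically by
#' \code{\link{classify_chain_parity}} and may be \code{"unclassified"} for
#' structures far from a lattice.
#'
#' @param path PDB file path.
#' @param form Polymorph label to attach (\code{"Ibeta"}, \code{"II"} or
#'   \code{NA} when unknown).
#' @return A \code{cellulose_crystal}.
#' @export
read_pdb <- function(path, form = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e)
                    stop("failed to parse PDB file ", path, ": ",
                         conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("no ATOM records found in ", path)
  segid <- trimws(as.character(at$segid))
  chain <- trimws(as.character(at$chain))
  use_segid <- any(nzchar(segid))
  cid <- if (use_segid) segid else chain
  cid[!nzchar(cid)] <- "A"
  atoms <- data.frame(serial = at$eleno, chain = cid, resno = at$resno,
                      resid = at$resid, name = trimws(at$elety),
                      element = substr(trimws(at$elety), 1, 1),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  chains <- .derive_chain_table(atoms)
  cr <- structure(list(form = form, atoms = atoms, chains = chains,
                       template = if (!is.na(form) &&
                                      form %in% c("Ibeta", "II"))
                         unit_cell_template(form) else NULL,
                       central_chain_ids = NULL),
                  class = "cellulose_crystal")
  cr$chains$parity <- classify_chain_parity(cr)
  cr
}

# chain table (dp, direction) from an atom table
.derive_chain_table <- function(atoms) {
  ids <- unique(atoms$chain)
  rows <- lapply(ids, function(cid) {
    sel <- atoms$chain == cid
    resnos <- sort(unique(atoms$resno[sel]))
    dirv <- c(0, 0, 1)
    if (length(resnos) >= 2) {
      first <- colMeans(atoms[sel & atoms$resno == resnos[1],
                              c("x", "y", "z")])
      last <- colMeans(atoms[sel & atoms$resno == resnos[length(resnos)],
                             c("x", "y", "z")])
      v <- as.numeric(last - first)
      nv <- sqrt(sum(v^2))
      if (nv > 0) dirv <- v / nv
    }
    data.frame(chain_id = cid, parity = "unclassified",
               dir_x = dirv[1], dir_y = dirv[2], dir_z = dirv[3],
               dp = length(resnos), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the central chains of a crystal
#'
#' Returns the \code{n_central} chains closest to the lateral (xy) centroid
#' of all chain axes, the chains used for bulk-energy averaging because their
#' first-neighbor shells are complete.  Ties are broken by chain id, so the
#' selection is deterministic and independent of chain ordering.
#'
#' @param crystal A \code{cellulose_crystal}.
#' @param n_central Number of chains to select (0 to the number of chains).
#' @return Character vector of chain ids.
#' @export
select_central_chains <- function(crystal, n_central = 30) {
  stopifnot(inherits(crystal, "cellulose_crystal"))
  ids <- crystal$chains$chain_id
  if (n_central > length(ids))
    stop("n_central (", n_central, ") exceeds the number of chains (",
         length(ids), ")")
  if (n_central == 0) return(character(0))
  cen <- t(vapply(ids, function(cid) {
    sel <- crystal$atoms$chain == cid
    c(mean(crystal$atoms$x[sel]), mean(crystal$atoms$y[sel]))
  }, numeric(2)))
  mid <- colMeans(cen)
  d <- sqrt((cen[, 1] - mid[1])^2 + (cen[, 2] - mid[2])^2)
  ids[order(round(d, 6), ids)][seq_len(n_central)]
}

#' Classify chain parity (origin vs center)
#'
#' Origin and center chains differ by a quarter-cell shift along the chain
#' axis, i.e. by half the per-residue rise.  Chains are therefore clustered
#' by the phase of their centroid along the chain axis modulo the rise:
#' chains in phase with the reference chain (the first chain id) share its
#' parity, chains half a rise out of phase have the opposite parity, and
#' chains falling between the two clusters are labeled
#' \code{"unclassified"} rather than guessed.  For crystals built by
#' \code{\link{build_crystal}} the stored template parities are returned
#' directly.
#'
#' @param crystal A \code{cellulose_crystal}.
#' @param rise Per-residue rise in Angstrom; taken from the crystal template
#'   when present, otherwise estimated from consecutive residue centroids.
#' @return Character vector of labels (\code{"origin"}, \code{"center"},
#'   \code{"unclassified"}) in the order of \code{crystal$chains$chain_id}.
#' @export
classify_chain_parity <- function(crystal, rise = NULL) {
  stopifnot(inherits(crystal, "cellulose_crystal"))
  ch <- crystal$chains
  if (all(ch$parity %in% c("origin", "center"))) return(ch$parity)
  ref_par <- if (ch$parity[1] %in% c("origin", "center"))
    ch$parity[1] else "origin"
  other <- if (ref_par == "origin") "center" else "origin"
  # antiparallel crystal: parity follows the chain direction
  dirs <- as.matrix(ch[, c("dir_x", "dir_y", "dir_z")])
  dots <- drop(dirs %*% dirs[1, ])
  if (any(dots < 0)) {
    lab <- rep("unclassified", nrow(ch))
    lab[dots > 0.5] <- ref_par
    lab[dots < -0.5] <- other
    return(lab)
  }
  if (is.null(rise)) {
    if (!is.null(crystal$template)) rise <- crystal$template$rise
    else rise <- .estimate_rise(crystal)
  }
  if (!is.finite(rise) || rise <= 0) return(rep("unclassified", nrow(ch)))
  phase <- vapply(ch$chain_id, function(cid) {
    sel <- crystal$atoms$chain == cid
    mean(crystal$atoms$z[sel]) %% rise
  }, numeric(1))
  ref <- phase[1]
  # circular distance on a circle of circumference `rise`
  dd <- abs(phase - ref)
  dd <- pmin(dd, rise - dd)
  lab <- rep("unclassified", nrow(ch))
  lab[dd < rise / 6] <- ref_par
  lab[dd > rise / 3] <- other
  lab
}

# median projected residue-to-residue spacing, used when no template is known
.estimate_rise <- function(crystal) {
  steps <- unlist(lapply(crystal$chains$chain_id, function(cid) {
    sel <- crystal$atoms$chain == cid
    resnos <- sort(unique(crystal$atoms$resno[sel]))
    if (length(resnos) < 2) return(numeric(0))
    cz <- vapply(resnos, function(r)
      mean(crystal$atoms$z[sel & crystal$atoms$resno == r]), numeric(1))
    abs(diff(cz))
  }))
  if (length(steps) == 0) return(NA_real_)
  stats::median(steps)
}

#' Infer covalent bonds of a crystal
#'
#' Distance-based bond inference within each chain (no interchain bonds):
#' heavy-atom pairs closer than 1.85 Angstrom and hydrogen/heavy pairs closer
#' than 1.25 Angstrom are bonded.  Used to derive the 1-2 and 1-3 exclusion
#' pairs of the intrachain nonbonded energy.  An explicit bond list stored in
#' \code{crystal$bonds} (two-column matrix of atom serials) takes precedence.
#'
#' @param crystal A \code{cellulose_crystal}.
#' @return Two-column integer matrix of bonded atom-row indices into
#'   \code{crystal$atoms}.
#' @export
crystal_bonds <- function(crystal) {
  stopifnot(inherits(crystal, "cellulose_crystal"))
  if (!is.null(crystal$bonds)) {
    m <- match(as.vector(crystal$bonds), crystal$atoms$serial)
    if (anyNA(m)) stop("bond list refers to unknown atom serials")
    return(matrix(m, ncol = 2))
  }
  a <- crystal$atoms
  out <- list()
  for (cid in unique(a$chain)) {
    rows <- which(a$chain == cid)
    xyz <- as.matrix(a[rows, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    is_h <- a$element[rows] == "H"
    cut <- matrix(1.85, nrow(d), ncol(d))
    cut[is_h, ] <- 1.25
    cut[, is_h] <- 1.25
    cut[is_h, is_h] <- 0          # no H-H bonds
    hit <- which(d > 0 & d < cut, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit) > 0)
      out[[length(out) + 1L]] <- cbind(rows[hit[, 1]], rows[hit[, 2]])
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

#' @export
print.cellulose_crystal <- function(x, ...) {
  cat("cellulose crystal (form ", x$form, "): ",
      nrow(x$chains), " chains, dp ",
      paste(unique(x$chains$dp), collapse = "/"), ", ",
      nrow(x$atoms), " atoms\n", sep = "")
  par <- table(x$chains$parity)
  cat("  parity:", paste(names(par), par, sep = "=", collapse = ", "), "\n")
  if (inherits(x, "parameterized_crystal"))
    cat("  parameterized (variant ",
        attr(x, "forcefield_variant") %||% "?", ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
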