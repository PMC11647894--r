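#' @title Synthetic fixtures: two-body systems, hydrogen-bond geometries,
#'   toy crystals, size series
#' @name synthdata
#' @description Generators for all synthetic inputs the test suite needs:
#'   minimal two-body systems with analytic energies, idealized
#'   hydrogen-bond fixtures at prescribed geometry, toy crystals shipping a
#'   brute-force pair-sum energy ledger computed by an independent O(N^2)
#'   oracle, and per-chain energy series linear in chain length with
#'   controllable noise.  All generators are deterministic given their
#'   arguments (and seed, where one applies).
NULL

# wrap an atom table into a parameterized_crystal
.as_pcrystal <- function(atoms, chains, form = "synthetic", bonds = NULL) {
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  cr <- structure(list(form = form, atoms = atoms, chains = chains,
                       template = NULL, central_chain_ids = NULL,
                       bonds = bonds),
                  class = c("parameterized_crystal", "cellulose_crystal"))
  cr
}

#' Minimal two-body system with analytic energies
#'
#' Two parameterized atoms in separate chains at distance \code{r}, with the
#' closed-form Coulomb and Lennard-Jones energies attached as the
#' \code{"analytic"} attribute.  Used as the oracle input for the pair
#' energy primitives.
#'
#' @param q1,q2 Partial charges in e.
#' @param r Distance in Angstrom (> 0).
#' @param radius Atomic vdW radii (length 1 or 2), Angstrom.
#' @param epsilon Well depths (length 1 or 2), kcal/mol.
#' @return A \code{parameterized_crystal} of two single-atom chains.
#' @export
make_two_body <- function(q1, q2, r, radius = c(3.442, 3.442),
                          epsilon = c(0, 0)) {
  if (!is.finite(r) || r <= 0) stop("distance r must be positive")
  radius <- rep(radius, length.out = 2)
  epsilon <- rep(epsilon, length.out = 2)
  atoms <- data.frame(chain = c("A", "B"), resno = c(1L, 1L),
                      resid = "LIG", name = c("Q1", "Q2"), element = "Q",
                      x = c(0, r), y = 0, z = 0,
                      charge = c(q1, q2), radius = radius, epsilon = epsilon,
                      stringsAsFactors = FALSE)
  chains <- data.frame(chain_id = c("A", "B"),
                       parity = c("origin", "center"),
                       dir_x = 0, dir_y = 0, dir_z = 1, dp = 1L,
                       stringsAsFactors = FALSE)
  cr <- .as_pcrystal(atoms, chains, form = "two_body")
  rmin <- mean(radius)
  eps <- sqrt(prod(epsilon))
  s6 <- (rmin / r)^6
  attr(cr, "analytic") <- c(electrostatic = COULOMB_PREFACTOR * q1 * q2 / r,
                            vdw = eps * (s6 * s6 - 2 * s6))
  cr
}

# rotation matrix taking unit vector a to unit vector b (Rodrigues)
.rotation_align <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

# in-plane (z = 0) rotation of a 2D direction by ang degrees
.rot2 <- function(v, ang) {
  th <- ang * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2], 0)
}

#' Idealized hydrogen-bond fixture at prescribed geometry
#'
#' Builds a minimal parameterized structure containing one donor C-O-H
#' triple and one acceptor group placed so that the hydrogen-bond geometry
#' (\code{d_HO}, \code{d_OO}, angle at H) is met exactly.  All atoms are
#' placed in the donor O-H...O plane (out-of-plane freedom is fixed to
#' zero, since the three geometry numbers underdetermine a 3D placement);
#' the donor C and the acceptor group are placed anti to the partner group
#' with standard bond lengths (C-O 1.43, O-H 0.96 Angstrom) and
#' tetrahedral-like angles.  An optional matrix of donor-acceptor pair
#' distances refines the placement by least squares, which lets a fixture
#' reproduce a full set of tabulated pair energies.
#'
#' @param donor Donor oxygen name: \code{"O2"}, \code{"O3"} or \code{"O6"}.
#' @param acceptor Acceptor oxygen name: \code{"O2"}, \code{"O3"},
#'   \code{"O5"} or \code{"O6"}.
#' @param d_HO H...acceptor-O distance, Angstrom.
#' @param d_OO donor-O...acceptor-O distance, Angstrom.
#' @param angle Donor-O--H...O angle at the hydrogen, degrees.
#' @param scope \code{"inter"} (donor and acceptor in different chains) or
#'   \code{"intra"}.
#' @param ff Force field for charges and Lennard-Jones parameters.
#' @param pair_distances Optional numeric matrix of target cross distances
#'   (rownames: donor atom names, colnames: acceptor atom names; NA entries
#'   are unconstrained).  Atom positions not fixed by the bond geometry are
#'   refined to match these distances.
#' @param donor_parity,acceptor_parity Chain parity labels for the fixture.
#' @return A \code{parameterized_crystal}; the realized geometry is attached
#'   as the \code{"geometry"} attribute.
#' @export
make_hbond_fixture <- function(donor = "O6", acceptor = "O3",
                               d_HO = 1.77, d_OO = 2.72, angle = 162,
                               scope = c("inter", "intra"),
                               ff = load_forcefield(),
                               pair_distances = NULL,
                               donor_parity = "origin",
                               acceptor_parity = "origin") {
  scope <- match.arg(scope)
  donor <- match.arg(donor, c("O2", "O3", "O6"))
  acceptor <- match.arg(acceptor, c("O2", "O3", "O5", "O6"))
  if (d_HO <= 0 || d_OO <= 0) stop("distances must be positive")
  if (angle < 0 || angle > 180) stop("angle must be in [0, 180] degrees")
  th <- angle * pi / 180
  disc <- d_OO^2 - (d_HO * sin(th))^2
  if (disc < 0)
    stop("unsatisfiable geometry: d_OO too short for d_HO at this angle")
  d_cov <- d_HO * cos(th) + sqrt(disc)
  if (d_cov <= 0.5 || d_cov > 1.6)
    stop("unsatisfiable geometry: implied covalent O-H length ",
         sprintf("%.3f", d_cov), " Angstrom")

  o_d <- c(0, 0, 0)
  o_a <- c(d_OO, 0, 0)
  # angle of H at the donor O, from the law of cosines
  cos_a <- (d_cov^2 + d_OO^2 - d_HO^2) / (2 * d_cov * d_OO)
  cos_a <- min(1, max(-1, cos_a))
  sin_a <- sqrt(1 - cos_a^2)
  h <- d_cov * c(cos_a, sin_a, 0)

  # donor C: 1.43 A from donor O, C-O-H angle 108.5 deg, anti to acceptor
  uh <- (h - o_d) / sqrt(sum((h - o_d)^2))
  cand <- list(o_d + 1.43 * .rot2(uh, 108.5), o_d + 1.43 * .rot2(uh, -108.5))
  c_d <- cand[[which.max(vapply(cand, function(p)
    sum((p - o_a)^2), numeric(1)))]]

  donor_atoms <- data.frame(
    name = c(.donor_C_of[donor], donor, paste0("H", donor)),
    x = c(c_d[1], o_d[1], h[1]), y = c(c_d[2], o_d[2], h[2]),
    z = c(c_d[3], o_d[3], h[3]), stringsAsFactors = FALSE)

  if (acceptor == "O5") {
    tpl <- glucose_template()
    members <- .acceptor_group_of("O5")
    sub <- tpl$interior[match(members, tpl$interior$name), ]
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, xyz[members == "O5", ])
    v <- colMeans(xyz[members != "O5", , drop = FALSE])
    R <- .rotation_align(v, o_a - o_d)
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2, o_a, "+")
    acc_atoms <- data.frame(name = members, x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE)
  } else {
    # hydroxyl acceptor: C anti to the donor, H pointing away from the donor
    ud <- (o_d - o_a) / d_OO
    c_cand <- list(o_a + 1.43 * .rot2(ud, 120), o_a + 1.43 * .rot2(ud, -120))
    # put the acceptor C on the opposite side of the O-O axis from H
    c_a <- if (c_cand[[1]][2] * h[2] <= c_cand[[2]][2] * h[2])
      c_cand[[1]] else c_cand[[2]]
    uc <- (c_a - o_a) / sqrt(sum((c_a - o_a)^2))
    h_cand <- list(o_a + 0.96 * .rot2(uc, 108.5),
                   o_a + 0.96 * .rot2(uc, -108.5))
    h_a <- h_cand[[which.max(vapply(h_cand, function(p)
      sum((p - o_d)^2), numeric(1)))]]
    acc_atoms <- data.frame(
      name = c(.donor_C_of[acceptor], acceptor, paste0("H", acceptor)),
      x = c(c_a[1], o_a[1], h_a[1]), y = c(c_a[2], o_a[2], h_a[2]),
      z = c(c_a[3], o_a[3], h_a[3]), stringsAsFactors = FALSE)
  }

  if (!is.null(pair_distances))
    acc_atoms <- .refine_fixture(donor_atoms, acc_atoms, donor, acceptor,
                                 pair_distances)

  donor_atoms$chain <- "A"
  donor_atoms$resno <- 1L
  acc_atoms$chain <- if (scope == "inter") "B" else "A"
  acc_atoms$resno <- 2L
  atoms <- rbind(donor_atoms, acc_atoms)
  atoms$resid <- "BGC"
  atoms$element <- substr(atoms$name, 1, 1)
  idx <- match(atoms$name, ff$name)
  if (anyNA(idx))
    stop("fixture atom(s) missing from force field: ",
         paste(atoms$name[is.na(idx)], collapse = ", "))
  atoms$charge <- ff$charge[idx]
  atoms$radius <- ff$radius[idx]
  atoms$epsilon <- ff$epsilon[idx]
  chains <- if (scope == "inter") {
    data.frame(chain_id = c("A", "B"),
               parity = c(donor_parity, acceptor_parity),
               dir_x = 0, dir_y = 0, dir_z = 1, dp = 1L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(chain_id = "A", parity = donor_parity,
               dir_x = 0, dir_y = 0, dir_z = 1, dp = 2L,
               stringsAsFactors = FALSE)
  }
  cr <- .as_pcrystal(atoms, chains, form = "hbond_fixture")
  attr(cr, "forcefield_variant") <- attr(ff, "variant")
  g <- hbond_geometry(o_d, h, o_a)
  if (abs(g["d_HO"] - d_HO) > 1e-6 || abs(g["d_OO"] - d_OO) > 1e-6 ||
      abs(g["angle"] - angle) > 1e-4)  # angle is degenerate at collinearity
    stop("internal error: fixture geometry deviates from specification")
  attr(cr, "geometry") <- g
  cr
}

# least-squares refinement of acceptor-atom positions against target
# donor-acceptor distances; donor triple and the acceptor O stay fixed
.refine_fixture <- function(donor_atoms, acc_atoms, donor, acceptor,
                            pair_distances) {
  dn <- donor_atoms$name
  an <- acc_atoms$name
  if (is.null(rownames(pair_distances)) || is.null(colnames(pair_distances)))
    stop("pair_distances needs donor rownames and acceptor colnames")
  free <- which(an != acceptor)           # acceptor O is fixed by geometry
  if (length(free) == 0) return(acc_atoms)
  dxyz <- as.matrix(donor_atoms[, c("x", "y", "z")])
  axyz0 <- as.matrix(acc_atoms[, c("x", "y", "z")])
  targets <- list()
  for (i in seq_along(dn)) for (j in seq_along(an)) {
    if (dn[i] %in% rownames(pair_distances) &&
        an[j] %in% colnames(pair_distances)) {
      tgt <- pair_distances[dn[i], an[j]]
      if (is.finite(tgt) && an[j] %in% an[free])
        targets[[length(targets) + 1L]] <- c(i, match(an[j], an[free]), tgt)
    }
  }
  if (length(targets) == 0) return(acc_atoms)
  tmat <- do.call(rbind, targets)
  obj <- function(p) {
    pos <- matrix(p, ncol = 3)
    resid <- vapply(seq_len(nrow(tmat)), function(k) {
      d <- sqrt(sum((dxyz[tmat[k, 1], ] - pos[tmat[k, 2], ])^2))
      d - tmat[k, 3]
    }, numeric(1))
    # weak regularization toward the initial placement keeps the problem
    # well-posed when the targets underdetermine the positions
    sum(resid^2) + 1e-6 * sum((pos - axyz0[free, , drop = FALSE])^2)
  }
  opt <- stats::optim(as.vector(axyz0[free, , drop = FALSE]), obj,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  axyz0[free, ] <- matrix(opt$par, ncol = 3)
  acc_atoms$x <- axyz0[, 1]; acc_atoms$y <- axyz0[, 2]
  acc_atoms$z <- axyz0[, 3]
  acc_atoms
}

#' Toy crystal with a brute-force energy ledger
#'
#' Straight chains of point-charge residues on a square lattice, shipped
#' with ground-truth interchain and intrachain energies computed by an
#' independent brute-force O(N^2) loop over unique atom pairs (with 1-2 and
#' 1-3 exclusions from the explicit linear bond topology).  The ledger is
#' the oracle against which the decomposition code is validated.
#'
#' @param n_chains Number of chains on a square grid.
#' @param dp Residues per chain.
#' @param lattice_spacing Chain-to-chain spacing, Angstrom (> 0).
#' @param motif Per-residue atom motif: data frame with columns \code{name},
#'   \code{dx}, \code{dy}, \code{dz} (offsets within the residue),
#'   \code{charge}, \code{radius}, \code{epsilon}.  Default: a two-atom
#'   +0.3/-0.3 e dipole.
#' @param rise Residue-to-residue rise along the chain, Angstrom.
#' @param bonded Link consecutive atoms along each chain (enables 1-2/1-3
#'   exclusions in the intrachain ledger).
#' @return A \code{parameterized_crystal} with attribute \code{"ledger"}: a
#'   list with \code{interchain} and \code{intrachain} totals
#'   (\code{c(electrostatic, vdw)}) and the total unique-pair sum.
#' @export
make_toy_crystal <- function(n_chains = 3, dp = 4, lattice_spacing = 5,
                             motif = NULL, rise = 3.0, bonded = TRUE) {
  if (lattice_spacing <= 0) stop("lattice_spacing must be positive")
  if (n_chains < 1 || dp < 1) stop("n_chains and dp must be >= 1")
  if (is.null(motif))
    motif <- data.frame(name = c("Q1", "Q2"), dx = 0, dy = c(0, 0),
                        dz = c(0, 1.2), charge = c(0.3, -0.3),
                        radius = 3.4, epsilon = 0.15,
                        stringsAsFactors = FALSE)
  side <- ceiling(sqrt(n_chains))
  ids <- .chain_id_pool(n_chains)
  atoms_list <- list(); chain_rows <- list(); bonds <- list()
  serial0 <- 0L
  for (k in seq_len(n_chains)) {
    ix <- (k - 1) %% side
    iy <- (k - 1) %/% side
    res <- lapply(seq_len(dp), function(r)
      data.frame(chain = ids[k], resno = r, resid = "TOY",
                 name = motif$name, element = substr(motif$name, 1, 1),
                 x = ix * lattice_spacing + motif$dx,
                 y = iy * lattice_spacing + motif$dy,
                 z = (r - 1) * rise + motif$dz,
                 charge = motif$charge, radius = motif$radius,
                 epsilon = motif$epsilon, stringsAsFactors = FALSE))
    at <- do.call(rbind, res)
    n <- nrow(at)
    if (bonded && n > 1)
      bonds[[k]] <- cbind(serial0 + seq_len(n - 1), serial0 + seq_len(n - 1) + 1L)
    serial0 <- serial0 + n
    atoms_list[[k]] <- at
    chain_rows[[k]] <- data.frame(
      chain_id = ids[k],
      parity = if ((ix + iy) %% 2 == 0) "origin" else "center",
      dir_x = 0, dir_y = 0, dir_z = 1, dp = dp, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms_list)
  bonds <- if (length(bonds) > 0) do.call(rbind, bonds) else NULL
  cr <- .as_pcrystal(atoms, do.call(rbind, chain_rows), form = "toy",
                     bonds = bonds)
  # duplicate-position check (overlapping chains)
  key <- paste(round(cr$atoms$x, 9), round(cr$atoms$y, 9),
               round(cr$atoms$z, 9))
  if (anyDuplicated(key)) stop("overlapping chains: duplicate atom positions")
  attr(cr, "ledger") <- .brute_force_ledger(cr)
  cr
}

# independent O(N^2) oracle: plain loop over unique pairs, exclusion lookup
# from the explicit bond graph (distance <= 2 edges)
.brute_force_ledger <- function(cr) {
  a <- cr$atoms
  n <- nrow(a)
  excl <- matrix(FALSE, n, n)
  if (!is.null(cr$bonds) && nrow(cr$bonds) > 0) {
    adj <- matrix(FALSE, n, n)
    b <- matrix(match(as.vector(cr$bonds), a$serial), ncol = 2)
    adj[b] <- TRUE; adj[b[, 2:1, drop = FALSE]] <- TRUE
    two <- (adj %*% adj) > 0
    excl <- adj | two
    diag(excl) <- FALSE
  }
  inter <- c(electrostatic = 0, vdw = 0)
  intra <- c(electrostatic = 0, vdw = 0)
  total <- c(electrostatic = 0, vdw = 0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      same <- a$chain[i] == a$chain[j]
      if (same && excl[i, j]) next
      r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      e <- 18.2223^2 * a$charge[i] * a$charge[j] / r
      rm <- (a$radius[i] + a$radius[j]) / 2
      ep <- sqrt(a$epsilon[i] * a$epsilon[j])
      v <- ep * ((rm / r)^12 - 2 * (rm / r)^6)
      total <- total + c(e, v)
      if (same) intra <- intra + c(e, v) else inter <- inter + c(e, v)
    }
  }
  list(interchain = inter, intrachain = intra, total = total)
}

#' Synthetic per-chain energy series, linear in chain length
#'
#' @param slope Bulk energy per glucose unit, kcal/mol.
#' @param intercept Chain-end term, kcal/mol.
#' @param noise_sd Gaussian noise standard deviation, kcal/mol (0 for an
#'   exact line).
#' @param dp_list Nonempty vector of chain lengths.
#' @param seed Optional integer seed for reproducible noise.
#' @return A \code{size_series} data frame (\code{dp}, \code{energy}).
#' @export
make_size_series <- function(slope, intercept = 0, noise_sd = 0,
                             dp_list = c(6, 8, 10, 12), seed = NULL) {
  if (length(dp_list) == 0) stop("dp_list is empty")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0) stats::rnorm(length(dp_list), 0, noise_sd)
           else rep(0, length(dp_list))
  ss <- data.frame(dp = as.numeric(dp_list),
                   energy = slope * dp_list + intercept + noise)
  attr(ss, "term") <- "synthetic"
  attr(ss, "variant") <- NA_character_
  class(ss) <- c("size_series", "data.frame")
  ss
}
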