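#' @title Pairwise nonbonded energies and their decomposition
#' @name energetics
#' @description Coulomb and Lennard-Jones pair energies with GLYCAM-style
#'   combination rules, and their decomposition into interchain and
#'   intrachain contributions over selected chains of a parameterized
#'   crystal.  All sums are full pairwise sums: no distance cutoff, no
#'   periodic images, relative permittivity 1 (finite crystal in vacuo with
#'   neutral residues).
NULL

#' Coulomb energy of two point charges
#'
#' \eqn{E = 18.2223^2 \, q_i q_j / r} in kcal/mol for charges in e and the
#' distance in Angstrom (the GLYCAM convention \eqn{Q = 18.2223 q}).
#'
#' @param q_i,q_j Partial charges in units of the elementary charge.
#' @param r Distance in Angstrom (> 0); vectorized.
#' @return Energy in kcal/mol.
#' @examples
#' coulomb_energy(-0.688, -0.709, 2.72)   # ~ 59.5 kcal/mol
#' @export
coulomb_energy <- function(q_i, q_j, r) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("distance r must be positive and finite")
  COULOMB_PREFACTOR * q_i * q_j / r
}

#' Lennard-Jones energy of an atom pair
#'
#' 12-6 potential \eqn{E = \epsilon[(R_{min}/r)^{12} - 2 (R_{min}/r)^6]}
#' with \eqn{R_{min} = (R_i + R_j)/2} (arithmetic mean of the atomic vdW
#' radii) and \eqn{\epsilon = \sqrt{\epsilon_i \epsilon_j}} (geometric mean
#' of the well depths).  The minimum value \eqn{-\epsilon} is attained
#' exactly at \eqn{r = R_{min}}.
#'
#' @param params_i,params_j Parameter sets with fields \code{radius}
#'   (Angstrom) and \code{epsilon} (kcal/mol), e.g. rows of a
#'   \code{forcefield}.
#' @param r Distance in Angstrom (> 0); vectorized.
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(params_i, params_j, r) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("distance r must be positive and finite")
  rmin <- (params_i$radius + params_j$radius) / 2
  eps <- sqrt(params_i$epsilon * params_j$epsilon)
  s6 <- (rmin / r)^6
  eps * (s6^2 - 2 * s6)
}

# vectorized pair sum between two atom sets (data frames with x,y,z,charge,
# radius, epsilon); returns c(electrostatic, vdw) in kcal/mol
.pair_sum <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(c(electrostatic = 0, vdw = 0))
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  d <- sqrt(dx * dx + dy * dy + dz * dz)
  if (any(d <= 0))
    stop("coincident atoms in pair sum (zero interatomic distance)")
  elec <- COULOMB_PREFACTOR * sum(outer(a$charge, b$charge) / d)
  rmin <- outer(a$radius, b$radius, "+") / 2
  eps <- sqrt(outer(a$epsilon, b$epsilon))
  s6 <- (rmin / d)^6
  vdw <- sum(eps * (s6 * s6 - 2 * s6))
  c(electrostatic = elec, vdw = vdw)
}

# energies of an explicit list of atom-row pairs (i, j index into atoms)
.pair_list_sum <- function(atoms, i, j) {
  if (length(i) == 0) return(c(electrostatic = 0, vdw = 0))
  d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
              (atoms$z[i] - atoms$z[j])^2)
  if (any(d <= 0)) stop("coincident atoms in pair list")
  elec <- sum(COULOMB_PREFACTOR * atoms$charge[i] * atoms$charge[j] / d)
  rmin <- (atoms$radius[i] + atoms$radius[j]) / 2
  eps <- sqrt(atoms$epsilon[i] * atoms$epsilon[j])
  s6 <- (rmin / d)^6
  c(electrostatic = elec, vdw = sum(eps * (s6 * s6 - 2 * s6)))
}

#' Interaction energy between two atom groups
#'
#' Full double sum of pairwise Coulomb and Lennard-Jones energies over all
#' cross pairs of two disjoint atom groups; no exclusions are applied across
#' groups.  This is the primitive behind the group-based hydrogen-bond
#' scoring.
#'
#' @param group_a,group_b Data frames of parameterized atoms (columns
#'   \code{x}, \code{y}, \code{z}, \code{charge}, \code{radius},
#'   \code{epsilon}; a \code{serial} column, when present, is used for the
#'   disjointness check).
#' @return Named numeric vector \code{c(electrostatic =, vdw =)} in kcal/mol.
#' @export
group_interaction_energy <- function(group_a, group_b) {
  need <- c("x", "y", "z", "charge", "radius", "epsilon")
  if (!all(need %in% names(group_a)) || !all(need %in% names(group_b)))
    stop("groups must carry columns ", paste(need, collapse = ", "))
  if ("serial" %in% names(group_a) && "serial" %in% names(group_b) &&
      length(intersect(group_a$serial, group_b$serial)) > 0)
    stop("groups overlap (shared atom serials)")
  .pair_sum(group_a, group_b)
}

#' Interchain nonbonded energy of selected chains
#'
#' For each chain c of the subset, the per-chain interchain energy is half
#' the sum of all pairwise energies between the atoms of c and the atoms of
#' every other chain of the whole crystal (not restricted to the subset);
#' the factor 1/2 avoids double counting of atom pairs when averaging over
#' chains.  The reported total is the mean (default) or the sum of the
#' per-chain values.  With \code{aggregate = "sum"} and the subset equal to
#' all chains, the total equals the brute-force sum over all unique
#' interchain atom pairs.
#'
#' @param pcrystal A \code{parameterized_crystal}.
#' @param chain_subset Chain ids to evaluate; defaults to the crystal's
#'   stored central chains, or to all chains.
#' @param aggregate \code{"mean"} or \code{"sum"} over per-chain values.
#' @return An \code{energy_breakdown}: list with \code{scope},
#'   \code{electrostatic} and \code{vdw} totals, a \code{per_chain} data
#'   frame, \code{per_glucose} values (totals divided by dp, \code{NA} when
#'   chain lengths differ) and the aggregation mode.
#' @export
interchain_energy <- function(pcrystal, chain_subset = NULL,
                              aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  .check_param(pcrystal)
  if (is.null(chain_subset))
    chain_subset <- pcrystal$central_chain_ids %||% pcrystal$chains$chain_id
  if (length(chain_subset) == 0) stop("chain_subset is empty")
  if (!all(chain_subset %in% pcrystal$chains$chain_id))
    stop("unknown chain id(s): ",
         paste(setdiff(chain_subset, pcrystal$chains$chain_id),
               collapse = ", "))
  atoms <- pcrystal$atoms
  per <- t(vapply(chain_subset, function(cid) {
    sel <- atoms$chain == cid
    0.5 * .pair_sum(atoms[sel, ], atoms[!sel, ])
  }, c(electrostatic = 0, vdw = 0)))
  .make_breakdown("interchain", chain_subset, per, aggregate,
                  pcrystal$chains$dp[match(chain_subset,
                                           pcrystal$chains$chain_id)],
                  attr(pcrystal, "forcefield_variant"))
}

#' Intrachain nonbonded energy of selected chains
#'
#' Pairwise Coulomb and Lennard-Jones sums within each chain with bonded
#' exclusions: 1-2 (bonded) and 1-3 (two bonds apart) pairs are excluded;
#' 1-4 pairs and beyond are included at full strength (the GLYCAM
#' convention of no 1-4 scaling).  Bonded terms (bond, angle, dihedral
#' energies) are not part of this quantity: it is the nonbonded intrachain
#' component only.
#'
#' @param pcrystal A \code{parameterized_crystal}.
#' @param chain_subset Chain ids; defaults as in
#'   \code{\link{interchain_energy}}.
#' @param bonds Optional two-column matrix of bonded atom serials; by
#'   default bonds are taken from \code{pcrystal$bonds} or inferred from
#'   distances (\code{\link{crystal_bonds}}).
#' @param exclusions \code{"1-3"} (default: exclude 1-2 and 1-3 pairs) or
#'   \code{"1-2"} (exclude directly bonded pairs only).
#' @param aggregate \code{"mean"} or \code{"sum"} over per-chain values.
#' @return An \code{energy_breakdown} with scope \code{"intrachain"}.
#' @export
intrachain_nonbonded_energy <- function(pcrystal, chain_subset = NULL,
                                        bonds = NULL,
                                        exclusions = c("1-3", "1-2"),
                                        aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  exclusions <- match.arg(exclusions)
  .check_param(pcrystal)
  if (is.null(chain_subset))
    chain_subset <- pcrystal$central_chain_ids %||% pcrystal$chains$chain_id
  if (length(chain_subset) == 0) stop("chain_subset is empty")
  atoms <- pcrystal$atoms
  if (is.null(bonds)) {
    bmat <- crystal_bonds(pcrystal)
  } else {
    m <- match(as.vector(bonds), atoms$serial)
    if (anyNA(m)) stop("bond list refers to unknown atom serials")
    bmat <- matrix(m, ncol = 2)
  }
  excl <- .exclusion_pairs(bmat, nrow(atoms), exclusions)
  per <- t(vapply(chain_subset, function(cid) {
    rows <- which(atoms$chain == cid)
    sub <- atoms[rows, ]
    n <- nrow(sub)
    if (n < 2) return(c(electrostatic = 0, vdw = 0))
    comb <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    full <- .pair_list_sum(sub, comb[, 1], comb[, 2])
    if (nrow(excl) > 0) {
      keep <- excl[excl[, 1] %in% rows & excl[, 2] %in% rows, , drop = FALSE]
      if (nrow(keep) > 0)
        full <- full - .pair_list_sum(atoms, keep[, 1], keep[, 2])
    }
    full
  }, c(electrostatic = 0, vdw = 0)))
  .make_breakdown("intrachain", chain_subset, per, aggregate,
                  pcrystal$chains$dp[match(chain_subset,
                                           pcrystal$chains$chain_id)],
                  attr(pcrystal, "forcefield_variant"))
}

# unique pairs at bond-graph distance 1 (and 2 for "1-3") as a 2-col matrix
.exclusion_pairs <- function(bmat, n_atoms, exclusions) {
  if (nrow(bmat) == 0) return(matrix(integer(0), ncol = 2))
  pairs <- rbind(bmat, bmat[, 2:1, drop = FALSE])
  if (exclusions == "1-3") {
    adj <- split(pairs[, 2], pairs[, 1])
    extra <- list()
    for (mid in names(adj)) {
      nb <- adj[[mid]]
      if (length(nb) >= 2) {
        cmb <- utils::combn(sort(nb), 2)
        extra[[mid]] <- t(cmb)
      }
    }
    if (length(extra) > 0) pairs <- rbind(pairs, do.call(rbind, extra))
  }
  pairs <- t(apply(pairs, 1, sort))
  pairs <- unique(pairs)
  pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
}

.make_breakdown <- function(scope, chain_ids, per, aggregate, dp, variant) {
  per_chain <- data.frame(chain_id = chain_ids,
                          electrostatic = per[, "electrostatic"],
                          vdw = per[, "vdw"],
                          stringsAsFactors = FALSE, row.names = NULL)
  agg <- if (aggregate == "mean") colMeans(per) else colSums(per)
  dp_u <- unique(dp)
  per_glc <- if (length(dp_u) == 1 && aggregate == "mean")
    agg / dp_u else c(electrostatic = NA_real_, vdw = NA_real_)
  structure(list(scope = scope,
                 electrostatic = unname(agg["electrostatic"]),
                 vdw = unname(agg["vdw"]),
                 per_chain = per_chain,
                 per_glucose = per_glc,
                 aggregate = aggregate,
                 dp = if (length(dp_u) == 1) dp_u else dp,
                 variant = variant %||% NA_character_),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("%s energy (%s over %d chains):\n", x$scope, x$aggregate,
              nrow(x$per_chain)))
  cat(sprintf("  electrostatic %10.3f kcal/mol\n", x$electrostatic))
  cat(sprintf("  vdW           %10.3f kcal/mol\n", x$vdw))
  if (!anyNA(x$per_glucose))
    cat(sprintf("  per glucose   %10.3f (elec) %10.3f (vdW)\n",
                x$per_glucose["electrostatic"], x$per_glucose["vdw"]))
  invisible(x)
}

.check_param <- function(pcrystal) {
  if (!inherits(pcrystal, "parameterized_crystal"))
    stop("crystal is not parameterized; call assign_parameters() first")
  need <- c("charge", "radius", "epsilon")
  if (!all(need %in% names(pcrystal$atoms)) ||
      anyNA(pcrystal$atoms[need]))
    stop("crystal has unparameterized atoms")
  invisible(TRUE)
}
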