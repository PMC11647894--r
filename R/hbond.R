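#' @title Hydrogen-bond detection and group-based scoring
#' @name hbond
#' @description Detects hydrogen bonds with a distance- and angle-based
#'   geometric criterion and scores them in three modes: the naive
#'   donor-OH/acceptor-O pair (\code{OH_O}), the donor C-O-H triple against
#'   the acceptor oxygen (\code{COH_O}), and the full multipole description
#'   pairing the donor triple with the near-neutral acceptor group
#'   (\code{COH_COX}): C, O, H for hydroxyl acceptors, the five-atom
#'   O4-C1-O5-C5-C4 set for the ring oxygen O5.
NULL

HB_DONOR_H <- c("HO2", "HO3", "HO6")
HB_ACCEPTORS <- c("O2", "O3", "O5", "O6")

# donor O -> bound C
.donor_C_of <- c(O2 = "C2", O3 = "C3", O6 = "C6")

# acceptor O -> acceptor-group member names (within the acceptor residue)
.acceptor_group_of <- function(acceptor_O) {
  switch(acceptor_O,
         O2 = c("C2", "O2", "HO2"),
         O3 = c("C3", "O3", "HO3"),
         O6 = c("C6", "O6", "HO6"),
         O5 = c("O4", "C1", "O5", "C5", "C4"),
         stop("unsupported acceptor oxygen: ", acceptor_O))
}

#' Geometry of one hydrogen bond
#'
#' @param donor_O,donor_H,acceptor_O Numeric xyz coordinates (length 3).
#' @return Named vector with \code{d_HO} (H to acceptor O, Angstrom),
#'   \code{d_OO} (donor O to acceptor O, Angstrom) and \code{angle}: the
#'   donor-O--H...acceptor-O angle at the hydrogen, in degrees, i.e. the
#'   angle between the vectors H->donor O and H->acceptor O (180 for a
#'   collinear bond).
#' @export
hbond_geometry <- function(donor_O, donor_H, acceptor_O) {
  v1 <- donor_O - donor_H
  v2 <- acceptor_O - donor_H
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  d_oo <- sqrt(sum((donor_O - acceptor_O)^2))
  if (n1 == 0 || n2 == 0 || d_oo == 0)
    stop("coincident atoms in hydrogen-bond geometry")
  cosang <- sum(v1 * v2) / (n1 * n2)
  cosang <- min(1, max(-1, cosang))
  c(d_HO = n2, d_OO = d_oo, angle = acos(cosang) * 180 / pi)
}

#' Detect hydrogen bonds in a parameterized crystal
#'
#' Donors are the hydroxyl groups O2-H, O3-H, O6-H; acceptors are the
#' oxygens O2, O3, O5 and O6.  A donor H and an acceptor O form a hydrogen
#' bond when the H...O distance is at most \code{max_d_HO} and the
#' O-H...O angle at the hydrogen is at least \code{min_angle}.  One donor H
#' may satisfy the criteria for several acceptors (a branched bond); each
#' pairing is reported as its own record.  Defaults (3.0 Angstrom, 115
#' degrees) are wide enough to admit the weak branch bond of cellulose
#' Ibeta (d_HO up to ~3.0 Angstrom, angle down to ~118 degrees) while
#' excluding ordinary nonbonded contacts.
#'
#' @param pcrystal A \code{parameterized_crystal} with hydrogens.
#' @param max_d_HO Maximum H...acceptor distance in Angstrom.
#' @param min_angle Minimum donor-O--H...O angle in degrees.
#' @return A data frame of class \code{hbond_table}, one row per bond, with
#'   donor/acceptor identities, geometry (\code{d_HO}, \code{d_OO},
#'   \code{angle}), \code{scope} (\code{"inter"} or \code{"intra"}), chain
#'   parities and a class label such as \code{"O6oH...O3o inter"}; rows are
#'   ordered deterministically by donor chain, residue, donor O and
#'   acceptor.  The criteria used are attached as attributes.
#' @export
detect_hbonds <- function(pcrystal, max_d_HO = 3.0, min_angle = 115) {
  .check_param(pcrystal)
  atoms <- pcrystal$atoms
  don_h <- which(atoms$name %in% HB_DONOR_H)
  if (length(don_h) == 0)
    stop("structure contains no hydroxyl hydrogens (HO2/HO3/HO6); ",
         "hydrogen-bond detection needs a hydrogen-bearing input")
  acc <- which(atoms$name %in% HB_ACCEPTORS)
  if (length(acc) == 0) return(.empty_hbond_table(max_d_HO, min_angle))

  # donor O and C of each donor H (same chain + residue)
  don_o_name <- sub("^H", "", atoms$name[don_h])
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  don_o <- match(paste(atoms$chain[don_h], atoms$resno[don_h], don_o_name),
                 key)
  don_c <- match(paste(atoms$chain[don_h], atoms$resno[don_h],
                       .donor_C_of[don_o_name]), key)
  ok <- !is.na(don_o) & !is.na(don_c)
  don_h <- don_h[ok]; don_o <- don_o[ok]; don_c <- don_c[ok]
  don_o_name <- don_o_name[ok]
  if (length(don_h) == 0) return(.empty_hbond_table(max_d_HO, min_angle))

  dx <- outer(atoms$x[don_h], atoms$x[acc], "-")
  dy <- outer(atoms$y[don_h], atoms$y[acc], "-")
  dz <- outer(atoms$z[don_h], atoms$z[acc], "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  self <- outer(don_o, acc, "==")
  hit <- which(d <= max_d_HO & !self, arr.ind = TRUE)
  if (nrow(hit) == 0) return(.empty_hbond_table(max_d_HO, min_angle))

  hi <- don_h[hit[, 1]]; oi <- don_o[hit[, 1]]; ci <- don_c[hit[, 1]]
  ai <- acc[hit[, 2]]
  geom <- t(mapply(function(o, h, a)
    hbond_geometry(c(atoms$x[o], atoms$y[o], atoms$z[o]),
                   c(atoms$x[h], atoms$y[h], atoms$z[h]),
                   c(atoms$x[a], atoms$y[a], atoms$z[a])),
    oi, hi, ai))
  keep <- geom[, "angle"] >= min_angle
  if (!any(keep)) return(.empty_hbond_table(max_d_HO, min_angle))
  hi <- hi[keep]; oi <- oi[keep]; ci <- ci[keep]; ai <- ai[keep]
  geom <- geom[keep, , drop = FALSE]

  parity <- pcrystal$chains$parity[match(atoms$chain,
                                         pcrystal$chains$chain_id)]
  pl <- function(p) ifelse(p == "origin", "o", ifelse(p == "center", "c", ""))
  scope <- ifelse(atoms$chain[hi] == atoms$chain[ai], "intra", "inter")
  hb <- data.frame(
    donor_chain = atoms$chain[hi], donor_resno = atoms$resno[hi],
    donor_O = atoms$name[oi], donor_H = atoms$name[hi],
    donor_C = atoms$name[ci],
    acceptor_chain = atoms$chain[ai], acceptor_resno = atoms$resno[ai],
    acceptor_O = atoms$name[ai],
    donor_O_row = oi, donor_H_row = hi, donor_C_row = ci,
    acceptor_O_row = ai,
    d_HO = geom[, "d_HO"], d_OO = geom[, "d_OO"], angle = geom[, "angle"],
    scope = scope,
    donor_parity = parity[hi], acceptor_parity = parity[ai],
    stringsAsFactors = FALSE)
  hb$class_label <- paste0(hb$donor_O, pl(hb$donor_parity), "H...",
                           hb$acceptor_O, pl(hb$acceptor_parity), " ",
                           hb$scope)
  hb <- hb[order(hb$donor_chain, hb$donor_resno, hb$donor_O,
                 hb$acceptor_chain, hb$acceptor_resno, hb$acceptor_O), ]
  rownames(hb) <- NULL
  attr(hb, "max_d_HO") <- max_d_HO
  attr(hb, "min_angle") <- min_angle
  class(hb) <- c("hbond_table", "data.frame")
  hb
}

.empty_hbond_table <- function(max_d_HO, min_angle) {
  hb <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                   donor_O = character(0), donor_H = character(0),
                   donor_C = character(0), acceptor_chain = character(0),
                   acceptor_resno = integer(0), acceptor_O = character(0),
                   donor_O_row = integer(0), donor_H_row = integer(0),
                   donor_C_row = integer(0), acceptor_O_row = integer(0),
                   d_HO = numeric(0), d_OO = numeric(0), angle = numeric(0),
                   scope = character(0), donor_parity = character(0),
                   acceptor_parity = character(0),
                   class_label = character(0), stringsAsFactors = FALSE)
  attr(hb, "max_d_HO") <- max_d_HO
  attr(hb, "min_angle") <- min_angle
  class(hb) <- c("hbond_table", "data.frame")
  hb
}

#' Score hydrogen bonds in one of three modes
#'
#' \describe{
#'   \item{\code{OH_O}}{donor O and H against the acceptor O: the naive
#'     dipole picture.  For the cellulose charge set this interaction is
#'     typically repulsive, because the donor-O/acceptor-O repulsion exceeds
#'     the H/acceptor-O attraction.}
#'   \item{\code{COH_O}}{donor C, O, H against the acceptor O.}
#'   \item{\code{COH_COX}}{donor C, O, H against the full near-neutral
#'     acceptor group: C, O, H for hydroxyl acceptors; O4, C1, O5, C5, C4
#'     for O5 acceptors.  The multipole description.}
#' }
#' Energies are full group-group pair sums
#' (\code{\link{group_interaction_energy}}); the vdW component uses the same
#' atom groups as the electrostatic one.
#'
#' @param pcrystal The \code{parameterized_crystal} the bonds were detected
#'   in.
#' @param hbonds An \code{hbond_table} from \code{\link{detect_hbonds}} (or
#'   a single row of one).
#' @param mode \code{"OH_O"}, \code{"COH_O"} or \code{"COH_COX"}.
#' @return The \code{hbond_table} with columns \code{electrostatic},
#'   \code{vdw} (kcal/mol) and \code{mode} appended.
#' @export
hbond_energy <- function(pcrystal, hbonds,
                         mode = c("COH_COX", "COH_O", "OH_O")) {
  mode <- match.arg(mode)
  .check_param(pcrystal)
  atoms <- pcrystal$atoms
  n <- nrow(hbonds)
  elec <- numeric(n)
  vdw <- numeric(n)
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  for (k in seq_len(n)) {
    donor_rows <- switch(mode,
      OH_O = c(hbonds$donor_O_row[k], hbonds$donor_H_row[k]),
      c(hbonds$donor_C_row[k], hbonds$donor_O_row[k], hbonds$donor_H_row[k]))
    if (mode == "COH_COX") {
      members <- .acceptor_group_of(hbonds$acceptor_O[k])
      acc_rows <- match(paste(hbonds$acceptor_chain[k],
                              hbonds$acceptor_resno[k], members), key)
      if (anyNA(acc_rows))
        stop("acceptor group member(s) missing for ", hbonds$class_label[k],
             " in chain ", hbonds$acceptor_chain[k], " residue ",
             hbonds$acceptor_resno[k], ": ",
             paste(members[is.na(acc_rows)], collapse = ", "))
    } else {
      acc_rows <- hbonds$acceptor_O_row[k]
    }
    e <- .pair_list_sum(atoms,
                        rep(donor_rows, times = length(acc_rows)),
                        rep(acc_rows, each = length(donor_rows)))
    elec[k] <- e["electrostatic"]
    vdw[k] <- e["vdw"]
  }
  hbonds$electrostatic <- elec
  hbonds$vdw <- vdw
  hbonds$mode <- mode
  hbonds
}

#' Per-glucose hydrogen-bond energy, averaged over chain parities
#'
#' Each bond's energy is attributed to the glucose unit of its donor.  For
#' each chain parity (origin, center) the energies of the selected bonds are
#' summed and divided by the number of glucose units considered; the
#' returned value is the mean of the origin-chain and center-chain
#' per-glucose sums.
#'
#' @param hbonds An \code{hbond_table} with energies
#'   (\code{\link{hbond_energy}}).
#' @param scope \code{"inter"} or \code{"intra"}; only bonds of this scope
#'   are summed.
#' @param value Column to aggregate (\code{"electrostatic"} or
#'   \code{"vdw"}).
#' @param n_per_parity Optional named vector giving the number of glucose
#'   units per parity over which the sums are normalized (e.g.
#'   \code{c(origin = 120, center = 120)} for bonds collected from 30
#'   central chains of 12-mers restricted to 8 interior units).  By default
#'   the distinct donor residues of each parity are counted.
#' @return Per-glucose energy in kcal/mol (mean over parities).
#' @export
aggregate_per_glucose <- function(hbonds, scope = c("inter", "intra"),
                                  value = "electrostatic",
                                  n_per_parity = NULL) {
  scope <- match.arg(scope)
  if (!value %in% names(hbonds))
    stop("no ", value, " column; run hbond_energy() first")
  hb <- hbonds[hbonds$scope == scope, , drop = FALSE]
  if (nrow(hb) == 0) return(0)
  if (any(!hb$donor_parity %in% c("origin", "center")))
    stop("bonds with unclassified donor-chain parity; classify parity first")
  parities <- sort(unique(hb$donor_parity))
  per <- vapply(parities, function(p) {
    sel <- hb$donor_parity == p
    n <- if (!is.null(n_per_parity)) {
      if (!p %in% names(n_per_parity))
        stop("n_per_parity has no entry for parity ", p)
      n_per_parity[[p]]
    } else {
      length(unique(paste(hb$donor_chain[sel], hb$donor_resno[sel])))
    }
    if (n <= 0) stop("non-positive glucose count for parity ", p)
    sum(hb[[value]][sel]) / n
  }, numeric(1))
  mean(per)
}

#' Hydrogen-bond share of the interchain electrostatic energy
#'
#' Ratio of the per-glucose interchain hydrogen-bond electrostatic energy to
#' the bulk interchain electrostatic energy per glucose unit, as a percent.
#' Both quantities are negative (attractive) for cellulose, giving a
#' positive percentage; the ratio is reported rounded to integer percent.
#'
#' @param hbond_per_glucose Per-glucose hydrogen-bond energy, kcal/mol.
#' @param bulk_elec_per_glucose Bulk interchain electrostatic energy per
#'   glucose, kcal/mol (nonzero).
#' @return Integer percent.
#' @export
fraction_of_interchain_electrostatics <- function(hbond_per_glucose,
                                                  bulk_elec_per_glucose) {
  if (!is.finite(bulk_elec_per_glucose) || bulk_elec_per_glucose == 0)
    stop("bulk electrostatic energy must be nonzero")
  round(100 * hbond_per_glucose / bulk_elec_per_glucose)
}
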