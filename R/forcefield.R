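#' @title Force-field tables for cellulose nonbonded energetics
#' @name forcefield
#' @description Partial charges and Lennard-Jones parameters for the atoms of
#'   an anhydroglucose unit, with support for the osmotic-pressure-recalibrated
#'   force-field variant (well depths rescaled by 0.94) and for terminal-charge
#'   neutralization.
NULL

#' Coulomb prefactor used by the GLYCAM family of force fields.
#'
#' The electrostatic energy of two atoms with partial charges \eqn{q_i, q_j}
#' (in e) at distance \eqn{r} (in Angstrom) is \eqn{Q_i Q_j / r} with
#' \eqn{Q = 18.2223 q}, i.e. a prefactor of \eqn{18.2223^2 \approx 332.05}
#' kcal mol\eqn{^{-1}} Angstrom e\eqn{^{-2}}.
#' @keywords internal
COULOMB_PREFACTOR <- 18.2223^2

#' Names of the recognized force-field variants
#' @keywords internal
FF_VARIANTS <- c("GLYCAM06", "GLYCAM06_OSMOr14_TIP5P")

#' Load a nonbonded parameter table
#'
#' Reads a plain-text parameter table (one row per atom name: partial charge
#' in e, vdW radius in Angstrom, well depth in kcal/mol) and applies the
#' well-depth rescaling of the requested force-field variant.  The
#' \code{GLYCAM06_OSMOr14_TIP5P} variant rescales the Lennard-Jones well
#' depths of all non-exempt atom types by 0.94, a recalibration fitted to
#' osmotic pressures of carbohydrate solutions; partial charges are identical
#' between variants.
#'
#' @param variant Force-field variant, one of \code{"GLYCAM06"} (no
#'   rescaling) or \code{"GLYCAM06_OSMOr14_TIP5P"} (well depths times 0.94).
#' @param table_source Path to the parameter table.  Defaults to the table
#'   packaged in \code{inst/extdata}.
#' @param exempt_types Character vector of atom names whose well depth is
#'   \emph{not} rescaled in the recalibrated variant.  Default: none.
#' @return An object of class \code{"forcefield"}: a data frame with columns
#'   \code{name}, \code{charge}, \code{radius}, \code{epsilon}, and
#'   attributes \code{variant}, \code{epsilon_scale} and \code{exempt_types}.
#' @examples
#' ff <- load_forcefield()
#' ff[ff$name == "O3", ]        # charge -0.709 e, radius 3.442 A
#' @export
load_forcefield <- function(variant = "GLYCAM06",
                            table_source = default_parameter_table(),
                            exempt_types = character()) {
  variant <- match.arg(variant, FF_VARIANTS)
  if (!file.exists(table_source))
    stop("parameter table not found: ", table_source)
  tab <- utils::read.table(table_source, header = FALSE, comment.char = "#",
                           col.names = c("name", "charge", "radius", "eps"),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab$name))
    stop("duplicate atom name(s) in parameter table: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  if (any(!is.finite(tab$charge)) || any(!is.finite(tab$radius)) ||
      any(!is.finite(tab$eps)))
    stop("non-finite parameter value in table ", table_source)
  if (any(tab$radius <= 0))
    stop("non-positive vdW radius for atom(s): ",
         paste(tab$name[tab$radius <= 0], collapse = ", "))
  if (any(tab$eps < 0))
    stop("negative well depth for atom(s): ",
         paste(tab$name[tab$eps < 0], collapse = ", "))

  scale <- if (variant == "GLYCAM06_OSMOr14_TIP5P") 0.94 else 1.0
  eps <- tab$eps
  rescale <- !(tab$name %in% exempt_types)
  eps[rescale] <- eps[rescale] * scale

  ff <- data.frame(name = tab$name, charge = tab$charge,
                   radius = tab$radius, epsilon = eps,
                   stringsAsFactors = FALSE)
  attr(ff, "variant") <- variant
  attr(ff, "epsilon_scale") <- scale
  attr(ff, "exempt_types") <- exempt_types
  class(ff) <- c("forcefield", "data.frame")
  ff
}

#' Path of the packaged parameter table
#' @return File path of the plain-text parameter table shipped with the
#'   package.
#' @export
default_parameter_table <- function() {
  system.file("extdata", "glycam06_cellulose.par", package = "cellenergy",
              mustWork = TRUE)
}

#' Near-neutral charge groups of the glucose unit
#'
#' The charged atoms of a central glucose unit form four nearly neutral
#' groups: the three hydroxyl COH groups (C2-O2-HO2, C3-O3-HO3, C6-O6-HO6)
#' and the five remaining charged atoms around the ring-oxygen acceptor O5
#' (O4, C1, O5, C5, C4).  These groups are the basis of the multipole
#' hydrogen-bond description: an O5 acceptor contributes all five atoms of
#' its group.
#'
#' @param ff Optional \code{forcefield} used to attach net group charges.
#' @return A list of \code{charge_group} objects, each with fields
#'   \code{label}, \code{member_atom_names} and (when \code{ff} is supplied)
#'   \code{net_charge}.
#' @export
charge_groups <- function(ff = NULL) {
  groups <- list(
    list(label = "C2O2H",    member_atom_names = c("C2", "O2", "HO2")),
    list(label = "C3O3H",    member_atom_names = c("C3", "O3", "HO3")),
    list(label = "C6O6H",    member_atom_names = c("C6", "O6", "HO6")),
    list(label = "O5-group", member_atom_names = c("O4", "C1", "O5", "C5", "C4"))
  )
  if (!is.null(ff)) {
    for (i in seq_along(groups)) {
      m <- match(groups[[i]]$member_atom_names, ff$name)
      if (anyNA(m))
        stop("charge group ", groups[[i]]$label, " has members missing from ",
             "the force field: ",
             paste(groups[[i]]$member_atom_names[is.na(m)], collapse = ", "))
      groups[[i]]$net_charge <- sum(ff$charge[m])
    }
  }
  lapply(groups, function(g) structure(g, class = "charge_group"))
}

#' Atom names of one interior glucose unit carrying nonzero charge
#' @keywords internal
charged_glucose_atoms <- function() {
  c("C1", "C2", "C3", "C4", "C5", "C6",
    "O2", "O3", "O4", "O5", "O6",
    "HO2", "HO3", "HO6")
}

#' Assign force-field parameters to a crystal
#'
#' Attaches a partial charge, vdW radius and well depth to every atom of a
#' crystal by atom-name lookup in a force-field table.
#'
#' @param crystal A \code{cellulose_crystal} (see \code{\link{build_crystal}}
#'   or \code{\link{read_pdb}}).
#' @param ff A \code{forcefield} from \code{\link{load_forcefield}}.
#' @return A \code{parameterized_crystal}: the input crystal whose atom table
#'   gains columns \code{charge}, \code{radius}, \code{epsilon}.
#' @export
assign_parameters <- function(crystal, ff) {
  stopifnot(inherits(crystal, "cellulose_crystal"), inherits(ff, "forcefield"))
  atoms <- crystal$atoms
  if (nrow(atoms) == 0) {
    crystal$atoms <- cbind(atoms, charge = numeric(0), radius = numeric(0),
                           epsilon = numeric(0))
    class(crystal) <- unique(c("parameterized_crystal", class(crystal)))
    return(crystal)
  }
  idx <- match(atoms$name, ff$name)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("atom name(s) not in force field: ",
         paste(sprintf("%s (chain %s residue %d)",
                       atoms$name[bad], atoms$chain[bad], atoms$resno[bad])[
                         seq_len(min(5, length(bad)))],
               collapse = "; "),
         if (length(bad) > 5) sprintf(" ... and %d more", length(bad) - 5))
  }
  atoms$charge <- ff$charge[idx]
  atoms$radius <- ff$radius[idx]
  atoms$epsilon <- ff$epsilon[idx]
  crystal$atoms <- atoms
  attr(crystal, "forcefield_variant") <- attr(ff, "variant")
  class(crystal) <- unique(c("parameterized_crystal", class(crystal)))
  crystal
}

#' Neutralize the terminal glucose units of every chain
#'
#' Chain-terminal glucose units carry the extra cap atoms of the reducing and
#' non-reducing ends and are therefore not neutral under the standard charge
#' set.  Because a net residue charge would make the interchain electrostatics
#' long-ranged (in a crystal in vacuo there is no solvent to screen it), the
#' excess charge of each terminal residue is removed by adjusting the partial
#' charges of that residue's hydrogen atoms: the excess is distributed equally
#' over all H atoms of the terminal residue.  Interior residues are untouched,
#' and the operation is idempotent.
#'
#' @param pcrystal A \code{parameterized_crystal}.
#' @param tol Residues within \code{tol} e of neutrality are left unchanged.
#' @return The crystal with every terminal glucose unit neutral.
#' @export
neutralize_termini <- function(pcrystal, tol = 1e-12) {
  stopifnot(inherits(pcrystal, "parameterized_crystal"))
  atoms <- pcrystal$atoms
  if (nrow(atoms) == 0) return(pcrystal)
  for (cid in unique(atoms$chain)) {
    sel_chain <- atoms$chain == cid
    rr <- range(atoms$resno[sel_chain])
    for (res in unique(rr)) {
      sel <- sel_chain & atoms$resno == res
      excess <- sum(atoms$charge[sel])
      if (abs(excess) <= tol) next
      is_h <- sel & grepl("^H", atoms$name)
      nh <- sum(is_h)
      if (nh == 0)
        stop("terminal residue ", res, " of chain ", cid,
             " has no H atoms to adjust")
      atoms$charge[is_h] <- atoms$charge[is_h] - excess / nh
    }
  }
  pcrystal$atoms <- atoms
  pcrystal
}
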