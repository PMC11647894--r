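# shared fixtures for the test suite; everything is generated in code

# published pairwise electrostatic energies (kcal/mol) between the donor
# group H-O6-C6 and acceptor group H-O3-C3 of the interchain O6oH...O3o
# hydrogen bond of cellulose Ibeta; used as data to pin fixture geometry
printed_pair_energies <- function() {
  matrix(c(59.5, -30.4, -16.7,
           -56.3, 25.2, 13.7,
           -18.1, 9.2, 5.9),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("O6", "HO6", "C6"), c("O3", "HO3", "C3")))
}

# invert the Coulomb law to turn tabulated pair energies into distances
derived_pair_distances <- function(E = printed_pair_energies(),
                                   ff = load_forcefield()) {
  q <- stats::setNames(ff$charge, ff$name)
  D <- E
  for (i in rownames(E)) for (j in colnames(E))
    D[i, j] <- 18.2223^2 * q[i] * q[j] / E[i, j]
  D
}

# published hydrogen-bond geometry and donor-group/acceptor-O electrostatic
# energies for cellulose Ibeta (recalibrated-variant rows)
ibeta_hbond_rows <- function() {
  data.frame(
    donor    = c("O3", "O3", "O2", "O2", "O6", "O6", "O6", "O6"),
    acceptor = c("O5", "O5", "O6", "O6", "O3", "O3", "O2", "O2"),
    scope    = c("intra", "intra", "intra", "intra",
                 "inter", "inter", "inter", "inter"),
    parity   = c("origin", "center", "origin", "center",
                 "origin", "center", "origin", "center"),
    d_HO  = c(1.82, 1.78, 1.81, 1.76, 1.77, 1.90, 2.97, 2.98),
    d_OO  = c(2.76, 2.74, 2.79, 2.72, 2.72, 2.87, 3.59, 3.54),
    angle = c(161, 170, 172, 166, 162, 170, 122, 118),
    coh_o = c(-9.7, -10.4, -15.7, -15.9, -14.9, -14.4, -7.5, -9.5),
    stringsAsFactors = FALSE)
}

# bond table shaped like the published interchain class energies, one donor
# glucose per parity, for the per-glucose aggregation arithmetic
class_energy_table <- function(origin_values, center_values) {
  data.frame(
    donor_chain = c("A", "A", "B", "B"),
    donor_resno = 1L,
    donor_parity = c("origin", "origin", "center", "center"),
    scope = "inter",
    electrostatic = c(origin_values, center_values),
    stringsAsFactors = FALSE)
}

small_ibeta <- function(n_chains = 6, dp = 4, variant = "GLYCAM06") {
  cr <- build_crystal("Ibeta", n_chains, dp)
  neutralize_termini(assign_parameters(cr, load_forcefield(variant)))
}
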