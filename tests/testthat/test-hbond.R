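test_that("hydrogen-bond geometry follows the collinear and right-angle constructions", {
  g <- hbond_geometry(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0))
  expect_equal(unname(g["d_HO"]), 1.8)
  expect_equal(unname(g["d_OO"]), 2.8)
  expect_equal(unname(g["angle"]), 180)

  g90 <- hbond_geometry(c(0, 1, 0), c(0, 0, 0), c(2, 0, 0))
  expect_equal(unname(g90["angle"]), 90)

  expect_error(hbond_geometry(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "coincident")
})

test_that("fixtures built at tabulated geometries recompute to those geometries", {
  rows <- ibeta_hbond_rows()
  for (k in seq_len(nrow(rows))) {
    fx <- make_hbond_fixture(rows$donor[k], rows$acceptor[k],
                             rows$d_HO[k], rows$d_OO[k], rows$angle[k],
                             scope = rows$scope[k])
    g <- attr(fx, "geometry")
    expect_equal(unname(g["d_HO"]), rows$d_HO[k], tolerance = 1e-6)
    expect_equal(unname(g["d_OO"]), rows$d_OO[k], tolerance = 1e-6)
    expect_equal(unname(g["angle"]), rows$angle[k], tolerance = 1e-6)
  }
})

test_that("detection admits tabulated strong and weak bonds and rejects distant pairs", {
  strong <- make_hbond_fixture("O6", "O3", 1.77, 2.72, 162)
  hb <- detect_hbonds(strong)
  expect_true("O6oH...O3o inter" %in% hb$class_label)

  weak <- make_hbond_fixture("O6", "O2", 2.97, 3.59, 122)
  hbw <- detect_hbonds(weak)
  expect_true(any(hbw$donor_O == "O6" & hbw$acceptor_O == "O2"))

  far <- make_hbond_fixture("O6", "O3", 8.0, 8.9, 160)
  expect_equal(nrow(detect_hbonds(far)), 0)
})

test_that("structures without hydroxyl hydrogens are refused with advice", {
  pc <- small_ibeta(2, 2)
  pc$atoms <- pc$atoms[!grepl("^HO", pc$atoms$name), ]
  expect_error(detect_hbonds(pc), "hydrogen")
})

test_that("loosening the criteria never removes a detected bond", {
  pc <- small_ibeta(6, 4)
  tight <- detect_hbonds(pc, max_d_HO = 2.2, min_angle = 140)
  loose <- detect_hbonds(pc, max_d_HO = 3.0, min_angle = 115)
  key <- function(h) paste(h$donor_chain, h$donor_resno, h$donor_O,
                           h$acceptor_chain, h$acceptor_resno, h$acceptor_O)
  expect_true(all(key(tight) %in% key(loose)))
  expect_gte(nrow(loose), nrow(tight))
})

test_that("scoring modes nest additively and a chargeless fixture scores zero", {
  fx <- make_hbond_fixture("O6", "O3", 1.77, 2.72, 162)
  hb <- detect_hbonds(fx)[1, , drop = FALSE]
  e_oho <- hbond_energy(fx, hb, "OH_O")
  e_coho <- hbond_energy(fx, hb, "COH_O")
  e_cox <- hbond_energy(fx, hb, "COH_COX")

  # COH_COX = COH_O + donor triple vs the non-O acceptor-group atoms
  a <- fx$atoms
  donor <- a[a$resno == 1, ]
  rest <- a[a$resno == 2 & a$name != "O3", ]
  extra <- group_interaction_energy(donor, rest)
  expect_equal(e_cox$electrostatic,
               e_coho$electrostatic + unname(extra["electrostatic"]),
               tolerance = 1e-10)
  expect_equal(e_cox$vdw, e_coho$vdw + unname(extra["vdw"]),
               tolerance = 1e-10)

  # naive OH/O scoring is repulsive at this geometry: the O-O repulsion
  # exceeds the H-O attraction
  expect_gt(e_oho$electrostatic, 0)
  expect_gt(coulomb_energy(-0.688, -0.709, 2.72) +
              coulomb_energy(0.424, -0.709, 1.77), 0)

  fx0 <- fx
  fx0$atoms$charge <- 0
  for (m in c("OH_O", "COH_O", "COH_COX"))
    expect_equal(hbond_energy(fx0, hb, m)$electrostatic, 0)
})

test_that("O5 acceptors use the five-atom acceptor group", {
  fx <- make_hbond_fixture("O3", "O5", 1.82, 2.76, 161, scope = "intra")
  expect_setequal(fx$atoms$name[fx$atoms$resno == 2],
                  c("O4", "C1", "O5", "C5", "C4"))
  hb <- detect_hbonds(fx)
  hb <- hb[hb$acceptor_O == "O5", , drop = FALSE]
  expect_equal(nrow(hb), 1)
  e <- hbond_energy(fx, hb, "COH_COX")
  expect_true(is.finite(e$electrostatic))
  # the missing-member error names the absent atom
  fx2 <- fx
  fx2$atoms <- fx2$atoms[fx2$atoms$name != "C5", ]
  hb2 <- detect_hbonds(fx2)
  hb2 <- hb2[hb2$acceptor_O == "O5", , drop = FALSE]
  expect_error(hbond_energy(fx2, hb2, "COH_COX"), "C5")
})

test_that("donor-group/acceptor-O energies at tabulated geometries track the published column", {
  # planar idealized fixtures; the 1 kcal/mol allowance covers the
  # out-of-plane freedom the three geometry numbers do not pin down
  rows <- ibeta_hbond_rows()
  for (k in seq_len(nrow(rows))) {
    fx <- make_hbond_fixture(rows$donor[k], rows$acceptor[k],
                             rows$d_HO[k], rows$d_OO[k], rows$angle[k],
                             scope = rows$scope[k])
    hb <- detect_hbonds(fx, max_d_HO = 3.1, min_angle = 110)
    hb <- hb[hb$acceptor_O == rows$acceptor[k] &
               hb$donor_O == rows$donor[k], , drop = FALSE]
    expect_equal(nrow(hb), 1)
    e <- hbond_energy(fx, hb, "COH_O")
    expect_equal(e$electrostatic, rows$coh_o[k], tolerance = 1,
                 expected.label = sprintf("published %s -> %s value",
                                          rows$donor[k], rows$acceptor[k]))
    # vdW contact repulsion whenever the oxygens sit below contact distance
    if (rows$d_OO[k] < 3.0) expect_gt(e$vdw, 0)
  }
})

test_that("per-glucose aggregation averages the parity sums and guards its inputs", {
  cox <- class_energy_table(c(-8.1, -0.7), c(-6.7, -2.3))
  expect_equal(aggregate_per_glucose(cox, "inter"), -8.9, tolerance = 1e-12)
  coh <- class_energy_table(c(-14.9, -7.5), c(-14.4, -9.5))
  expect_equal(aggregate_per_glucose(coh, "inter"), -23.15,
               tolerance = 1e-12)
  expect_equal(aggregate_per_glucose(cox[0, ], "inter"), 0)

  bad <- cox
  bad$donor_parity[2] <- "unclassified"
  expect_error(aggregate_per_glucose(bad, "inter"), "parity")

  # explicit glucose counts rescale the sums
  expect_equal(aggregate_per_glucose(cox, "inter",
                                     n_per_parity = c(origin = 2, center = 2)),
               -8.9 / 2, tolerance = 1e-12)
})

test_that("the hydrogen-bond share of interchain electrostatics reproduces the published percentages", {
  expect_equal(fraction_of_interchain_electrostatics(-8.9, -13.5), 66)
  expect_equal(fraction_of_interchain_electrostatics(-15.75, -21.5), 73)
  expect_equal(fraction_of_interchain_electrostatics(0, -13.5), 0)
  expect_error(fraction_of_interchain_electrostatics(-8.9, 0), "nonzero")
})
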