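test_that("Coulomb energy is symmetric, scales as 1/r, and vanishes for zero charge", {
  set.seed(11)
  for (k in 1:20) {
    q1 <- runif(1, -1, 1); q2 <- runif(1, -1, 1)
    r <- runif(1, 0.5, 20); a <- runif(1, 0.5, 4)
    expect_equal(coulomb_energy(q1, q2, r), coulomb_energy(q2, q1, r))
    expect_equal(coulomb_energy(q1, q2, a * r),
                 coulomb_energy(q1, q2, r) / a, tolerance = 1e-12)
  }
  expect_identical(coulomb_energy(0, -0.7, 3), 0)
  expect_error(coulomb_energy(0.1, 0.1, 0), "positive")
  expect_error(coulomb_energy(0.1, 0.1, -2), "positive")
})

test_that("Lennard-Jones well has exact depth and location and decays to nothing", {
  pi_ <- list(radius = 3.442, epsilon = 0.2104)
  pj <- list(radius = 3.3674, epsilon = 0.17)
  rmin <- (pi_$radius + pj$radius) / 2
  eps <- sqrt(pi_$epsilon * pj$epsilon)
  expect_equal(lj_energy(pi_, pj, rmin), -eps, tolerance = 1e-14)
  # rmin is the argmin
  expect_equal(stats::optimize(function(r) lj_energy(pi_, pj, r),
                               c(2, 6), tol = 1e-10)$minimum, rmin,
               tolerance = 1e-6)
  expect_lt(abs(lj_energy(pi_, pj, 10 * rmin)), 1e-5 * eps)
  # two hydroxyl oxygens below contact distance repel
  o3 <- list(radius = 3.442, epsilon = 0.2104)
  expect_gt(lj_energy(o3, o3, 2.72), 0)
  expect_error(lj_energy(pi_, pj, 0), "positive")
})

test_that("group interaction equals the double pairwise sum and rejects overlap", {
  set.seed(12)
  mk <- function(n, x0) data.frame(
    serial = seq_len(n) + round(x0 * 100),
    x = x0 + runif(n), y = runif(n), z = runif(n),
    charge = runif(n, -0.5, 0.5), radius = runif(n, 2.5, 3.8),
    epsilon = runif(n, 0.05, 0.25))
  a <- mk(4, 0); b <- mk(3, 6)
  got <- group_interaction_energy(a, b)
  elec <- 0; vdw <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    r <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                     as.numeric(b[j, c("x", "y", "z")]))^2))
    elec <- elec + coulomb_energy(a$charge[i], b$charge[j], r)
    vdw <- vdw + lj_energy(a[i, ], b[j, ], r)
  }
  expect_equal(unname(got["electrostatic"]), elec, tolerance = 1e-12)
  expect_equal(unname(got["vdw"]), vdw, tolerance = 1e-12)

  expect_error(group_interaction_energy(a, a), "overlap")
  a0 <- a; a0$charge <- 0
  expect_equal(unname(group_interaction_energy(a0, b)["electrostatic"]), 0)
})

test_that("interchain energy is zero for one chain and symmetric for identical chains", {
  one <- make_toy_crystal(1, 4)
  e <- interchain_energy(one)
  expect_equal(e$electrostatic, 0)
  expect_equal(e$vdw, 0)

  two <- make_toy_crystal(2, 4)
  e2 <- interchain_energy(two)
  expect_equal(e2$per_chain$electrostatic[1], e2$per_chain$electrostatic[2],
               tolerance = 1e-12)
  expect_equal(e2$per_chain$vdw[1], e2$per_chain$vdw[2], tolerance = 1e-12)
  # totals are the configured aggregate of the per-chain values
  expect_equal(e2$electrostatic, mean(e2$per_chain$electrostatic),
               tolerance = 1e-12)
  es <- interchain_energy(two, aggregate = "sum")
  expect_equal(es$electrostatic, sum(e2$per_chain$electrostatic),
               tolerance = 1e-12)
})

test_that("intrachain exclusions drop 1-2 and 1-3 pairs and keep 1-4 and beyond", {
  # two bonded atoms: everything excluded
  atoms <- data.frame(chain = "A", resno = 1L, resid = "TOY",
                      name = c("Q1", "Q2"), element = "Q",
                      x = c(0, 1.2), y = 0, z = 0,
                      charge = c(0.3, -0.3), radius = 3, epsilon = 0.1,
                      serial = 1:2)
  chains <- data.frame(chain_id = "A", parity = "origin", dir_x = 0,
                       dir_y = 0, dir_z = 1, dp = 1L)
  cr <- structure(list(form = "toy", atoms = atoms, chains = chains,
                       template = NULL, central_chain_ids = NULL,
                       bonds = cbind(1L, 2L)),
                  class = c("parameterized_crystal", "cellulose_crystal"))
  e <- intrachain_nonbonded_energy(cr)
  expect_equal(e$electrostatic, 0)
  expect_equal(e$vdw, 0)

  # linear 4-atom chain: only the 1-4 pair survives under 1-3 exclusions
  a4 <- data.frame(chain = "A", resno = 1L, resid = "TOY",
                   name = paste0("Q", 1:4), element = "Q",
                   x = c(0, 1.5, 3.0, 4.5), y = 0, z = 0,
                   charge = c(0.4, -0.2, -0.2, 0.4),
                   radius = 3, epsilon = 0.1, serial = 1:4)
  cr4 <- structure(list(form = "toy", atoms = a4, chains = chains,
                        template = NULL, central_chain_ids = NULL,
                        bonds = cbind(1:3, 2:4)),
                   class = c("parameterized_crystal", "cellulose_crystal"))
  e4 <- intrachain_nonbonded_energy(cr4)
  r14 <- 4.5
  expect_equal(e4$electrostatic, coulomb_energy(0.4, 0.4, r14),
               tolerance = 1e-12)
  expect_equal(e4$vdw,
               lj_energy(list(radius = 3, epsilon = 0.1),
                         list(radius = 3, epsilon = 0.1), r14),
               tolerance = 1e-10)
  # with 1-2 exclusions only, the two 1-3 pairs come back
  e12 <- intrachain_nonbonded_energy(cr4, exclusions = "1-2")
  expect_equal(e12$electrostatic,
               e4$electrostatic + 2 * coulomb_energy(0.4, -0.2, 3.0),
               tolerance = 1e-12)

  # a charge-free chain leaves a pure vdW result
  cr0 <- cr4
  cr0$atoms$charge <- 0
  e0 <- intrachain_nonbonded_energy(cr0)
  expect_equal(e0$electrostatic, 0)
  expect_equal(e0$vdw, e4$vdw, tolerance = 1e-12)
})

test_that("unparameterized input is refused", {
  cr <- build_crystal("Ibeta", 2, 2)
  expect_error(interchain_energy(cr), "parameterized")
})
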