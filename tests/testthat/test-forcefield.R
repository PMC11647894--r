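test_that("packaged parameter table carries the published charges and radii", {
  ff <- load_forcefield("GLYCAM06")
  expect_equal(ff$charge[ff$name == "O3"], -0.709)
  expect_equal(ff$radius[ff$name == "O3"], 3.442)
  expect_equal(ff$charge[ff$name == "O6"], -0.688)
  expect_equal(ff$charge[ff$name == "HO6"], 0.424)
  expect_equal(ff$radius[ff$name == "O5"], 3.3674)
  expect_equal(ff$radius[ff$name == "O2"], 3.442)

  # a central glucose unit is exactly neutral
  idx <- match(charged_glucose_atoms(), ff$name)
  expect_false(anyNA(idx))
  expect_lt(abs(sum(ff$charge[idx])), 1e-10)
})

test_that("charge groups are near-neutral with the published net charges", {
  gr <- charge_groups(load_forcefield())
  nets <- vapply(gr, function(g) g$net_charge, numeric(1))
  labels <- vapply(gr, function(g) g$label, character(1))
  expect_equal(labels, c("C2O2H", "C3O3H", "C6O6H", "O5-group"))
  expect_equal(nets, c(0.029, 0.007, 0.018, -0.054), tolerance = 1e-3)
  expect_length(gr[[4]]$member_atom_names, 5)
  expect_setequal(gr[[4]]$member_atom_names, c("O4", "C1", "O5", "C5", "C4"))
})

test_that("the recalibrated variant rescales well depths by 0.94 and nothing else", {
  base <- load_forcefield("GLYCAM06")
  osmo <- load_forcefield("GLYCAM06_OSMOr14_TIP5P")
  expect_equal(osmo$charge, base$charge)
  expect_equal(osmo$radius, base$radius)
  nz <- base$epsilon > 0
  expect_equal(osmo$epsilon[nz] / base$epsilon[nz],
               rep(0.94, sum(nz)), tolerance = 1e-12)

  ex <- load_forcefield("GLYCAM06_OSMOr14_TIP5P", exempt_types = c("O5", "C1"))
  expect_equal(ex$epsilon[ex$name == "O5"], base$epsilon[base$name == "O5"])
  expect_equal(ex$epsilon[ex$name == "C1"], base$epsilon[base$name == "C1"])
  expect_equal(ex$epsilon[ex$name == "O3"],
               0.94 * base$epsilon[base$name == "O3"])
})

test_that("malformed parameter tables are rejected", {
  expect_error(load_forcefield(table_source = tempfile()), "not found")
  bad <- tempfile(fileext = ".par")
  writeLines(c("O3 -0.709 -1.0 0.21"), bad)
  expect_error(load_forcefield(table_source = bad), "radius.*O3")
})

test_that("assign_parameters parameterizes every atom and keeps central residues neutral", {
  cr <- build_crystal("Ibeta", 4, 4)
  pc <- assign_parameters(cr, load_forcefield())
  expect_s3_class(pc, "parameterized_crystal")
  expect_false(anyNA(pc$atoms$charge))
  # interior residues (2 .. dp-1) are neutral without any adjustment
  for (cid in pc$chains$chain_id) {
    sel <- pc$atoms$chain == cid & pc$atoms$resno %in% 2:3
    for (r in unique(pc$atoms$resno[sel])) {
      net <- sum(pc$atoms$charge[sel & pc$atoms$resno == r])
      expect_lt(abs(net), 1e-10)
    }
  }
})

test_that("unknown atom names abort with the atom named", {
  cr <- build_crystal("Ibeta", 2, 2)
  cr$atoms$name[5] <- "XX"
  expect_error(assign_parameters(cr, load_forcefield()), "XX")
})

test_that("an empty crystal parameterizes to an empty structure", {
  cr <- build_crystal("Ibeta", 2, 2)
  cr$atoms <- cr$atoms[0, ]
  pc <- assign_parameters(cr, load_forcefield())
  expect_equal(nrow(pc$atoms), 0)
  expect_true("charge" %in% names(pc$atoms))
})

test_that("neutralize_termini zeroes terminal residues, touches only their hydrogens, and is idempotent", {
  pc0 <- assign_parameters(build_crystal("Ibeta", 3, 6), load_forcefield())
  pc <- neutralize_termini(pc0)
  a0 <- pc0$atoms
  a1 <- pc$atoms
  for (cid in pc$chains$chain_id) {
    sel <- a1$chain == cid
    for (r in range(a1$resno[sel]))
      expect_lt(abs(sum(a1$charge[sel & a1$resno == r])), 1e-10)
  }
  interior <- a1$resno %in% 2:5
  expect_identical(a1$charge[interior], a0$charge[interior])
  changed <- which(a1$charge != a0$charge)
  expect_true(all(grepl("^H", a1$name[changed])))
  expect_true(all(a1$resno[changed] %in% c(1, 6)))
  # coordinates and every non-charge column are untouched
  expect_identical(a1[setdiff(names(a1), "charge")],
                   a0[setdiff(names(a0), "charge")])
  # fixed point
  pc2 <- neutralize_termini(pc)
  expect_identical(pc2$atoms$charge, pc$atoms$charge)
})

test_that("a charged terminal residue without hydrogens is a hard error", {
  pc <- assign_parameters(build_crystal("Ibeta", 1, 2), load_forcefield())
  a <- pc$atoms
  drop <- a$resno == 1 & grepl("^H", a$name)
  pc$atoms <- a[!drop, ]
  expect_error(neutralize_termini(pc), "no H atoms")
})
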