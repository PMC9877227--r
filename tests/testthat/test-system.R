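test_that("minimal-image distance matches identity, wrap, and the 27-image oracle", {
  expect_equal(minimal_image_distance(c(0, 0, 0), c(0, 0, 0),
                                      c(50, 50, 50)), 0)
  expect_equal(minimal_image_distance(c(1, 0, 0), c(99, 0, 0),
                                      c(100, 100, 100)), 2)
  expect_error(minimal_image_distance(c(0, 0, 0), c(1, 1, 1), c(10, -1, 10)),
               "positive")
  set.seed(42)
  box <- c(37, 52, 24)
  for (q in 1:1000) {
    a <- runif(3, 0, 1) * box; b <- runif(3, 0, 1) * box
    expect_equal(minimal_image_distance(a, b, box), bf_min_image(a, b, box),
                 tolerance = 1e-12)
  }
  # symmetry
  a <- c(3, 40, 11); b <- c(35, 2, 20)
  expect_equal(minimal_image_distance(a, b, box),
               minimal_image_distance(b, a, box))
})

test_that("leaflet assignment splits by marker z about the midplane", {
  lip <- data.frame(resname = "DOPC", x = c(10, 10), y = c(10, 10),
                    z = c(70, 30))
  sys <- make_flat_system(lip, species = simple_species(1))
  la <- assign_leaflets(sys, 1)
  expect_equal(la$midplane, 50)
  expect_setequal(unname(la$leaflet), c("upper", "lower"))
  # generator ground truth: 64 per leaflet
  cfg <- test_config(n_frames = 1L)
  s <- build_bilayer(cfg)
  la <- assign_leaflets(s, 1)
  expect_equal(sum(la$leaflet == "upper"), 64)
  expect_equal(sum(la$leaflet == "lower"), 64)
  expect_equal(unname(la$leaflet),
               attr(s, "ground_truth")$lipid_leaflet)
  # degenerate tie: all markers at one z -> all upper, with a warning
  lip2 <- data.frame(resname = "DOPC", x = c(5, 15), y = c(5, 15),
                     z = c(40, 40))
  sys2 <- make_flat_system(lip2, species = simple_species(1))
  expect_warning(la2 <- assign_leaflets(sys2, 1), "degenerate")
  expect_true(all(la2$leaflet == "upper"))
})

test_that("leaflet labels partition the lipid set in every frame", {
  cfg <- tiny_cfg()
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  nlip <- length(unique(tr$atoms$resuid[tr$atoms$segment == "lipid"]))
  for (f in c(1L, 25L, 60L)) {
    la <- assign_leaflets(tr, f)
    expect_equal(length(la$leaflet), nlip)
    expect_equal(sum(la$leaflet == "upper") + sum(la$leaflet == "lower"),
                 nlip)
  }
})

test_that("binding-leaflet detection finds the generator's first contact", {
  cfg <- tiny_cfg()
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  gt <- attr(tr, "ground_truth")
  bl <- detect_binding_leaflet(tr)
  expect_equal(bl$leaflet, "upper")
  expect_equal(bl$frame, gt$first_contact_frame)
  # cutoff 0 -> no contact sentinel
  bl0 <- detect_binding_leaflet(tr, cutoff = 0)
  expect_true(is.na(bl0$leaflet))
  # protein parked far above for the whole run -> sentinel (tall box so
  # the periodic z-image stays out of reach too)
  cfg2 <- test_config(n_frames = 10L, binding_frame = 200L,
                      start_height = 60, box = c(56.6, 56.6, 200))
  tr2 <- simulate_trajectory(build_bilayer(cfg2), cfg2)
  bl2 <- detect_binding_leaflet(tr2)
  expect_true(is.na(bl2$leaflet))
  expect_true(is.na(bl2$frame))
  expect_error(detect_binding_leaflet(tr, window = integer()), "empty")
})

test_that("systems written to PDB/GRO/DCD reload with identical bookkeeping", {
  cfg <- test_config(n_frames = 5L)
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  d <- withr::local_tempdir()
  paths <- write_system(tr, d, "syn")
  s_dcd <- load_system(paths["pdb"], paths["dcd"])
  expect_equal(n_atoms(s_dcd), n_atoms(tr))
  expect_equal(n_frames(s_dcd), n_frames(tr))
  expect_equal(table(s_dcd$atoms$species[s_dcd$atoms$role == "marker"]),
               table(tr$atoms$species[tr$atoms$role == "marker"]))
  expect_lt(max(abs(s_dcd$coords - tr$coords)), 1e-4)
  s_gro <- load_system(paths["gro"])
  expect_equal(n_atoms(s_gro), n_atoms(tr))
  expect_lt(max(abs(s_gro$coords[, , 1] - tr$coords[, , 1])), 6e-3)
  s_pdb <- load_system(paths["pdb"], paths["traj_pdb"])
  expect_equal(n_frames(s_pdb), n_frames(tr))
  expect_lt(max(abs(s_pdb$coords - tr$coords)), 1e-3)
})

test_that("loading rejects mismatched, unknown and unsupported inputs", {
  cfg <- test_config(n_frames = 3L)
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  d <- withr::local_tempdir()
  paths <- write_system(tr, d, "syn")
  # frame atom count != structure atom count
  small <- make_flat_system(
    data.frame(resname = "DOPC", x = 1:3, y = 1, z = 50),
    species = simple_species(1))
  write_pdb(small, file.path(d, "small.pdb"))
  expect_error(load_system(file.path(d, "small.pdb"), paths["dcd"]),
               "atom count mismatch")
  # unknown lipid residue names are listed
  cfg2 <- simple_species(1)
  expect_error(load_system(paths["pdb"], species = cfg2), "CHL1|POPI")
  # unsupported format
  xtc <- file.path(d, "traj.xtc"); file.create(xtc)
  expect_error(load_system(paths["pdb"], xtc), "unsupported")
  expect_error(load_system(file.path(d, "nope.pdb")), "not found")
})

test_that("construction echo: 10 DOPC + 2 PIP2 in one frame", {
  lip <- data.frame(resname = rep(c("DOPC", "PI25"), c(10, 2)),
                    x = seq(5, 60, by = 5), y = 10, z = rep(c(70, 30), 6))
  sys <- make_flat_system(lip)
  expect_equal(length(unique(sys$atoms$resuid[sys$atoms$segment == "lipid"])),
               12)
  expect_setequal(unique(stats::na.omit(sys$atoms$species)),
                  c("DOPC", "PIP2"))
  d <- withr::local_tempdir()
  write_pdb(sys, file.path(d, "mini.pdb"))
  back <- load_system(file.path(d, "mini.pdb"), species = simple_species())
  expect_equal(sum(back$atoms$role == "marker", na.rm = TRUE), 12)
})

test_that("domain lookup excludes linker gaps between domain ranges", {
  doms <- mlkl_domains()
  lip <- data.frame(resname = "DOPC", x = c(1, 2), y = 1, z = c(70, 30))
  ca <- matrix(rep(c(50, 50, 90), 5), ncol = 3, byrow = TRUE)
  sys <- make_flat_system(lip, protein_ca = ca, species = simple_species(1))
  sys$domains <- doms
  expect_equal(domain_of(sys, c(1, 121, 125, 133, 180, 193, 459, 470)),
               c("4HB", "4HB", "linker", "brace", "linker", "PsK", "PsK",
                 "none"))
})
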