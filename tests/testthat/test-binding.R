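# flat two-leaflet fixture: markers at z = 20 (lower) and 70/taken as upper
flat_fixture <- function(ca_z = 50, nframes = 1L, n_up = 4L) {
  lip <- data.frame(resname = "DOPC",
                    x = c(seq(10, 40, length.out = n_up), 10, 40),
                    y = c(rep(10, n_up), 40, 40),
                    z = c(rep(20, n_up), 80, 80))
  ca <- matrix(c(20, 10, ca_z), ncol = 3)
  make_flat_system(lip, protein_ca = ca, nframes = nframes,
                   species = simple_species(1))
}

test_that("domain COM distance is the z-gap to the marker plane", {
  sys <- flat_fixture(ca_z = 50, nframes = 3L)
  d <- domain_com_distance(sys, "protein", leaflet = "lower")
  expect_equal(d, rep(30, 3))
  d1 <- domain_com_distance(sys, "protein", window = 2L, leaflet = "lower")
  expect_length(d1, 1)
  expect_error(domain_com_distance(sys, "nope", leaflet = "lower"),
               "unknown domain")
})

test_that("descending protein gives a non-increasing COM distance until binding", {
  cfg <- tiny_cfg()
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  d <- domain_com_distance(tr, "4HB", leaflet = "upper")
  pre <- d[1:cfg$binding_frame]
  expect_true(all(diff(pre) <= 1e-9))
  post <- d[(cfg$binding_frame + 1):n_frames(tr)]
  expect_lt(max(post) - min(post), 1.5)   # static bound protein, z noise only
})

test_that("contact frequency counts frames with the inclusive 12 A rule", {
  # one residue whose marker distance is 11.9, 12.1, 5.0 over three frames
  lip <- data.frame(resname = "DOPC", x = 10, y = 10, z = 20)
  ca <- matrix(c(10, 10, 50), ncol = 3)
  sys <- make_flat_system(lip, protein_ca = ca, nframes = 3L,
                          species = simple_species(1))
  sys$coords[1, 3, ] <- 20 + c(11.9, 12.1, 5.0)
  rc <- residue_contact_frequency(sys, leaflet = "upper")
  expect_equal(rc$pct_time, 100 * 2 / 3, tolerance = 1e-12)
  # saturation and separation
  sys$coords[1, 3, ] <- 25
  expect_equal(residue_contact_frequency(sys, leaflet = "upper")$pct_time,
               100)
  sys$coords[1, 3, ] <- 160                    # 100 A away (no wrap hit)
  sys$box[] <- 400
  expect_equal(residue_contact_frequency(sys, leaflet = "upper")$pct_time, 0)
  expect_error(residue_contact_frequency(sys, window = integer(),
                                         leaflet = "upper"), "empty")
})

test_that("contact frequency is invariant under rigid translation", {
  cfg <- tiny_cfg()
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  rc1 <- residue_contact_frequency(tr, 30:60, leaflet = "upper")
  tr2 <- tr
  tr2$coords <- tr$coords + 7.3
  rc2 <- residue_contact_frequency(tr2, 30:60, leaflet = "upper")
  expect_equal(rc1$pct_time, rc2$pct_time)
})

test_that("domain-species contacts match constructed geometry and conserve counts", {
  # single Calpha-only residue 5 A from exactly 3 DOPC markers
  lip <- data.frame(resname = rep(c("DOPC", "PI25"), c(4, 2)),
                    x = c(10, 15, 20, 40, 10, 40), y = 10,
                    z = c(55, 55, 55, 55, 20, 20))
  ca <- matrix(c(15, 10, 60), ncol = 3)
  sys <- make_flat_system(lip, protein_ca = ca, species = simple_species())
  # Calpha-marker distances: 7.07, 5, 7.07, 25.5 -> exactly 3 within 8 A
  dsc <- domain_species_contacts(sys, cutoff = 8, leaflet = "upper")
  expect_equal(dsc$mean_contacts[dsc$species == "DOPC"], 3)
  expect_equal(dsc$mean_contacts[dsc$species == "PIP2"], 0)
  # conservation: sum over species equals the pooled-marker count
  cfg <- tiny_cfg()
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  dsc2 <- domain_species_contacts(tr, 50:60, leaflet = "upper")
  pooled <- 0
  la_frames <- 50:60
  ph <- which(tr$atoms$segment == "protein" & tr$atoms$element != "H")
  for (f in la_frames) {
    mk <- lipidprint:::marker_table(tr, f)
    la <- assign_leaflets(tr, f)
    mk <- mk[la$leaflet[as.character(mk$resuid)] == "upper", ]
    D <- lipidprint:::mi_cross_dist(tr$coords[ph, , f],
                                    as.matrix(mk[, c("x", "y", "z")]),
                                    tr$box[f, ])
    pooled <- pooled + sum(D <= 12)
  }
  expect_equal(sum(dsc2$mean_contacts) * length(la_frames), pooled)
})

test_that("doubling a static window keeps means and shrinks block SE", {
  lip <- data.frame(resname = "DOPC", x = c(10, 12, 40), y = 10,
                    z = c(55, 55, 20))
  ca <- matrix(c(11, 10, 58), ncol = 3)
  sys <- make_flat_system(lip, protein_ca = ca, nframes = 10L,
                          species = simple_species(1))
  d5 <- domain_species_contacts(sys, 1:5, leaflet = "upper")
  d10 <- domain_species_contacts(sys, 1:10, leaflet = "upper")
  expect_equal(d5$mean_contacts, d10$mean_contacts)
  expect_true(all(d10$se <= d5$se + 1e-12))
})

test_that("insertion depth is signed toward the bilayer core", {
  # Calpha 3 A below the upper marker plane -> depth +3
  lip <- data.frame(resname = "DOPC", x = c(10, 20, 30, 40), y = 10,
                    z = c(70, 70, 30, 30))
  ca <- matrix(c(15, 10, 67), ncol = 3)
  sys <- make_flat_system(lip, protein_ca = ca, species = simple_species(1))
  dp <- insertion_depth(sys, leaflet = "upper")
  expect_equal(dp$profile$depth, 3)
  expect_equal(dp$deepest, 1)
  # all above the plane -> all negative, deepest = least negative
  ca2 <- matrix(c(15, 10, 75, 25, 10, 72), ncol = 3, byrow = TRUE)
  sys2 <- make_flat_system(lip, protein_ca = ca2,
                           species = simple_species(1))
  dp2 <- insertion_depth(sys2, leaflet = "upper")
  expect_true(all(dp2$profile$depth < 0))
  expect_equal(dp2$deepest,
               dp2$profile$resid[which.max(dp2$profile$depth)])
  # synthetic protein bound past the plane -> positive depth recovered
  cfg <- tiny_cfg(bound_height = -2)
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  dp3 <- insertion_depth(tr, 40:60, leaflet = "upper")
  expect_gt(max(dp3$profile$depth), 1)
})

test_that("RMSD and RMSF vanish for static and rigidly translated trajectories", {
  cfg <- test_config(n_frames = 5L, D = 0, z_jitter = 0,
                     binding_frame = 100L, bias = c(PIP2 = 0))
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  expect_equal(rmsd_series(tr), rep(0, 5), tolerance = 1e-9)
  expect_equal(rmsf(tr)$rmsf, rep(0, 16), tolerance = 1e-9)
  # rigid translation of the whole protein
  tr2 <- tr
  prot <- which(tr2$atoms$segment == "protein")
  for (f in 2:5) tr2$coords[prot, 1, f] <- tr2$coords[prot, 1, f] + 10 * f
  expect_equal(rmsd_series(tr2), rep(0, 5), tolerance = 1e-9)
})

test_that("two-frame RMSF of one displaced atom approaches d/2", {
  # many anchor atoms pin the superposition; one atom moves by d
  set.seed(7)
  n <- 200L
  ca <- cbind(runif(n, 0, 50), runif(n, 0, 50), runif(n, 40, 60))
  lip <- data.frame(resname = "DOPC", x = c(1, 2), y = 1, z = c(70, 30))
  sys <- make_flat_system(lip, protein_ca = ca, nframes = 2L,
                          species = simple_species(1))
  d <- 4
  sys$coords[n, 3, 2] <- sys$coords[n, 3, 1] + d
  rf <- rmsf(sys)
  expect_equal(rf$rmsf[n], d / 2, tolerance = 0.05)
  expect_lt(max(rf$rmsf[-n]), 0.2)
})
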