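test_that("largest-remainder composition gives exact per-species counts", {
  cfg600 <- synthetic_config(n_frames = 1L)
  s <- build_bilayer(cfg600)
  cnt <- unlist(attr(s, "ground_truth")$leaflet_counts$upper)
  expect_equal(cnt[["DOPC"]], 240)
  expect_equal(cnt[["CHOL"]], 192)
  expect_equal(cnt[["DOPE"]], 120)
  expect_equal(cnt[["PIP"]], 24)
  expect_equal(cnt[["PIP2"]], 24)
  expect_equal(sum(cnt), 600)
  # degenerate composition: everything one species
  one <- species_config(list(
    list(name = "DOPC", resnames = "DOPC", marker = "P",
         hydrophilic = c("O11", "O12"), hydrophobic = c("C21", "C22"),
         charge = 0L, molfrac = 1),
    list(name = "PIP2", resnames = "PI25", marker = "P",
         hydrophilic = c("O11", "O12"), hydrophobic = c("C21", "C22"),
         charge = -5L, molfrac = 0)))
  cfg10 <- synthetic_config(lipids_per_leaflet = 10L, box = c(25, 20, 80),
                            species = one, n_frames = 1L,
                            protein_residues = 4L, protein_radius = 5)
  s10 <- build_bilayer(cfg10)
  tab <- table(s10$atoms$species[s10$atoms$role == "marker"])
  expect_equal(as.integer(tab[["DOPC"]]), 20)
  expect_false("PIP2" %in% names(tab))
})

test_that("fixed seed reproduces the bilayer and trajectory bit-for-bit", {
  cfg <- test_config(n_frames = 10L, seed = 99L)
  s1 <- build_bilayer(cfg); s2 <- build_bilayer(cfg)
  expect_identical(s1$coords, s2$coords)
  t1 <- simulate_trajectory(s1, cfg); t2 <- simulate_trajectory(s2, cfg)
  expect_identical(t1$coords, t2$coords)
})

test_that("frozen dynamics: D = 0 and no bias leaves lateral positions fixed", {
  cfg <- test_config(n_frames = 10L, D = 0, bias = c(PIP2 = 0),
                     z_jitter = 0)
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  lip <- which(tr$atoms$segment == "lipid")
  expect_equal(tr$coords[lip, 1:2, 10], tr$coords[lip, 1:2, 1])
})

test_that("ensemble MSD follows the 2D diffusion law 4 D t", {
  msd_at <- function(tr, tmax) {
    lip <- which(tr$atoms$role == "marker")
    box <- tr$box[1, ]
    # accumulate per-frame minimal-image displacements (unwrapped track)
    disp <- matrix(0, length(lip), 2)
    out <- numeric(tmax)
    for (f in 2:(tmax + 1)) {
      for (k in 1:2) {
        d <- tr$coords[lip, k, f] - tr$coords[lip, k, f - 1]
        d <- d - box[k] * round(d / box[k])
        disp[, k] <- disp[, k] + d
      }
      out[f - 1] <- mean(rowSums(disp^2))
    }
    out
  }
  acc <- 0
  for (seed in 1:3) {
    cfg <- test_config(n_frames = 51L, D = 1, dt = 1,
                       bias = c(PIP2 = 0), seed = seed)
    tr <- simulate_trajectory(build_bilayer(cfg), cfg)
    acc <- acc + msd_at(tr, 50)
  }
  msd <- acc / 3
  for (t in c(10, 25, 50))
    expect_lt(abs(msd[t] - 4 * t) / (4 * t), 0.15)
})

test_that("recruitment bias concentrates the biased species at the protein", {
  cfg <- test_config(n_frames = 300L, binding_frame = 50L,
                     bias = c(PIP2 = 0.5), seed = 3L)
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  a <- tr$atoms
  mk <- which(a$role == "marker")
  f <- n_frames(tr)
  box <- tr$box[f, ]
  up <- tr$coords[mk, 3, 1] > box[3] / 2
  dx <- tr$coords[mk, 1, f] - box[1] / 2
  dx <- dx - box[1] * round(dx / box[1])
  dy <- tr$coords[mk, 2, f] - box[2] / 2
  dy <- dy - box[2] * round(dy / box[2])
  near <- sqrt(dx^2 + dy^2) <= 15 & up
  frac_near <- mean(a$species[mk][near] == "PIP2")
  frac_bulk <- mean(a$species[mk][up] == "PIP2")
  expect_gt(frac_near, frac_bulk)
})

test_that("species counts are conserved across frames", {
  cfg <- tiny_cfg()
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  tab1 <- table(tr$atoms$species[tr$atoms$role == "marker"])
  expect_equal(sum(tab1), 128)
  # atoms table is frame-invariant by construction; markers never leave
  # their leaflet given the small z noise
  la1 <- assign_leaflets(tr, 1)$leaflet
  la60 <- assign_leaflets(tr, 60)$leaflet
  expect_equal(la1, la60)
})

test_that("planted hydrogen-bond geometries are exact and exclusive", {
  cfg <- tiny_cfg()
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  # n = 0: no protein-lipid donor-acceptor pair within 3.2 A
  p0 <- plant_hbond_geometry(tr, 0, frame = 60)
  expect_equal(nrow(bf_hbonds(p0, 60, d_cut = 3.2, angle_cut = 180)), 0)
  # n = 7: brute-force scan finds exactly the planted pairs
  p7 <- plant_hbond_geometry(tr, 7, frame = 60)
  gt <- attr(p7, "ground_truth")$planted_hbonds
  oracle <- bf_hbonds(p7, 60)
  expect_equal(nrow(oracle), 7)
  expect_setequal(paste(oracle[, 1], oracle[, 2]),
                  paste(gt$donor, gt$acceptor))
  # angle forced to 120 degrees: distance passes, linearity fails
  p120 <- plant_hbond_geometry(tr, 1, frame = 60, angle = 120)
  expect_equal(nrow(detect_hbonds(p120, 60)), 0)
  expect_error(plant_hbond_geometry(tr, 1000, frame = 60), "exceeds")
})

test_that("planted defect patches expose the requested disk geometry", {
  cfg <- test_config(n_frames = 2L, binding_frame = 2L)
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  # area recovery at 1 A cells, several centers incl. the box corner
  for (ctr in list(c(15, 15), c(0, 10), c(28, 0))) {
    p <- plant_defect_patch(tr, 1, ctr, 5.64, "upper")
    fd <- find_defects(classify_surface(p, 1, "upper", cell = 1))
    expect_equal(nrow(fd), 1)
    expect_lt(abs(fd$area - 100) / 100, 0.10)
  }
  # two disjoint patches -> two components
  p2 <- plant_defect_patch(tr, 1, c(12, 12), 5.64, "upper")
  p2 <- plant_defect_patch(p2, 1, c(40, 40), 8, "upper")
  fd2 <- find_defects(classify_surface(p2, 1, "upper", cell = 1))
  expect_equal(nrow(fd2), 2)
  expect_lt(abs(sort(fd2$area)[1] - pi * 5.64^2) / (pi * 5.64^2), 0.12)
  expect_lt(abs(sort(fd2$area)[2] - pi * 8^2) / (pi * 8^2), 0.12)
  # halving the cell size moves the measured area by < 10%
  p <- plant_defect_patch(tr, 1, c(15, 15), 5.64, "upper")
  a1 <- find_defects(classify_surface(p, 1, "upper", cell = 1))$area
  a05 <- find_defects(classify_surface(p, 1, "upper", cell = 0.5))$area
  expect_lt(abs(a1 - a05) / a1, 0.10)
  expect_error(plant_defect_patch(tr, 1, c(10, 10), -1), "positive")
})
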