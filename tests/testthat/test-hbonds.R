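# builds a one-residue protein (CA, N, HN) plus one lipid acceptor bead
# (O11) with the acceptor at donor-acceptor distance dA and D-H...A angle
# `angle`; two far-away lipids complete a valid bilayer
hb_pair_system <- function(dA, angle = 180) {
  atoms <- data.frame(
    eleno = 1:10,
    name = c("CA", "N", "HN", "O11", rep(c("P", "O11", "O12"), 2)),
    resname = c(rep("ALA", 3), "DOPC", rep("DOPC", 3), rep("DOPC", 3)),
    resid = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L))
  Dp <- c(20, 20, 74); Hp <- c(20, 20, 73)
  # place A at distance dA from D, in-plane angle phi chosen so the
  # D-H...A angle at the hydrogen equals `angle` (numeric solve)
  ang_of <- function(phi) {
    A <- Dp + dA * c(sin(phi), 0, -cos(phi))
    w1 <- Dp - Hp; w2 <- A - Hp
    acos(sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2))) * 180 / pi
  }
  phis <- seq(0, pi, by = 1e-4)
  phi <- phis[which.min(abs(vapply(phis, ang_of, 0) - angle))]
  Ap <- Dp + dA * c(sin(phi), 0, -cos(phi))
  co <- rbind(c(20, 20, 75), Dp, Hp, Ap,
              cbind(c(40, 41, 42), 40, 70),
              cbind(c(60, 61, 62), 60, 30))
  membrane_system(atoms, array(co, c(10, 3, 1)), c(100, 100, 100),
                  species = simple_species(1))
}

test_that("donor/acceptor typing follows element and bonded-hydrogen rules", {
  # serine-like protein residue with OG-HG; DOPC-like beads have no O-H
  atoms <- data.frame(
    eleno = 1:9,
    name = c("CA", "OG", "HG", rep(c("P", "O11", "O12"), 2)),
    resname = c(rep("SER", 3), rep("DOPC", 6)),
    resid = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L))
  co <- rbind(c(10, 10, 90), c(11, 10, 90), c(11.95, 10, 90),
              cbind(c(30, 31, 32), 30, 70),
              cbind(c(50, 51, 52), 50, 30))
  sys <- membrane_system(atoms, array(co, c(9, 3, 1)), c(100, 100, 100),
                         species = simple_species(1))
  da <- find_donors_acceptors(sys)
  expect_equal(nrow(da$donors), 1)
  expect_equal(sys$atoms$name[da$donors$donor], "OG")
  expect_equal(sys$atoms$name[da$donors$hydrogen], "HG")
  # all N/O are acceptors; lipid O beads contribute none as donors
  expect_true(all(sys$atoms$element[da$acceptors] %in% c("N", "O")))
  expect_gt(sum(sys$atoms$segment[da$acceptors] == "lipid"), 0)
})

test_that("the pseudo-protein carries one donor pair per residue", {
  cfg <- test_config(n_frames = 1L)
  s <- build_bilayer(cfg)
  da <- find_donors_acceptors(s)
  prot_donors <- sum(s$atoms$segment[da$donors$donor] == "protein")
  expect_equal(prot_donors, cfg$protein_residues)
})

test_that("the geometric criterion accepts and rejects the textbook cases", {
  s1 <- hb_pair_system(3.0)
  r <- detect_hbonds(s1, 1)
  expect_equal(nrow(r), 1)
  expect_equal(r$distance, 3.0, tolerance = 1e-9)
  expect_equal(r$angle, 180, tolerance = 1e-6)
  expect_equal(r$donor_side, "protein")
  expect_equal(r$acceptor_species, "DOPC")
  expect_equal(nrow(detect_hbonds(hb_pair_system(3.3), 1)), 0)
  expect_equal(nrow(detect_hbonds(hb_pair_system(3.0, angle = 140), 1)), 0)
  # boundaries: just inside either cutoff still counts
  expect_equal(nrow(detect_hbonds(hb_pair_system(3.1999), 1)), 1)
  expect_equal(nrow(detect_hbonds(hb_pair_system(3.0, angle = 150.5), 1)), 1)
})

test_that("detection equals the brute-force oracle on random systems", {
  for (seed in 1:10) {
    sys <- random_hbond_system(seed)
    got <- detect_hbonds(sys, 1)
    oracle <- bf_hbonds(sys, 1)
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(got))
      expect_equal(unname(cbind(got$donor, got$acceptor)), unname(oracle))
  }
})

test_that("counts are invariant under rigid rotation plus translation", {
  # pick a random system that actually carries a few bonds
  sys <- NULL
  for (seed in 11:40) {
    cand <- random_hbond_system(seed)
    if (nrow(detect_hbonds(cand, 1)) > 0) { sys <- cand; break }
  }
  n0 <- nrow(detect_hbonds(sys, 1))
  expect_gt(n0, 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  ctr <- sys$box[1, ] / 2
  xyz <- sweep(sys$coords[, , 1], 2, ctr) %*% t(R)
  xyz <- sweep(xyz, 2, ctr + c(3, -2, 5), "+")
  for (k in 1:3) xyz[, k] <- xyz[, k] %% sys$box[1, k]
  sys2 <- sys
  sys2$coords <- array(xyz, dim(sys$coords))
  expect_equal(nrow(detect_hbonds(sys2, 1)), n0)
})

test_that("tightening either cutoff never increases the count", {
  for (seed in c(2, 5)) {
    sys <- random_hbond_system(seed, n_res = 30L, n_lip = 35L)
    n_loose <- nrow(detect_hbonds(sys, 1, d_cut = 3.6, angle_cut = 45))
    n_mid <- nrow(detect_hbonds(sys, 1, d_cut = 3.2, angle_cut = 45))
    expect_lte(n_mid, n_loose)
    expect_lte(nrow(detect_hbonds(sys, 1, d_cut = 2.8, angle_cut = 45)),
               n_mid)
    expect_lte(nrow(detect_hbonds(sys, 1, d_cut = 3.2, angle_cut = 20)),
               n_mid)
  }
})

test_that("species counting reports held bonds with zero block error", {
  cfg <- test_config(n_frames = 10L, D = 0, z_jitter = 0,
                     binding_frame = 2L, bias = c(PIP2 = 0))
  tr <- simulate_trajectory(build_bilayer(cfg), cfg)
  for (f in seq_len(10)) tr <- plant_hbond_geometry(tr, 3, frame = f)
  cnt <- count_hbonds_by_species(tr, 1:10)
  expect_equal(sum(cnt$mean), 3)
  expect_equal(sum(cnt$se), 0)
  expect_equal(sum(cnt$total), 30)
  # permutation symmetry of the window
  cnt2 <- count_hbonds_by_species(tr, sample(1:10))
  expect_equal(cnt2$mean, cnt$mean)
  # far-apart system counts zero
  cfg2 <- test_config(n_frames = 3L, binding_frame = 100L,
                      start_height = 60)
  tr2 <- simulate_trajectory(build_bilayer(cfg2), cfg2)
  expect_equal(sum(count_hbonds_by_species(tr2, 1:3)$mean), 0)
  # two-window comparison is plain bookkeeping
  cmp <- compare_hbond_windows(tr, 1:5, 6:10)
  expect_equal(cmp$delta, cmp$mean_final - cmp$mean_initial)
})
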