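# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no stored data.

# two-species config for tiny hand-built systems (counts 10:2 by default)
simple_species <- function(f1 = 10 / 12) {
  species_config(list(
    list(name = "DOPC", resnames = "DOPC", marker = "P",
         hydrophilic = c("O11", "O12"),
         hydrophobic = c("C21", "C22", "C31", "C32"),
         charge = 0L, molfrac = f1),
    list(name = "PIP2", resnames = "PI25", marker = "P",
         hydrophilic = c("O11", "O12"),
         hydrophobic = c("C21", "C22", "C31", "C32"),
         charge = -5L, molfrac = 1 - f1)))
}

# hand-built system: `lipids` is a data.frame with resname, x, y, z (marker
# position); optional protein_ca is a matrix of Calpha positions
make_flat_system <- function(lipids, protein_ca = NULL, box = c(100, 100, 100),
                             nframes = 1L, species = simple_species()) {
  rows <- list(); xyz <- list(); rid <- 0L
  if (!is.null(protein_ca)) {
    for (i in seq_len(nrow(protein_ca))) {
      rid <- rid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        eleno = NA, name = "CA", resname = "ALA", resid = rid)
      xyz[[length(xyz) + 1L]] <- protein_ca[i, , drop = FALSE]
    }
  }
  for (i in seq_len(nrow(lipids))) {
    rid <- rid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      eleno = NA, name = "P", resname = lipids$resname[i], resid = rid)
    xyz[[length(xyz) + 1L]] <-
      matrix(c(lipids$x[i], lipids$y[i], lipids$z[i]), 1)
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  co <- do.call(rbind, xyz)
  coords <- array(co, c(nrow(co), 3, nframes))
  membrane_system(atoms, coords, box, species = species)
}

# brute-force minimal-image distance over the 27 neighbor images
bf_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# brute-force hydrogen-bond oracle: full triple enumeration over
# protein<->lipid donor/acceptor pairs with the geometric criterion
bf_hbonds <- function(system, frame, d_cut = 3.2, angle_cut = 30) {
  da <- find_donors_acceptors(system)
  a <- system$atoms
  box <- system$box[frame, ]
  hits <- list()
  for (i in seq_len(nrow(da$donors))) {
    for (j in seq_along(da$acceptors)) {
      dn <- da$donors$donor[i]; hy <- da$donors$hydrogen[i]
      ac <- da$acceptors[j]
      if (a$segment[dn] == a$segment[ac]) next
      if (a$resuid[dn] == a$resuid[ac]) next
      d <- bf_min_image(system$coords[dn, , frame],
                        system$coords[ac, , frame], box)
      if (d > d_cut) next
      w1 <- system$coords[dn, , frame] - system$coords[hy, , frame]
      w1 <- w1 - box * round(w1 / box)
      w2 <- system$coords[ac, , frame] - system$coords[hy, , frame]
      w2 <- w2 - box * round(w2 / box)
      ang <- acos(max(-1, min(1, sum(w1 * w2) /
                                sqrt(sum(w1^2) * sum(w2^2))))) * 180 / pi
      if (180 - ang <= angle_cut)
        hits[[length(hits) + 1L]] <- c(dn, ac)
    }
  }
  if (!length(hits)) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, hits)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# random small protein+lipid system for oracle-equivalence tests
random_hbond_system <- function(seed, n_res = 20L, n_lip = 25L,
                                box = c(30, 30, 30)) {
  set.seed(seed)
  rows <- list(); xyz <- list()
  for (r in seq_len(n_res)) {
    p <- runif(3, 0, box)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rows[[length(rows) + 1L]] <- data.frame(
      eleno = NA, name = c("CA", "N", "HN", "O"), resname = "ALA",
      resid = r)
    xyz[[length(xyz) + 1L]] <- rbind(p, p + c(1.2, 0, 0),
                                     p + c(1.2, 0, 0) + u,
                                     p + c(-1.2, 0, 0))
  }
  for (l in seq_len(n_lip)) {
    p <- runif(3, 0, box)
    rows[[length(rows) + 1L]] <- data.frame(
      eleno = NA, name = c("P", "O11", "O12"), resname = "DOPC",
      resid = n_res + l)
    xyz[[length(xyz) + 1L]] <- rbind(p, p + runif(3, -2, 2),
                                     p + runif(3, -2, 2))
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  co <- do.call(rbind, xyz)
  membrane_system(atoms, array(co, c(nrow(co), 3, 1)), box,
                  species = simple_species(1))
}

# recursive flood-fill component labelling oracle (wrap-aware)
ff_label <- function(mask, connectivity = 8L) {
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  offs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[s] != 0L) next
      lab[s] <- cur
      i <- ((s - 1L) %% n) + 1L; j <- ((s - 1L) %/% n) + 1L
      for (o in offs) {
        ii <- ((i - 1L + o[1]) %% n) + 1L
        jj <- ((j - 1L + o[2]) %% p) + 1L
        t <- (jj - 1L) * n + ii
        if (mask[t] && lab[t] == 0L) stack <- c(stack, t)
      }
    }
  }
  lab
}

# canonical partition signature for comparing two labelings
partition_sig <- function(lab) {
  ids <- setdiff(unique(as.vector(lab)), 0L)
  sets <- lapply(ids, function(i) sort(which(lab == i)))
  sets[order(vapply(sets, `[`, 0L, 1L))]
}

# hand-made classified grid / mask constructors (defect fixtures)
make_surface_grid <- function(labels, box = c(nrow(labels), ncol(labels), 100),
                              frame = 1L, leaflet = "upper") {
  structure(list(labels = labels, bins_x = nrow(labels),
                 bins_y = ncol(labels),
                 cell_area = box[1] * box[2] / (nrow(labels) * ncol(labels)),
                 plane = 0, frame = frame, leaflet = leaflet, box = box),
            class = "surface_grid")
}

make_mask <- function(mask, box = c(nrow(mask), ncol(mask), 100)) {
  ca <- box[1] * box[2] / (nrow(mask) * ncol(mask))
  structure(list(mask = mask, bins_x = nrow(mask), bins_y = ncol(mask),
                 area = sum(mask) * ca, cell_area = ca, box_mean = box,
                 window = 1L),
            class = "protein_mask")
}

# shared small synthetic trajectory (built once per test run)
tiny_cfg <- function(...) test_config(n_frames = 60L, binding_frame = 20L, ...)

# uniform random (ideal-gas) target field with Calpha reference atoms
make_gas_system <- function(seed, n = 2000L, n_ref = 50L,
                            box = c(60, 60, 60)) {
  set.seed(seed)
  atoms <- data.frame(
    eleno = seq_len(n_ref + n),
    name = c(rep("CA", n_ref), rep("P", n)),
    resname = c(rep("ALA", n_ref), rep("DOPC", n)),
    resid = seq_len(n_ref + n))
  xyz <- cbind(runif(n_ref + n, 0, box[1]), runif(n_ref + n, 0, box[2]),
               runif(n_ref + n, 0, box[3]))
  membrane_system(atoms, array(xyz, c(n_ref + n, 3, 1)), box,
                  species = simple_species(1))
}
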