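#' Configuration for the synthetic bilayer-trajectory generator
#'
#' The generator emulates the study conditions of a bound peripheral protein
#' on a five-species plasma-membrane model: a two-leaflet bilayer at
#' DOPC:Chol:DOPE:PIP:PIP2 = 40:32:20:4:4 mol%, 600 lipids per leaflet in a
#' ~173 A lateral box (the full-scale defaults), lateral Brownian lipid
#' diffusion, a rigid pseudo-protein that descends onto the upper leaflet,
#' and species-specific kinematic recruitment toward the protein axis.
#' Lipids are coarse bead clusters: a phospholipid is one marker (P) + two
#' hydrophilic headgroup beads + four hydrophobic tail beads, cholesterol is
#' one hydroxyl-oxygen marker (O3) + three hydrophobic beads. Bead roles and
#' coordinates are all the downstream analyses consume.
#'
#' @param lipids_per_leaflet lipid count per leaflet (default 600). Must
#'   factor into a near-square lattice.
#' @param box box lengths (A), default `c(173, 173, 100)`.
#' @param species a [species_config()] supplying mole fractions.
#' @param jitter lattice jitter half-width (A).
#' @param leaflet_offset marker-plane distance from bilayer midplane (A).
#' @param D lateral diffusion coefficient (A^2/ns).
#' @param dt frame interval (ns).
#' @param n_frames number of frames in the trajectory.
#' @param z_jitter s.d. of per-frame, non-cumulative z noise (A).
#' @param protein_radius pseudo-protein disk radius (A).
#' @param protein_residues number of pseudo-residues (each contributes one
#'   Calpha, one donor N with bonded HN, and one acceptor O bead).
#' @param start_height,bound_height Calpha plane height above the upper
#'   marker plane at frame 1 and after binding (A).
#' @param binding_frame frame at which the protein reaches its bound height.
#' @param bias named per-species drift speed toward the protein axis (A/ns),
#'   active after `binding_frame` inside `capture_radius`.
#' @param capture_radius lateral radius of the recruitment zone (A).
#' @param seed integer random seed; fixed seed gives bit-identical output.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(lipids_per_leaflet = 600L,
                             box = c(173, 173, 100),
                             species = default_species(),
                             jitter = 0.5,
                             leaflet_offset = 19,
                             D = 1.0,
                             dt = 1.0,
                             n_frames = 100L,
                             z_jitter = 0.2,
                             protein_radius = 15,
                             protein_residues = 30L,
                             start_height = 40,
                             bound_height = 3,
                             binding_frame = 50L,
                             bias = c(PIP2 = 0.5),
                             capture_radius = 30,
                             seed = 1L) {
  box <- as.numeric(unlist(box))          # tolerate YAML list input
  if (is.list(bias)) bias <- unlist(bias)
  cfg <- list(lipids_per_leaflet = as.integer(lipids_per_leaflet), box = box,
              species = species, jitter = jitter,
              leaflet_offset = leaflet_offset, D = D, dt = dt,
              n_frames = as.integer(n_frames), z_jitter = z_jitter,
              protein_radius = protein_radius,
              protein_residues = as.integer(protein_residues),
              start_height = start_height, bound_height = bound_height,
              binding_frame = as.integer(binding_frame), bias = bias,
              capture_radius = capture_radius, seed = as.integer(seed))
  stopifnot(cfg$lipids_per_leaflet > 0L, all(box > 0), D >= 0, dt > 0,
            cfg$n_frames >= 1L, z_jitter >= 0, protein_radius > 0,
            cfg$protein_residues >= 1L, capture_radius > 0)
  mf <- vapply(species, function(s) s$molfrac, 0)
  if (abs(sum(mf) - 1) > 1e-9) stop("mole fractions must sum to 1")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Test-scale synthetic configuration
#'
#' Same generator, smaller system: 64 lipids per leaflet in a ~57 A box.
#' Used throughout the test suite to keep run times short while preserving
#' every geometric property of the full-scale configuration.
#'
#' @param ... overrides passed to [synthetic_config()].
#' @export
test_config <- function(...) {
  args <- list(lipids_per_leaflet = 64L, box = c(56.6, 56.6, 100),
               protein_radius = 12, protein_residues = 16L,
               n_frames = 100L, binding_frame = 30L, capture_radius = 25)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# largest-remainder apportionment of n among fractions (ties broken by order)
largest_remainder <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  rem <- raw - base
  k <- n - sum(base)
  if (k > 0) {
    o <- order(-rem, seq_along(rem))
    base[o[seq_len(k)]] <- base[o[seq_len(k)]] + 1
  }
  as.integer(base)
}

# near-square factor pair of n (nx <= ny, nx * ny == n)
lattice_dims <- function(n) {
  nx <- floor(sqrt(n))
  while (nx >= 1L && n %% nx != 0L) nx <- nx - 1L
  ny <- n %/% nx
  if (ny > 3L * nx)
    stop("lipids_per_leaflet = ", n,
         " does not factor into a near-square lattice; choose a composite ",
         "count (e.g. 64, 600)")
  c(nx, ny)
}

# bead templates: per-species offsets (dx, dy, dz relative to the lipid site
# at the marker plane; dz is multiplied by the leaflet sign so tails always
# point toward the bilayer core), names, roles, effective radii
.bead_template <- function(sp) {
  if (length(sp$hydrophilic) >= 2L) {
    data.frame(
      name = c(sp$marker, sp$hydrophilic[1:2], sp$hydrophobic[1:4]),
      dx = c(0, 2.0, -2.0, 1.5, -1.5, 1.5, -1.5),
      dy = c(0, 2.0, -2.0, 1.5, 1.5, -1.5, -1.5),
      dz = c(0, 1.5, 1.5, -4, -7.5, -11, -14.5),
      role = c("marker", "hydrophilic", "hydrophilic", rep("hydrophobic", 4)),
      vdw = c(4.5, 4.5, 4.5, 2.5, 2.5, 2.5, 2.5))
  } else {
    data.frame(
      name = c(sp$marker, sp$hydrophobic[1:3]),
      dx = c(0, 1.2, 0, -1.2),
      dy = c(0, 0, 1.2, 0),
      dz = c(-1.0, -6, -10, -14),
      role = c("marker", rep("hydrophobic", 3)),
      vdw = c(6.0, 2.5, 2.5, 2.5))
  }
}

#' Build a single-frame synthetic bilayer with a pseudo-protein
#'
#' Lipids are placed on a jittered rectangular lattice per leaflet; species
#' counts follow largest-remainder rounding of `n x mole fraction`, so the
#' per-species counts are exact, reproducible test targets. The
#' pseudo-protein is a rigid disk of residues (sunflower layout), each with
#' one Calpha, one donor N with a bonded HN hydrogen, and one acceptor O
#' bead, positioned `start_height` above the upper marker plane.
#'
#' @param config a [synthetic_config()].
#' @return a single-frame [membrane_system()] carrying a `ground_truth`
#'   attribute (per-leaflet species counts and leaflet labels).
#' @export
build_bilayer <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$lipids_per_leaflet
  mf <- vapply(config$species, function(s) s$molfrac, 0)
  counts <- largest_remainder(n, mf)
  names(counts) <- names(config$species)
  if (any(mf > 0 & counts == 0))
    stop("composition infeasible at ", n, " lipids per leaflet: species ",
         paste(names(counts)[mf > 0 & counts == 0], collapse = ","),
         " would have zero lipids")
  dims <- lattice_dims(n)
  sx <- config$box[1] / dims[1]
  sy <- config$box[2] / dims[2]
  mid <- config$box[3] / 2
  grid <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]))

  nres <- config$protein_residues
  rows <- list(); coords <- list()
  # pseudo-protein (resids 1..nres), sunflower disk, start height above plane
  golden <- pi * (3 - sqrt(5))
  rr <- config$protein_radius * sqrt((seq_len(nres) - 0.5) / nres)
  th <- seq_len(nres) * golden
  cx <- config$box[1] / 2; cy <- config$box[2] / 2
  zp <- mid + config$leaflet_offset + config$start_height
  px <- cx + rr * cos(th); py <- cy + rr * sin(th)
  rows[[1]] <- data.frame(
    name = rep(c("CA", "N", "HN", "O"), nres),
    resname = "ALA",
    resid = rep(seq_len(nres), each = 4L),
    vdw = rep(c(4.0, 4.0, 1.2, 4.0), nres))
  coords[[1]] <- cbind(
    as.vector(rbind(px, px + 0.8, px + 0.8, px - 0.8)),
    as.vector(rbind(py, py, py, py)),
    rep(c(zp, zp + 1.2, zp + 0.2, zp + 1.0), nres))

  resid0 <- nres
  truth_leaflet <- character(0)
  for (leaf in c("upper", "lower")) {
    s <- if (leaf == "upper") 1 else -1
    zm <- mid + s * config$leaflet_offset
    lab <- sample(rep(names(counts), counts))
    x0 <- (grid$i - 0.5) * sx + stats::runif(n, -config$jitter, config$jitter)
    y0 <- (grid$j - 0.5) * sy + stats::runif(n, -config$jitter, config$jitter)
    for (k in seq_len(n)) {
      sp <- config$species[[lab[k]]]
      tmpl <- .bead_template(sp)
      resid0 <- resid0 + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        name = tmpl$name, resname = sp$resnames[1],
        resid = resid0, vdw = tmpl$vdw)
      coords[[length(coords) + 1L]] <- cbind(
        wrap_coords(x0[k] + tmpl$dx, config$box[1]),
        wrap_coords(y0[k] + tmpl$dy, config$box[2]),
        zm + s * tmpl$dz)
      truth_leaflet <- c(truth_leaflet, leaf)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  xyz <- do.call(rbind, coords)

  pres <- seq_len(nres)
  thirds <- floor(nres / 3)
  domains <- data.frame(label = c("4HB", "brace", "PsK"),
                        start = c(1L, thirds + 1L, 2L * thirds + 1L),
                        end = c(thirds, 2L * thirds, nres))
  sys <- membrane_system(atoms, array(xyz, c(nrow(atoms), 3, 1)),
                         box = config$box, time = 0,
                         species = config$species, domains = domains)
  attr(sys, "ground_truth") <- list(
    leaflet_counts = list(upper = as.list(counts), lower = as.list(counts)),
    lipid_leaflet = truth_leaflet,
    config_seed = config$seed)
  attr(sys, "config") <- config
  sys
}

#' Propagate a synthetic system through time
#'
#' Lipids take independent 2D Brownian steps (variance `2 D dt` per axis,
#' periodic wrapping) with small non-cumulative z noise; the protein descends
#' linearly from its start height to its bound height at `binding_frame` and
#' is static afterwards. After binding, species with a nonzero recruitment
#' bias drift toward the protein axis at the configured speed while inside
#' the capture radius (never closer than 5 A). Recruitment is kinematic, not
#' energetic: the resulting enrichment is controlled ground truth.
#'
#' @param initial a single-frame system from [build_bilayer()].
#' @param config the [synthetic_config()] used to build it.
#' @return a multi-frame [membrane_system()]; the `ground_truth` attribute
#'   gains the binding leaflet, the geometric first-contact frame, and the
#'   steady-state per-species enrichment in the recruitment region computed
#'   from the generator's own coordinates over the final 10% of frames.
#' @export
simulate_trajectory <- function(initial, config) {
  stopifnot(inherits(initial, "membrane_system"), n_frames(initial) == 1L)
  set.seed(config$seed + 1L)
  nf <- config$n_frames
  na <- n_atoms(initial)
  a <- initial$atoms
  box <- config$box
  coords <- array(NA_real_, c(na, 3, nf))
  coords[, , 1] <- initial$coords[, , 1]

  lip_res <- unique(a$resuid[a$segment == "lipid"])
  lip_atoms <- lapply(lip_res, function(r) which(a$resuid == r))
  lip_species <- vapply(lip_res, function(r)
    a$species[a$resuid == r][1], "")
  mk_idx <- vapply(lip_res, function(r)
    which(a$resuid == r & a$role == "marker")[1], 0L)
  base_z <- lapply(lip_atoms, function(i) coords[i, 3, 1])
  prot <- which(a$segment == "protein")
  upper <- coords[mk_idx, 3, 1] > box[3] / 2
  cxy <- c(box[1] / 2, box[2] / 2)

  sd_step <- sqrt(2 * config$D * config$dt)
  descent <- (config$start_height - config$bound_height) /
    max(config$binding_frame - 1L, 1L)
  biasv <- config$bias
  nl <- length(lip_res)

  for (f in 2:nf) {
    prev <- coords[, , f - 1L]
    cur <- prev
    dx <- stats::rnorm(nl, 0, sd_step)
    dy <- stats::rnorm(nl, 0, sd_step)
    dz <- stats::rnorm(nl, 0, config$z_jitter)
    for (k in seq_len(nl)) {
      i <- lip_atoms[[k]]
      cur[i, 1] <- prev[i, 1] + dx[k]
      cur[i, 2] <- prev[i, 2] + dy[k]
      cur[i, 3] <- base_z[[k]] + dz[k]
    }
    # recruitment drift toward the protein axis (binding leaflet only)
    if (f > config$binding_frame && length(biasv)) {
      for (spn in names(biasv)) {
        if (biasv[[spn]] <= 0) next
        sel <- which(lip_species == spn & upper)
        if (!length(sel)) next
        mx <- cur[mk_idx[sel], 1]; my <- cur[mk_idx[sel], 2]
        ddx <- mx - cxy[1]; ddx <- ddx - box[1] * round(ddx / box[1])
        ddy <- my - cxy[2]; ddy <- ddy - box[2] * round(ddy / box[2])
        rho <- sqrt(ddx^2 + ddy^2)
        inz <- which(rho <= config$capture_radius & rho > 5)
        for (q in inz) {
          k <- sel[q]
          step <- min(biasv[[spn]] * config$dt, rho[q] - 5)
          ux <- ddx[q] / rho[q]; uy <- ddy[q] / rho[q]
          i <- lip_atoms[[k]]
          cur[i, 1] <- cur[i, 1] - step * ux
          cur[i, 2] <- cur[i, 2] - step * uy
        }
      }
    }
    for (k in 1:2) {
      li <- unlist(lip_atoms)
      cur[li, k] <- wrap_coords(cur[li, k], box[k])
    }
    # protein descent, then static
    if (f <= config$binding_frame) {
      cur[prot, ] <- coords[prot, , 1]
      cur[prot, 3] <- cur[prot, 3] - descent * (f - 1L)
    } else {
      cur[prot, ] <- coords[prot, , f - 1L]
    }
    coords[, , f] <- cur
  }

  sys <- membrane_system(a, coords, matrix(box, nf, 3, byrow = TRUE),
                         time = (seq_len(nf) - 1) * config$dt,
                         species = initial$species, domains = initial$domains)
  gt <- attr(initial, "ground_truth")
  gt$binding_leaflet <- "upper"
  gt$binding_frame_config <- config$binding_frame

  # geometric first contact: protein Calpha within 12 A of any marker
  ca <- prot[a$name[prot] == "CA"]
  fc <- NA_integer_
  for (f in seq_len(nf)) {
    D <- mi_cross_dist(coords[ca, , f, drop = FALSE][, , 1],
                       coords[mk_idx, , f, drop = FALSE][, , 1], box)
    if (min(D) <= 12) { fc <- f; break }
  }
  gt$first_contact_frame <- fc

  # steady-state enrichment over the final 10% of frames, in the 15 A
  # analysis region about the protein axis, from generator coordinates
  tail_frames <- seq.int(max(1L, floor(0.9 * nf)), nf)
  spn <- names(config$species)
  reg <- matrix(0, length(tail_frames), length(spn),
                dimnames = list(NULL, spn))
  for (ti in seq_along(tail_frames)) {
    f <- tail_frames[ti]
    mx <- coords[mk_idx[upper], 1, f]; my <- coords[mk_idx[upper], 2, f]
    ddx <- mx - cxy[1]; ddx <- ddx - box[1] * round(ddx / box[1])
    ddy <- my - cxy[2]; ddy <- ddy - box[2] * round(ddy / box[2])
    inside <- sqrt(ddx^2 + ddy^2) <= 15
    tab <- table(factor(lip_species[upper][inside], levels = spn))
    reg[ti, ] <- as.integer(tab)
  }
  bulk <- table(factor(lip_species[upper], levels = spn))
  bulk_frac <- as.numeric(bulk) / sum(bulk)
  mean_reg <- colMeans(reg)
  reg_frac <- mean_reg / sum(mean_reg)
  gt$region_radius <- 15
  gt$enrichment <- stats::setNames(as.list(reg_frac / bulk_frac), spn)
  attr(sys, "ground_truth") <- gt
  attr(sys, "config") <- config
  sys
}

#' Plant exact hydrogen-bond geometries
#'
#' Repositions `n` distinct lipid headgroup acceptor beads so that exactly
#' `n` protein-donor/lipid-acceptor pairs satisfy a donor-acceptor distance
#' of 2.9 A with a D-H...A angle of `angle` degrees (default 180, ideal
#' linear geometry), and no other protein-lipid donor-acceptor pair comes
#' within 3.4 A. With `angle = 120` the planted pairs fail the 30-degree
#' linearity criterion, giving a negative control.
#'
#' @param system a [membrane_system()] with a pseudo-protein carrying N/HN
#'   donor beads (see [build_bilayer()]).
#' @param n number of bonds to plant (`0` allowed).
#' @param frame frame to modify (default: last).
#' @param angle planted D-H...A angle in degrees.
#' @return the modified system; `ground_truth$planted_hbonds` records the
#'   (donor, hydrogen, acceptor) atom indices.
#' @export
plant_hbond_geometry <- function(system, n, frame = n_frames(system),
                                 angle = 180) {
  a <- system$atoms
  box <- system$box[frame, ]
  dn <- which(a$segment == "protein" & a$name == "N")
  hn <- which(a$segment == "protein" & a$name == "HN")
  if (n > length(dn)) stop("n = ", n, " exceeds available donor pairs (",
                           length(dn), ")")
  la <- assign_leaflets(system, frame)
  upper_res <- as.integer(names(la$leaflet)[la$leaflet == "upper"])
  acc_pool <- which(a$segment == "lipid" & a$element == "O" &
                      a$role == "hydrophilic" & a$resuid %in% upper_res)
  if (n > length(unique(a$resuid[acc_pool])))
    stop("n exceeds available lipid acceptor beads")
  planted <- NULL
  if (n > 0L) {
    dsel <- dn[seq_len(n)]; hsel <- hn[seq_len(n)]
    # one acceptor bead per lipid, lipids nearest the protein axis first
    pool <- a[acc_pool, ]
    first_per_res <- acc_pool[!duplicated(pool$resuid)]
    cx <- mean(system$coords[dn, 1, frame])
    cy <- mean(system$coords[dn, 2, frame])
    ddx <- system$coords[first_per_res, 1, frame] - cx
    ddx <- ddx - box[1] * round(ddx / box[1])
    ddy <- system$coords[first_per_res, 2, frame] - cy
    ddy <- ddy - box[2] * round(ddy / box[2])
    asel <- first_per_res[order(ddx^2 + ddy^2)][seq_len(n)]
    for (i in seq_len(n)) {
      Dp <- system$coords[dsel[i], , frame]
      Hp <- system$coords[hsel[i], , frame]
      u <- (Hp - Dp) / sqrt(sum((Hp - Dp)^2))
      v <- c(u[3], 0, -u[1]); v <- v / sqrt(sum(v^2))  # any perpendicular
      if (abs(angle - 180) < 1e-9) {
        A <- Dp + 2.9 * u
      } else {
        # choose in-plane direction phi so the D-H...A angle hits `angle`
        phis <- seq(0, pi, by = 0.0005)
        ang_of <- function(phi) {
          A <- Dp + 2.9 * (cos(phi) * u + sin(phi) * v)
          w1 <- Dp - Hp; w2 <- A - Hp
          acos(sum(w1 * w2) / sqrt(sum(w1^2) * sum(w2^2))) * 180 / pi
        }
        phi <- phis[which.min(abs(vapply(phis, ang_of, 0) - angle))]
        A <- Dp + 2.9 * (cos(phi) * u + sin(phi) * v)
      }
      system$coords[asel[i], , frame] <- A
    }
    planted <- data.frame(donor = dsel, hydrogen = hsel, acceptor = asel)
  }
  # clear incidental near-contacts: push every non-planted lipid acceptor
  # bead that sits within 3.4 A of any protein donor down into the core
  others <- setdiff(acc_pool, planted$acceptor)
  for (iter in 1:10) {
    if (!length(others)) break
    Dm <- mi_cross_dist(system$coords[dn, , frame, drop = FALSE][, , 1],
                        system$coords[others, , frame, drop = FALSE][, , 1],
                        box)
    bad <- others[apply(Dm, 2, min) <= 3.4]
    if (!length(bad)) break
    system$coords[bad, 3, frame] <- system$coords[bad, 3, frame] - 8
  }
  gt <- attr(system, "ground_truth")
  gt$planted_hbonds <- planted
  gt$planted_hbond_frame <- frame
  gt$planted_hbond_n <- if (abs(angle - 180) < 1e-9) n else 0L
  attr(system, "ground_truth") <- gt
  system
}

#' Plant a hydrophobic-exposure patch
#'
#' Creates a circular packing defect of known geometry in one leaflet of one
#' frame: every headgroup bead (marker or hydrophilic) whose disk would
#' intersect the patch is displaced radially so its disk sits just outside
#' the patch boundary, and the acyl-tail beads of lipids whose marker was
#' inside the patch are raised to the marker plane. The disk of radius
#' `radius` then exposes only hydrophobic beads (or bare bilayer interior),
#' so the downstream defect detector should recover one component of area
#' `pi * radius^2`. Patches may cross the periodic boundary.
#'
#' @param system a [membrane_system()].
#' @param frame frame to modify.
#' @param center length-2 xy center (A).
#' @param radius patch radius (A), must be positive.
#' @param leaflet `"upper"` or `"lower"`.
#' @return the modified system; `ground_truth$planted_patches` accumulates
#'   the patch geometry.
#' @export
plant_defect_patch <- function(system, frame, center, radius,
                               leaflet = "upper") {
  if (radius <= 0) stop("patch radius must be positive")
  box <- system$box[frame, ]
  if (radius * 2 > min(box[1:2])) stop("patch does not fit inside the box")
  a <- system$atoms
  la <- assign_leaflets(system, frame)
  res <- as.integer(names(la$leaflet)[la$leaflet == leaflet])
  head_idx <- which(a$resuid %in% res & a$role %in% c("marker", "hydrophilic"))
  mk <- which(a$resuid %in% res & a$role == "marker")
  plane_z <- mean(system$coords[mk, 3, frame])

  x <- system$coords[head_idx, 1, frame]
  y <- system$coords[head_idx, 2, frame]
  ddx <- x - center[1]; ddx <- ddx - box[1] * round(ddx / box[1])
  ddy <- y - center[2]; ddy <- ddy - box[2] * round(ddy / box[2])
  rho <- sqrt(ddx^2 + ddy^2)
  rb <- a$vdw[head_idx]
  hit <- which(rho < radius + rb)
  inside_res <- unique(a$resuid[head_idx][rho < radius & a$role[head_idx] ==
                                            "marker"])
  if (length(hit)) {
    # Rearrange the displaced beads uniformly on a rim circle at distance d
    # from the patch center. Their disks scallop the patch boundary, so d is
    # solved numerically such that the area they leave uncovered equals the
    # nominal patch area pi * radius^2.
    radii <- rb[hit]
    K <- length(hit)
    theta <- 2 * pi * (seq_len(K) - 0.5) / K
    uncovered_area <- function(d) {
      h <- 0.2
      gx <- seq(-d, d, by = h)
      pts <- expand.grid(px = gx, py = gx)
      pts <- pts[pts$px^2 + pts$py^2 <= d^2, ]
      bx <- d * cos(theta); by <- d * sin(theta)
      cov <- rep(FALSE, nrow(pts))
      for (k in seq_len(K))
        cov <- cov | ((pts$px - bx[k])^2 + (pts$py - by[k])^2 <= radii[k]^2)
      sum(!cov) * h^2
    }
    target <- pi * radius^2
    lo <- max(0.5, radius - max(radii))
    hi <- radius + max(radii)
    tries <- 0L
    while (uncovered_area(hi) < target && tries < 4L) {
      hi <- hi + 2; tries <- tries + 1L
    }
    d <- stats::uniroot(function(d) uncovered_area(d) - target,
                        lower = lo, upper = hi, tol = 0.01)$root
    for (q in seq_len(K)) {
      i <- head_idx[hit[q]]
      system$coords[i, 1, frame] <-
        wrap_coords(center[1] + d * cos(theta[q]), box[1])
      system$coords[i, 2, frame] <-
        wrap_coords(center[2] + d * sin(theta[q]), box[2])
    }
  }
  # raise tails into the exposed disk, just below the headgroup beads so
  # they never occlude a headgroup laterally overhanging the rim
  tails <- which(a$resuid %in% inside_res & a$role == "hydrophobic")
  sgn <- if (leaflet == "upper") 1 else -1
  if (length(tails)) system$coords[tails, 3, frame] <- plane_z - 2 * sgn

  gt <- attr(system, "ground_truth")
  gt$planted_patches <- rbind(
    gt$planted_patches,
    data.frame(frame = frame, x = center[1], y = center[2], radius = radius,
               leaflet = leaflet, area = pi * radius^2))
  attr(system, "ground_truth") <- gt
  system
}
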