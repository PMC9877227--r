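#' Protein-membrane trajectory container
#'
#' A `membrane_system` bundles a topology (atom table), per-frame Cartesian
#' coordinates in Angstrom, per-frame orthorhombic box lengths, time stamps
#' in nanoseconds, a [species_config()] registry, and a protein domain table.
#'
#' @param atoms data.frame with columns `eleno`, `name`, `resname`, `resid`,
#'   `segment` (one of protein/lipid/solvent/ion), `element`; optional
#'   `species`, `role`, `vdw` columns are filled in from `species`.
#' @param coords numeric array `natoms x 3 x nframes` (Angstrom).
#' @param box numeric matrix `nframes x 3` of box lengths (Angstrom).
#' @param time numeric vector of frame time stamps (ns).
#' @param species a [species_config()].
#' @param domains data.frame with columns `label`, `start`, `end` giving
#'   non-overlapping protein residue-id ranges (see [mlkl_domains()]).
#' @return object of class `membrane_system`.
#' @export
membrane_system <- function(atoms, coords, box, time = NULL,
                            species = default_species(), domains = NULL) {
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n <- nrow(atoms)
  if (dim(coords)[1] != n)
    stop("atom count mismatch: topology has ", n, " atoms, coordinates have ",
         dim(coords)[1])
  nf <- dim(coords)[3]
  if (is.vector(box)) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) == 1L && nf > 1L) box <- box[rep(1L, nf), , drop = FALSE]
  if (nrow(box) != nf) stop("box must have one row per frame")
  if (any(box <= 0)) stop("box lengths must be strictly positive")
  if (is.null(time)) time <- seq_len(nf) - 1
  if (length(time) != nf) stop("time must have one stamp per frame")

  # unique residue key (contiguous runs of identical resid+resname)
  key <- paste(atoms$resid, atoms$resname)
  atoms$resuid <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))

  if (is.null(atoms$element)) atoms$element <- infer_element(atoms$name)
  if (is.null(atoms$segment)) atoms$segment <- classify_segment(atoms)

  sp_of <- species_of_resname(species, atoms$resname)
  lip <- atoms$segment == "lipid"
  unknown <- lip & is.na(sp_of)
  if (any(unknown))
    stop("unclassifiable lipid residue name(s): ",
         paste(unique(atoms$resname[unknown]), collapse = ", "))
  atoms$species <- ifelse(lip, sp_of, NA_character_)
  if (is.null(atoms$role)) atoms$role <- NA_character_
  for (s in species) {
    sel <- which(lip & atoms$species == s$name & is.na(atoms$role))
    if (length(sel)) atoms$role[sel] <- role_of_atom(s, atoms$name[sel])
  }
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_radius(atoms$element)
  atoms$vdw[is.na(atoms$vdw)] <- vdw_radius(atoms$element[is.na(atoms$vdw)])

  if (is.null(domains)) {
    pres <- sort(unique(atoms$resid[atoms$segment == "protein"]))
    domains <- if (length(pres))
      data.frame(label = "protein", start = min(pres), end = max(pres))
    else data.frame(label = character(), start = integer(), end = integer())
  }
  if (nrow(domains) > 1L) {
    o <- order(domains$start)
    d <- domains[o, ]
    if (any(d$start[-1L] <= d$end[-nrow(d)]))
      stop("domain residue ranges overlap")
  }

  structure(list(atoms = atoms, coords = coords, box = box,
                 time = as.numeric(time), species = species,
                 domains = domains),
            class = "membrane_system")
}

# segment from residue name: protein / lipid / solvent / ion
classify_segment <- function(atoms) {
  rn <- toupper(atoms$resname)
  seg <- rep("lipid", nrow(atoms))
  seg[rn %in% .aa3] <- "protein"
  seg[rn %in% .water_resnames] <- "solvent"
  seg[rn %in% .ion_resnames] <- "ion"
  seg
}

#' @export
print.membrane_system <- function(x, ...) {
  a <- x$atoms
  cat("membrane_system: ", nrow(a), " atoms, ", n_frames(x), " frame(s)\n",
      sep = "")
  cat("  box (frame 1): ", paste(sprintf("%.1f", x$box[1, ]), collapse = " x "),
      " A\n", sep = "")
  cat("  protein residues: ", length(unique(a$resid[a$segment == "protein"])),
      "; lipid residues: ", length(unique(a$resuid[a$segment == "lipid"])),
      "\n", sep = "")
  tab <- table(a$species[a$role == "marker"])
  if (length(tab))
    cat("  lipids by species: ",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Number of frames / atoms in a system
#' @param system a [membrane_system()].
#' @export
n_frames <- function(system) dim(system$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(system) dim(system$coords)[1]

#' MLKL domain table
#'
#' The three-domain architecture of the MLKL pseudokinase: the four-helical
#' bundle (4HB) residues 1-121, the brace helices 133-175, and the
#' pseudo-kinase domain (PsK) 193-459. Residues falling in the gaps
#' (122-132, 176-192) are treated as linker and excluded from per-domain
#' metrics.
#'
#' @return data.frame with columns `label`, `start`, `end`.
#' @export
mlkl_domains <- function() {
  data.frame(label = c("4HB", "brace", "PsK"),
             start = c(1L, 133L, 193L),
             end = c(121L, 175L, 459L))
}

# domain label for protein residue ids; "linker" when between defined ranges,
# "none" when outside all ranges entirely
domain_of <- function(system, resid) {
  d <- system$domains
  out <- rep("none", length(resid))
  if (!nrow(d)) return(out)
  inside <- resid >= min(d$start) & resid <= max(d$end)
  out[inside] <- "linker"
  for (i in seq_len(nrow(d)))
    out[resid >= d$start[i] & resid <= d$end[i]] <- d$label[i]
  out
}

#' Minimal-image distance under periodic boundaries
#'
#' Distance between points under orthorhombic periodic boundary conditions:
#' the minimum over all periodic images.
#'
#' @param a,b numeric length-3 vectors, or `n x 3` matrices of paired points.
#' @param box positive length-3 box lengths (Angstrom).
#' @return numeric distance(s) in Angstrom.
#' @export
minimal_image_distance <- function(a, b, box) {
  if (any(box <= 0)) stop("box lengths must be strictly positive")
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- a - b
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  sqrt(rowSums(d * d))
}

# all-pairs minimal-image distance matrix between point sets A (n x 3) and
# B (m x 3); returns n x m
mi_cross_dist <- function(A, B, box) {
  if (is.null(dim(A))) A <- matrix(A, ncol = 3)
  if (is.null(dim(B))) B <- matrix(B, ncol = 3)
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# marker-atom table for one frame: data.frame resuid, resid, species,
# x, y, z (optionally restricted to a leaflet label via `leaflets`)
marker_table <- function(system, frame) {
  a <- system$atoms
  i <- which(a$role == "marker")
  xyz <- system$coords[i, , frame, drop = FALSE]
  data.frame(idx = i, resuid = a$resuid[i], resid = a$resid[i],
             species = a$species[i],
             x = xyz[, 1, 1], y = xyz[, 2, 1], z = xyz[, 3, 1])
}

#' Assign lipids to leaflets
#'
#' Each lipid is assigned to the upper or lower leaflet by comparing its
#' headgroup marker atom's z coordinate to the instantaneous midplane (the
#' mean z of all marker atoms in that frame). Markers exactly at the midplane
#' go to the upper leaflet.
#'
#' @param system a [membrane_system()].
#' @param frame frame index (1-based).
#' @return a list of class `leaflet_assignment` with `frame`, `midplane`,
#'   and `leaflet`, a character vector (`"upper"`/`"lower"`) named by lipid
#'   residue uid.
#' @export
assign_leaflets <- function(system, frame = 1L) {
  mk <- marker_table(system, frame)
  if (nrow(mk) == 0L) stop("no lipids in system")
  mid <- mean(mk$z)
  lab <- ifelse(mk$z >= mid, "upper", "lower")
  if (length(unique(lab)) == 1L && nrow(mk) > 1L)
    warning("all lipid markers on one side of the midplane; ",
            "degenerate leaflet assignment")
  structure(list(frame = frame, midplane = mid,
                 leaflet = stats::setNames(lab, mk$resuid)),
            class = "leaflet_assignment")
}

# index of marker atoms belonging to a leaflet at `frame`
leaflet_marker_idx <- function(system, frame, leaflet) {
  la <- assign_leaflets(system, frame)
  mk <- marker_table(system, frame)
  mk$idx[la$leaflet[as.character(mk$resuid)] == leaflet]
}

# Calpha atom indices (synthetic pseudo-proteins use atom name "CA" too)
ca_idx <- function(system) {
  with(system$atoms, which(segment == "protein" & name == "CA"))
}

# protein heavy atoms (non-hydrogen)
protein_heavy_idx <- function(system) {
  with(system$atoms, which(segment == "protein" & element != "H"))
}

#' Detect the binding leaflet and first-contact frame
#'
#' Scans a frame window for the earliest frame at which any protein Calpha
#' lies within `cutoff` (default 12 A, inclusive) of any lipid headgroup
#' marker atom, by minimal-image distance. The binding leaflet is the leaflet
#' of the majority of marker atoms within the cutoff at that frame.
#'
#' @param system a [membrane_system()].
#' @param window integer frame indices to scan (default: all frames).
#' @param cutoff contact cutoff in Angstrom.
#' @return list with `leaflet` (`"upper"`, `"lower"`, or `NA` if the protein
#'   never makes contact) and `frame` (first-contact frame index or `NA`).
#' @export
detect_binding_leaflet <- function(system, window = seq_len(n_frames(system)),
                                   cutoff = 12) {
  if (length(window) == 0L) stop("empty frame window")
  ca <- ca_idx(system)
  if (length(ca) == 0L) stop("no protein Calpha atoms in system")
  for (f in window) {
    mk <- marker_table(system, f)
    D <- mi_cross_dist(system$coords[ca, , f, drop = FALSE][, , 1],
                       as.matrix(mk[, c("x", "y", "z")]), system$box[f, ])
    hit <- which(apply(D, 2, min) <= cutoff)
    if (length(hit)) {
      la <- assign_leaflets(system, f)
      labs <- la$leaflet[as.character(mk$resuid[hit])]
      lab <- names(which.max(table(labs)))
      return(list(leaflet = lab, frame = f))
    }
  }
  list(leaflet = NA_character_, frame = NA_integer_)
}

#' Convert a time interval to a frame-index window
#'
#' @param system a [membrane_system()].
#' @param from,to time bounds in ns (inclusive).
#' @return integer vector of frame indices.
#' @export
frames_between <- function(system, from = -Inf, to = Inf) {
  which(system$time >= from & system$time <= to)
}
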