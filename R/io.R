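#' Load a protein-membrane system from standard MD files
#'
#' Reads a structure (PDB or GRO) and optionally a trajectory (DCD or
#' multi-model PDB) and classifies every residue as protein, lipid, solvent
#' or ion using the species configuration. GRO coordinates (nm) are converted
#' to Angstrom on load. Boxes must be orthorhombic; triclinic input is
#' rejected. XTC is not a supported input format; convert to DCD first.
#'
#' @param structure_path path to a `.pdb` or `.gro` structure file.
#' @param trajectory_path optional path to a `.dcd` or multi-model `.pdb`
#'   trajectory; when omitted the structure's own frame(s) are used.
#' @param species a [species_config()] object or path to a species YAML file.
#' @param domains optional protein domain table (see [mlkl_domains()]).
#' @param dt frame interval in ns used for time stamps (default 1).
#' @return a [membrane_system()].
#' @export
load_system <- function(structure_path, trajectory_path = NULL,
                        species = default_species(), domains = NULL, dt = 1) {
  if (!file.exists(structure_path))
    stop("structure file not found: ", structure_path)
  if (is.character(species)) species <- read_species_config(species)

  ext <- tolower(tools::file_ext(structure_path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(structure_path, multi = TRUE)
    a <- pdb$atom
    atoms <- data.frame(eleno = a$eleno, name = trimws(a$elety),
                        resname = trimws(a$resid), resid = a$resno,
                        stringsAsFactors = FALSE)
    nf <- nrow(pdb$xyz)
    coords <- array(NA_real_, c(nrow(atoms), 3, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    box <- pdb_box(structure_path)
    box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  } else if (ext == "gro") {
    g <- read_gro(structure_path)
    atoms <- g$atoms
    coords <- array(g$xyz, c(nrow(atoms), 3, 1))
    box <- matrix(g$box, nrow = 1)
    nf <- 1L
  } else if (ext == "xtc") {
    stop("unsupported structure format: .xtc (use PDB or GRO)")
  } else stop("unsupported structure format: .", ext)

  if (!is.null(trajectory_path)) {
    if (!file.exists(trajectory_path))
      stop("trajectory file not found: ", trajectory_path)
    text <- tolower(tools::file_ext(trajectory_path))
    if (text == "dcd") {
      xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
      cell <- bio3d::read.dcd(trajectory_path, cell = TRUE, verbose = FALSE)
      if (ncol(xyz) != 3L * nrow(atoms))
        stop("atom count mismatch: structure has ", nrow(atoms),
             " atoms, trajectory frames have ", ncol(xyz) / 3)
      if (any(abs(cell[, 4:6] - 90) > 1e-3))
        stop("triclinic boxes are not supported (orthorhombic only)")
      nf <- nrow(xyz)
      coords <- array(NA_real_, c(nrow(atoms), 3, nf))
      for (f in seq_len(nf))
        coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      box <- as.matrix(cell[, 1:3, drop = FALSE])
    } else if (text == "pdb") {
      tr <- bio3d::read.pdb(trajectory_path, multi = TRUE)
      if (ncol(tr$xyz) != 3L * nrow(atoms))
        stop("atom count mismatch: structure has ", nrow(atoms),
             " atoms, trajectory frames have ", ncol(tr$xyz) / 3)
      nf <- nrow(tr$xyz)
      coords <- array(NA_real_, c(nrow(atoms), 3, nf))
      for (f in seq_len(nf))
        coords[, , f] <- matrix(tr$xyz[f, ], ncol = 3, byrow = TRUE)
      b <- pdb_box(trajectory_path)
      box <- matrix(b, nrow = nf, ncol = 3, byrow = TRUE)
    } else if (text == "xtc") {
      stop("unsupported trajectory format: .xtc (use DCD or multi-model PDB)")
    } else stop("unsupported trajectory format: .", text)
  }

  membrane_system(atoms, coords, box, time = (seq_len(nf) - 1) * dt,
                  species = species, domains = domains)
}

# CRYST1 box lengths from a PDB file (falls back to a generous bounding box
# when the record is absent); rejects triclinic cells
pdb_box <- function(path) {
  ln <- grep("^CRYST1", readLines(path, n = 200L, warn = FALSE), value = TRUE)
  if (!length(ln)) return(c(1000, 1000, 1000))
  abc <- as.numeric(c(substr(ln[1], 7, 15), substr(ln[1], 16, 24),
                      substr(ln[1], 25, 33)))
  ang <- as.numeric(c(substr(ln[1], 34, 40), substr(ln[1], 41, 47),
                      substr(ln[1], 48, 54)))
  if (any(abs(ang - 90) > 1e-3))
    stop("triclinic boxes are not supported (orthorhombic only)")
  abc
}

# fixed-width GRO reader (coordinates nm -> Angstrom)
read_gro <- function(path) {
  ln <- readLines(path, warn = FALSE)
  natoms <- as.integer(trimws(ln[2]))
  al <- ln[3:(2 + natoms)]
  atoms <- data.frame(
    eleno = as.integer(substr(al, 16, 20)),
    name = trimws(substr(al, 11, 15)),
    resname = trimws(substr(al, 6, 10)),
    resid = as.integer(substr(al, 1, 5)),
    stringsAsFactors = FALSE)
  xyz <- cbind(as.numeric(substr(al, 21, 28)),
               as.numeric(substr(al, 29, 36)),
               as.numeric(substr(al, 37, 44))) * 10
  bv <- as.numeric(strsplit(trimws(ln[3 + natoms]), "\\s+")[[1]])
  if (length(bv) > 3 && any(abs(bv[-(1:3)]) > 1e-9))
    stop("triclinic boxes are not supported (orthorhombic only)")
  list(atoms = atoms, xyz = xyz, box = bv[1:3] * 10)
}

#' Write a system to standard MD formats
#'
#' Writes the topology + frame 1 as PDB and GRO, the full trajectory as a
#' (multi-model) PDB and as a binary CHARMM-style DCD, and any attached
#' generator ground truth as JSON. The DCD written here reads back with any
#' standard DCD reader.
#'
#' @param system a [membrane_system()].
#' @param dir output directory (created if needed).
#' @param basename file stem for all outputs.
#' @return named character vector of file paths, invisibly.
#' @export
write_system <- function(system, dir, basename = "system") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(e) file.path(dir, paste0(basename, e))
  write_pdb(system, p(".pdb"), frames = 1L)
  write_gro(system, p(".gro"), frame = 1L)
  write_pdb(system, p("_traj.pdb"))
  write_dcd(system, p(".dcd"))
  write_species_config(system$species, p("_species.yaml"))
  out <- c(pdb = p(".pdb"), gro = p(".gro"), traj_pdb = p("_traj.pdb"),
           dcd = p(".dcd"), species = p("_species.yaml"))
  gt <- attr(system, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, p("_truth.json"), auto_unbox = TRUE, digits = NA)
    out <- c(out, truth = p("_truth.json"))
  }
  invisible(out)
}

#' @rdname write_system
#' @param path output file path.
#' @param frames frame indices to write (PDB writes one MODEL per frame).
#' @export
write_pdb <- function(system, path, frames = seq_len(n_frames(system))) {
  a <- system$atoms
  con <- file(path, "w")
  on.exit(close(con))
  b <- system$box[frames[1], ]
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90), con)
  multi <- length(frames) > 1L
  for (f in frames) {
    if (multi) writeLines(sprintf("MODEL     %4d", match(f, frames)), con)
    xyz <- system$coords[, , f]
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, substr(nm, 1, 4), substr(a$resname, 1, 4),
      a$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(a$element, 1, 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_system
#' @param frame frame index to write.
#' @export
write_gro <- function(system, path, frame = 1L) {
  a <- system$atoms
  xyz <- system$coords[, , frame] / 10
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("generated by lipidprint", con)
  writeLines(sprintf("%5d", nrow(a)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$resid %% 100000L, substr(a$resname, 1, 5),
                     substr(a$name, 1, 5), seq_len(nrow(a)) %% 100000L,
                     xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", system$box[frame, 1] / 10,
                     system$box[frame, 2] / 10, system$box[frame, 3] / 10), con)
  invisible(path)
}

#' @rdname write_system
#' @export
write_dcd <- function(system, path) {
  nf <- n_frames(system)
  na <- n_atoms(system)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: payload length markers around the payload
    tmp <- rawConnection(raw(0), "wb")
    writer(tmp)
    payload <- rawConnectionValue(tmp)
    close(tmp)
    writeBin(length(payload), con, size = 4L)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L      # crystal records present
  icntrl[20] <- 24L     # CHARMM version tag
  rec(function(c2) {
    writeBin(charToRaw("CORD"), c2)
    writeBin(icntrl, c2, size = 4L)
  })
  title <- sprintf("%-80s", "lipidprint trajectory")
  rec(function(c2) {
    writeBin(1L, c2, size = 4L)
    writeBin(charToRaw(title), c2)
  })
  rec(function(c2) writeBin(na, c2, size = 4L))
  for (f in seq_len(nf)) {
    b <- system$box[f, ]
    # XTL convention: a, cos(gamma), b, cos(beta), cos(alpha), c
    rec(function(c2) writeBin(c(b[1], 0, b[2], 0, 0, b[3]), c2, size = 8L))
    for (k in 1:3)
      rec(function(c2) writeBin(as.numeric(system$coords[, k, f]), c2,
                                size = 4L))
  }
  invisible(path)
}
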