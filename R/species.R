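#' Lipid species configuration
#'
#' A species configuration maps residue names to lipid species and records,
#' per species: the single headgroup marker atom that represents the lipid's
#' lateral position (the phosphorus atom for phospholipids, the hydroxyl
#' oxygen O3 for cholesterol), the hydrophilic headgroup atom names, the
#' hydrophobic (acyl chain / ring) atom names, the formal headgroup charge in
#' elementary units, and the nominal mole fraction in the bilayer.
#'
#' @param species a list of per-species lists with elements `name`,
#'   `resnames`, `marker`, `hydrophilic`, `hydrophobic`, `charge`, `molfrac`
#'   and optionally `donor_pairs` (named character vector: hydrogen atom name
#'   keyed by donor heavy-atom name, for lipids with titratable headgroups).
#' @return an object of class `species_config`.
#' @export
species_config <- function(species) {
  stopifnot(is.list(species), length(species) > 0L)
  for (sp in species) {
    need <- c("name", "resnames", "marker", "hydrophilic", "hydrophobic",
              "charge", "molfrac")
    miss <- setdiff(need, names(sp))
    if (length(miss))
      stop("species entry missing fields: ", paste(miss, collapse = ", "))
    if (length(sp$marker) != 1L)
      stop("species ", sp$name, ": exactly one marker atom name required")
    if (length(intersect(sp$hydrophilic, sp$hydrophobic)))
      stop("species ", sp$name,
           ": hydrophobic and hydrophilic atom sets must be disjoint")
  }
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate species names")
  mf <- vapply(species, function(s) as.numeric(s$molfrac), 0)
  if (abs(sum(mf) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", format(sum(mf)), ")")
  rn <- unlist(lapply(species, `[[`, "resnames"))
  if (anyDuplicated(rn))
    stop("residue name mapped to more than one species: ",
         paste(unique(rn[duplicated(rn)]), collapse = ", "))
  names(species) <- nm
  structure(species, class = "species_config")
}

#' Default plasma-membrane species set
#'
#' Five-species inner-leaflet plasma membrane model:
#' DOPC:Chol:DOPE:PIP:PIP2 at 40:32:20:4:4 mol%. Formal headgroup charges
#' default to 0/0/0/-3/-5 e. Atom names follow the coarse bead convention of
#' [build_bilayer()]; for atomistic inputs supply your own configuration with
#' the force-field atom names.
#'
#' @return a [species_config()] object.
#' @export
default_species <- function() {
  species_config(list(
    list(name = "DOPC", resnames = "DOPC", marker = "P",
         hydrophilic = c("O11", "O12"),
         hydrophobic = c("C21", "C22", "C31", "C32"),
         charge = 0L, molfrac = 0.40),
    list(name = "CHOL", resnames = c("CHL1", "CHOL"), marker = "O3",
         hydrophilic = character(),
         hydrophobic = c("C1", "C2", "C3"),
         charge = 0L, molfrac = 0.32),
    list(name = "DOPE", resnames = "DOPE", marker = "P",
         hydrophilic = c("O11", "O12"),
         hydrophobic = c("C21", "C22", "C31", "C32"),
         charge = 0L, molfrac = 0.20),
    list(name = "PIP", resnames = c("POPI", "PI14", "PIP"), marker = "P",
         hydrophilic = c("O11", "O12"),
         hydrophobic = c("C21", "C22", "C31", "C32"),
         charge = -3L, molfrac = 0.04),
    list(name = "PIP2", resnames = c("PI25", "PIP2"), marker = "P",
         hydrophilic = c("O11", "O12"),
         hydrophobic = c("C21", "C22", "C31", "C32"),
         charge = -5L, molfrac = 0.04)
  ))
}

#' Read / write a species configuration as YAML
#'
#' The YAML layout is a top-level `species:` list whose entries carry
#' `name`, `resnames`, `marker`, `hydrophilic`, `hydrophobic`, `charge`,
#' `molfrac` (and optionally `donor_pairs`).
#'
#' @param path file path.
#' @return `read_species_config()` returns a [species_config()];
#'   `write_species_config()` returns `path` invisibly.
#' @export
read_species_config <- function(path) {
  if (!file.exists(path)) stop("species config not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$species)) stop("species config: missing top-level 'species'")
  sp <- lapply(y$species, function(s) {
    if (!is.null(s$donor_pairs)) s$donor_pairs <- unlist(s$donor_pairs)
    s
  })
  species_config(sp)
}

#' @rdname read_species_config
#' @param cfg a [species_config()] object.
#' @export
write_species_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "species_config"))
  y <- list(species = lapply(unname(cfg), function(s) {
    s$resnames <- as.list(s$resnames)
    s$hydrophilic <- as.list(s$hydrophilic)
    s$hydrophobic <- as.list(s$hydrophobic)
    if (!is.null(s$donor_pairs)) s$donor_pairs <- as.list(s$donor_pairs)
    s
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.species_config <- function(x, ...) {
  cat("Species configuration (", length(x), " species)\n", sep = "")
  for (s in x)
    cat(sprintf("  %-6s molfrac %.3f charge %+d  marker %s  resnames: %s\n",
                s$name, s$molfrac, as.integer(s$charge), s$marker,
                paste(s$resnames, collapse = ",")))
  invisible(x)
}

# species name for each residue name; NA when unknown
species_of_resname <- function(cfg, resname) {
  map <- unlist(unname(lapply(cfg, function(s)
    stats::setNames(rep(s$name, length(s$resnames)), s$resnames))))
  unname(map[resname])
}

# role ("marker"/"hydrophilic"/"hydrophobic"/NA) of a lipid atom name within
# its species
role_of_atom <- function(sp, atom_name) {
  out <- rep(NA_character_, length(atom_name))
  out[atom_name == sp$marker] <- "marker"
  out[atom_name %in% sp$hydrophilic] <- "hydrophilic"
  out[atom_name %in% sp$hydrophobic] <- "hydrophobic"
  out
}
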