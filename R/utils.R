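#' Block-averaged standard error
#'
#' Splits a per-frame time series into `blocks` contiguous, (near-)equal
#' blocks and returns the standard error of the block means,
#' `sd(block means)/sqrt(blocks)`. This is the conventional way to quote
#' uncertainties on trajectory averages in the presence of serial
#' correlation: frames within a block are correlated, block means much less
#' so.
#'
#' @param x numeric vector, one value per frame.
#' @param blocks number of contiguous blocks (default 5).
#' @return standard error (0 for constant series; `NA` if `length(x) < blocks`).
#' @export
block_se <- function(x, blocks = 5L) {
  n <- length(x)
  if (n == 0L) stop("block_se: empty series")
  if (n < blocks) return(NA_real_)
  idx <- cut(seq_len(n), breaks = blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  stats::sd(bm) / sqrt(blocks)
}

# van der Waals radii (A) by element, Bondi-style values; used for disk
# rasterization (protein masks, surface classification) when an atom has no
# explicit radius.
.vdw_table <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8,
                K = 2.75, NA. = 2.27, CL = 1.75)

vdw_radius <- function(element) {
  r <- .vdw_table[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

# Infer element from an atom name: strip digits/primes, first letter wins
# ("CA" -> C, "O3" -> O, "HN" -> H, "P" -> P).
infer_element <- function(name) {
  nm <- toupper(gsub("[0-9']", "", name))
  el <- substr(nm, 1L, 1L)
  el[el == ""] <- "X"
  el
}

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
          "SER", "THR", "TRP", "TYR", "VAL")
.water_resnames <- c("TIP3", "TIP3P", "HOH", "SOL", "WAT", "SPC", "TIP4")
.ion_resnames <- c("K", "CL", "NA", "SOD", "POT", "CLA", "CAL", "MG", "CA2")

# Wrap coordinates into [0, box) per axis.
wrap_coords <- function(x, box) {
  x - floor(x / box) * box
}

# deterministic md5 of an R object (via its deparsed representation)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
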