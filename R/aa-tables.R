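# Shared amino-acid constants: 3<->1 letter codes, residue masses, vdW radii.

#' @keywords internal
AA_THREE <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
              "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

#' @keywords internal
AA_ONE <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")

#' @keywords internal
aa3to1 <- function(x) {
  out <- AA_ONE[match(toupper(x), AA_THREE)]
  out[is.na(out)] <- "X"
  out
}

#' @keywords internal
aa1to3 <- function(x) {
  out <- AA_THREE[match(toupper(x), AA_ONE)]
  if (anyNA(out)) stop("unknown one-letter amino-acid code: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

# Average residue (i.e. dehydrated) masses in Da; free peptide = sum + water.
#' @keywords internal
AA_MASS_AVG <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

#' @keywords internal
AA_MASS_MONO <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  Q = 128.05858, E = 129.04259, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

#' @keywords internal
MASS_WATER_AVG  <- 18.01528
#' @keywords internal
MASS_WATER_MONO <- 18.010565

# Element-based van der Waals radii (Angstrom), hydrogens ignored throughout.
#' @keywords internal
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)

#' @keywords internal
vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  if (anyNA(r)) stop("unknown element(s): ",
                     paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

#' @keywords internal
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# BLOSUM62 lookup via Biostrings' bundled matrix.
#' @keywords internal
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
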