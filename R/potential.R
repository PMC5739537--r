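# Residue-residue contact pair potentials. The design stage scores a
# candidate substitution by how much it worsens (raises) the summed contact
# energy against the antibody residues it touches; the same machinery scores
# intra-antigen packing for the stability filter. Any complete symmetric
# 20x20 matrix can be plugged in.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy
kd_hydropathy <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# nominal side-chain charge at neutral pH
aa_charge <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0.5,
  I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0
)

#' Validate and label a pair potential
#'
#' @param mat numeric 20x20 matrix with one-letter amino-acid row and column
#'   names, symmetric, all entries finite; lower values are more favorable
#'   contacts
#' @param name provenance label carried into outputs
#' @return object of class `pair_potential` (the matrix with a `name`
#'   attribute)
#' @export
pair_potential <- function(mat, name = "custom") {
  stopifnot(is.matrix(mat), nrow(mat) == 20L, ncol(mat) == 20L)
  if (!setequal(rownames(mat), AA1) || !setequal(colnames(mat), AA1)) {
    stop("pair potential must be indexed by the 20 one-letter amino-acid codes")
  }
  mat <- mat[AA1, AA1]
  if (!all(is.finite(mat))) stop("pair potential has non-finite entries")
  if (max(abs(mat - t(mat))) > 1e-9) stop("pair potential must be symmetric")
  structure(mat, name = name, class = c("pair_potential", "matrix", "array"))
}

#' Default physicochemical contact potential
#'
#' A simple two-term contact energy built from side-chain charge and
#' Kyte-Doolittle hydropathy: `p(a, b) = q_a * q_b - h_a * h_b` with
#' hydropathy scaled to `[-1, 1]`. Like-charge contacts and
#' hydrophobic/hydrophilic mismatches are unfavorable (higher); charge
#' complementarity and hydrophobic matching are favorable (lower). Any
#' published 20x20 contact potential can be supplied instead via
#' [read_pair_potential()].
#'
#' @return a [pair_potential()]
#' @export
default_pair_potential <- function() {
  h <- kd_hydropathy[AA1] / 4.5
  q <- aa_charge[AA1]
  mat <- outer(q, q) - outer(h, h)
  dimnames(mat) <- list(AA1, AA1)
  pair_potential(mat, name = "charge-hydropathy contact potential")
}

#' Read a 20x20 pair potential from a whitespace-delimited text file
#'
#' Expected format: a header row of 20 one-letter amino-acid codes, then 20
#' rows each starting with the row's code followed by 20 numbers.
#'
#' @param path input file
#' @param name provenance label (defaults to the file name)
#' @return a [pair_potential()]
#' @export
read_pair_potential <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  pair_potential(as.matrix(tab), name = name)
}

#' Write a pair potential in the text format read by [read_pair_potential()]
#'
#' @param pot a [pair_potential()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pair_potential <- function(pot, path) {
  utils::write.table(format(unclass(pot), digits = 8), path,
                     quote = FALSE, sep = "\t", col.names = NA)
  invisible(path)
}
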