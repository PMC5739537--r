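# Solvent-accessible surface area by Shrake-Rupley sphere sampling, and
# relative accessibility against per-amino-acid reference maxima.

# van der Waals radii by element (A). Defaults to carbon for rare elements.
vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
  out <- r[toupper(element)]
  out[is.na(out)] <- 1.70
  unname(out)
}

# Theoretical maximal accessible surface areas (A^2) per amino acid,
# Tien et al. 2013 ("theoretical" column); used as RSA denominators.
max_acc_area <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174
)

# deterministic quasi-uniform points on the unit sphere (golden-spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples a fixed quasi-uniform point set on each atom's solvent-expanded
#' sphere (van der Waals radius plus probe radius) and counts the points not
#' buried inside any neighboring atom's sphere. Deterministic for a fixed
#' `n_points`.
#'
#' @param xyz numeric matrix of heavy-atom coordinates (n x 3, Angstroms)
#' @param element character vector of element symbols, length n
#' @param probe probe radius in Angstroms (water, 1.4 by default)
#' @param n_points sphere sampling resolution per atom
#' @return numeric vector of per-atom areas in square Angstroms
#' @export
shrake_rupley <- function(xyz, element, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  stopifnot(n >= 1L, length(element) == n)
  radii <- vdw_radius(element) + probe
  pts <- sphere_points(n_points)
  # neighbor lists from one pairwise distance pass
  D <- cross_dist(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < radii[i] + radii & seq_len(n) != i)
    surf <- sweep(pts * radii[i], 2L, xyz[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj2 <- (surf[free, 1L] - xyz[j, 1L])^2 +
          (surf[free, 2L] - xyz[j, 2L])^2 +
          (surf[free, 3L] - xyz[j, 3L])^2
        free[free] <- dj2 > radii[j]^2
      }
      n_free <- sum(free)
    } else {
      n_free <- n_points
    }
    area[i] <- 4 * pi * radii[i]^2 * n_free / n_points
  }
  area
}

#' Relative solvent accessibility per residue
#'
#' Sums Shrake-Rupley atom areas per residue and divides by the theoretical
#' maximal area for that amino-acid type. Values can exceed 1 for highly
#' exposed (e.g. terminal) residues since the reference maxima are defined
#' in a tripeptide context.
#'
#' @param s an [ag_structure()]
#' @param probe probe radius in Angstroms
#' @param n_points sphere sampling resolution per atom
#' @return a tibble with columns `key`, `aa`, `sasa` (A^2) and `rsa`;
#'   residue types without a reference area get `rsa = NA` and a warning
#' @export
relative_accessibility <- function(s, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "ag_structure"))
  at <- s$atoms
  area <- shrake_rupley(coords_mat(at), at$element, probe, n_points)
  per_res <- tibble::tibble(key = at$key, area = area) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(sasa = sum(.data$area), .groups = "drop")
  out <- dplyr::left_join(s$residues[, c("key", "aa")], per_res, by = "key")
  out$rsa <- out$sasa / unname(max_acc_area[out$aa])
  if (anyNA(out$rsa)) {
    warning("residue type(s) without reference area excluded from surface: ",
            paste(unique(out$aa[is.na(out$rsa)]), collapse = ", "))
  }
  out
}

#' Surface residues at a relative-accessibility threshold
#'
#' @param acc output of [relative_accessibility()]
#' @param threshold RSA threshold; residues with RSA strictly greater than
#'   this are called surface (default 0.07, i.e. "greater than 7%")
#' @return character vector of residue keys
#' @export
surface_residues <- function(acc, threshold = 0.07) {
  acc$key[!is.na(acc$rsa) & acc$rsa > threshold]
}
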