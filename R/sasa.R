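# Shrake-Rupley accessible surface area on heavy atoms, with a fixed
# deterministic sphere point set, so repeated runs give identical areas.

.VDW_RADII <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)
.VDW_DEFAULT <- 1.70

# deterministic golden-spiral unit sphere points
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Accessible surface area per residue (Shrake-Rupley)
#'
#' Computes solvent-accessible surface area with a probe sphere rolled over
#' heavy atoms, sampling each atomic sphere at a fixed number of
#' deterministic points. Unknown elements fall back to a default van der
#' Waals radius of 1.70 A (with a message).
#'
#' @param atoms data.frame with columns `x`, `y`, `z`, `element` and a
#'   residue grouping column `group` (any atom-to-residue key).
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per atom (default 960).
#' @return named numeric vector of areas in A^2, one per distinct `group`
#'   value, in order of first appearance.
#' @export
sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  stopifnot(nrow(atoms) >= 1L)
  el <- toupper(trimws(atoms$element))
  keep <- el != "H"
  atoms <- atoms[keep, , drop = FALSE]
  el <- el[keep]
  if (!nrow(atoms)) stop("no heavy atoms")
  rad <- unname(.VDW_RADII[el])
  if (anyNA(rad)) {
    message("sasa: unknown element(s) ",
            paste(unique(el[is.na(rad)]), collapse = ","),
            "; using default radius ", .VDW_DEFAULT, " A")
    rad[is.na(rad)] <- .VDW_DEFAULT
  }
  r_ext <- rad + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)

  # pairwise neighbour lists
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    thresh <- (r_ext[i] + r_ext)^2
    nb <- which(d2[i, ] < thresh)
    nb <- nb[nb != i]
    P <- pts * r_ext[i]
    P <- sweep(P, 2L, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 > r_ext[j]^2)
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * r_ext[i]^2 * sum(acc) / n_points
  }
  grp <- as.character(atoms$group)
  out <- tapply(area, factor(grp, levels = unique(grp)), sum)
  setNames(as.numeric(out), names(out))
}
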