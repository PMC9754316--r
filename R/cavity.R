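# Molecular cavity from interlocking scaled van der Waals spheres, each
# tessellated by recursive icosahedral subdivision; tesserae whose centers lie
# strictly inside another sphere are discarded (exposed-surface filter).

# Default van der Waals radii (angstrom): one half of the UFF nonbonded
# distances, giving a 1.443 angstrom hydrogen sphere at unit scale.  The
# Bondi-Mantina set is kept as a named alternative.
.default_radii <- c(H = 1.443, He = 1.181, Be = 1.3725, C = 1.9255,
                    N = 1.83, O = 1.75)
.bondi_radii <- c(H = 1.20, He = 1.40, Be = 1.53, C = 1.70, N = 1.55,
                  O = 1.52)

#' Solvent and cavity parameters
#'
#' @param epsilon solvent dielectric constant (>= 1); 46.7 for DMSO,
#'   78.39 for water.
#' @param radii named element -> radius map in angstrom, or the set names
#'   `"uff"` (default: half the UFF nonbonded distances, hydrogen sphere
#'   1.443 angstrom) / `"bondi"` (Bondi-Mantina; commonly used with
#'   `scale = 1.2`).
#' @param scale dimensionless scaling of the radii (default 1).
#' @param tess_level icosahedral subdivision depth (each atomic sphere gets
#'   `20 * 4^tess_level` spherical triangles before the burial filter).
#' @return List of class `solvqe_solvent`.
#' @export
solvent_params <- function(epsilon = 46.7, radii = NULL, scale = 1.0,
                           tess_level = 3L) {
  if (epsilon < 1) stop("epsilon must be >= 1")
  r <- .default_radii
  if (is.character(radii)) {
    r <- switch(match.arg(radii, c("uff", "bondi")),
                uff = .default_radii, bondi = .bondi_radii)
  } else if (!is.null(radii)) r[names(radii)] <- radii
  if (any(r <= 0)) stop("radii must be positive")
  structure(list(epsilon = epsilon, radii_map = r, radius_scale = scale,
                 tess_level = as.integer(tess_level)),
            class = "solvqe_solvent")
}

# unit icosahedron: 12 vertices, 20 outward-oriented faces
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  # faces = all vertex triples at the minimal pairwise distance
  d <- as.matrix(dist(v))
  edge <- min(d[d > 1e-9]) + 1e-9
  faces <- NULL
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12)
    if (d[i, j] < edge && d[i, k] < edge && d[j, k] < edge)
      faces <- rbind(faces, c(i, j, k))
  # orient outward
  for (f in seq_len(nrow(faces))) {
    a <- v[faces[f, 1], ]; b <- v[faces[f, 2], ]; c3 <- v[faces[f, 3], ]
    nrm <- crossprod_vec(b - a, c3 - a)
    if (sum(nrm * (a + b + c3)) < 0) faces[f, 2:3] <- faces[f, 3:2]
  }
  list(vertices = v, faces = faces)
}

crossprod_vec <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

# subdivide each spherical triangle into 4, projecting midpoints to the sphere
.subdivide <- function(tri) {
  out <- vector("list", 4 * length(tri))
  k <- 0
  for (t3 in tri) {
    a <- t3[1, ]; b <- t3[2, ]; c3 <- t3[3, ]
    ab <- (a + b); ab <- ab / sqrt(sum(ab^2))
    bc <- (b + c3); bc <- bc / sqrt(sum(bc^2))
    ca <- (c3 + a); ca <- ca / sqrt(sum(ca^2))
    out[[k + 1]] <- rbind(a, ab, ca)
    out[[k + 2]] <- rbind(ab, b, bc)
    out[[k + 3]] <- rbind(ca, bc, c3)
    out[[k + 4]] <- rbind(ab, bc, ca)
    k <- k + 4
  }
  out
}

# solid angle of a spherical triangle on the unit sphere (Van Oosterom-Strackee)
.solid_angle <- function(a, b, c3) {
  num <- abs(sum(a * crossprod_vec(b, c3)))
  den <- 1 + sum(a * b) + sum(b * c3) + sum(c3 * a)
  2 * atan2(num, den)
}

#' Tessellate the molecular cavity
#'
#' Builds the union-of-spheres cavity: one sphere per atom with radius
#' `scale * radii[element]`, each tessellated into `20 * 4^tess_level`
#' spherical triangles.  A tessera's representative point is the triangle
#' centroid projected onto its sphere; its area is the spherical-triangle
#' area.  Tesserae whose center lies strictly inside another sphere are
#' discarded; a sphere may end up contributing no tesserae (fully buried).
#'
#' @param geom a [geometry()] object.
#' @param solvent a [solvent_params()] object.
#' @return Object of class `solvqe_cavity`: `centers` (N x 3, bohr), `areas`
#'   (bohr^2), `normals` (outward units), `sphere_of`, `sphere_centers`,
#'   `sphere_radii` (bohr), `solvent`.
#' @export
build_cavity <- function(geom, solvent = solvent_params()) {
  centers_at <- coords_bohr(geom)
  radii <- unname(.bohr(solvent$radius_scale *
                        solvent$radii_map[geom$atoms$element]))
  ico <- .icosahedron()
  tri0 <- lapply(seq_len(nrow(ico$faces)), function(f)
    ico$vertices[ico$faces[f, ], , drop = FALSE])
  tri <- tri0
  lev <- solvent$tess_level
  if (lev > 0) for (l in seq_len(lev)) tri <- .subdivide(tri)
  ntri <- length(tri)
  # unit-sphere template: centroids (projected), solid angles
  cent0 <- t(vapply(tri, function(t3) {
    m <- colSums(t3) / 3; m / sqrt(sum(m^2))
  }, numeric(3)))
  omega0 <- vapply(tri, function(t3)
    .solid_angle(t3[1, ], t3[2, ], t3[3, ]), 0)
  centers <- NULL; areas <- NULL; normals <- NULL; sphere_of <- NULL
  for (m in seq_len(nrow(centers_at))) {
    R <- radii[m]
    pts <- sweep(cent0 * R, 2, centers_at[m, ], `+`)
    keep <- rep(TRUE, ntri)
    for (m2 in seq_len(nrow(centers_at))) {
      if (m2 == m) next
      d2 <- (pts[, 1] - centers_at[m2, 1])^2 +
            (pts[, 2] - centers_at[m2, 2])^2 +
            (pts[, 3] - centers_at[m2, 3])^2
      keep <- keep & (d2 >= (radii[m2] * (1 - 1e-12))^2)
    }
    if (!any(keep)) next
    centers <- rbind(centers, pts[keep, , drop = FALSE])
    areas <- c(areas, omega0[keep] * R^2)
    normals <- rbind(normals, cent0[keep, , drop = FALSE])
    sphere_of <- c(sphere_of, rep(m, sum(keep)))
  }
  if (is.null(centers)) stop("cavity has zero exposed tesserae")
  # seam pruning: exposed tesserae of different spheres can end up nearly
  # coincident along sphere-intersection seams, which destroys the
  # conditioning of the collocation operators; drop the smaller-area member
  # of any cross-sphere pair closer than half the local mesh spacing
  N <- nrow(centers)
  if (N > 1 && nrow(centers_at) > 1) {
    keep <- rep(TRUE, N)
    spacing <- sqrt(areas)
    spheres <- unique(sphere_of)
    for (m1 in spheres) for (m2 in spheres[spheres > m1]) {
      i1 <- which(sphere_of == m1 & keep)
      i2 <- which(sphere_of == m2 & keep)
      if (!length(i1) || !length(i2)) next
      d2 <- outer(centers[i1, 1], centers[i2, 1], `-`)^2 +
            outer(centers[i1, 2], centers[i2, 2], `-`)^2 +
            outer(centers[i1, 3], centers[i2, 3], `-`)^2
      lim <- (0.5 * pmin(outer(spacing[i1], rep(1, length(i2))),
                         outer(rep(1, length(i1)), spacing[i2])))^2
      pairs <- which(d2 < lim, arr.ind = TRUE)
      for (r in seq_len(nrow(pairs))) {
        a1 <- i1[pairs[r, 1]]; a2 <- i2[pairs[r, 2]]
        if (keep[a1] && keep[a2])
          keep[if (areas[a1] <= areas[a2]) a1 else a2] <- FALSE
      }
    }
    centers <- centers[keep, , drop = FALSE]
    areas <- areas[keep]
    normals <- normals[keep, , drop = FALSE]
    sphere_of <- sphere_of[keep]
  }
  structure(list(centers = centers, areas = areas, normals = normals,
                 sphere_of = sphere_of, sphere_centers = centers_at,
                 sphere_radii = radii, solvent = solvent,
                 n_tess = nrow(centers)), class = "solvqe_cavity")
}

#' @export
print.solvqe_cavity <- function(x, ...) {
  cat(sprintf("Cavity: %d tesserae on %d sphere(s), area %.2f bohr^2, tess_level %d\n",
              x$n_tess, nrow(x$sphere_centers), sum(x$areas),
              x$solvent$tess_level))
  invisible(x)
}

#' Export a cavity as a point-cloud table
#'
#' Writes one row per tessera (center, area, outward normal, owning sphere)
#' as tab-separated values for external inspection.
#'
#' @param cavity a [build_cavity()] object.
#' @param path output file path.
#' @export
write_cavity_tsv <- function(cavity, path) {
  df <- data.frame(x = cavity$centers[, 1], y = cavity$centers[, 2],
                   z = cavity$centers[, 3], area = cavity$areas,
                   nx = cavity$normals[, 1], ny = cavity$normals[, 2],
                   nz = cavity$normals[, 3], sphere = cavity$sphere_of)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
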