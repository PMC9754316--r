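# Molecular geometries: construction, XYZ I/O, and the parametric templates
# used to generate every study system internally.

.element_Z <- c(H = 1L, He = 2L, Be = 4L, C = 6L, N = 7L, O = 8L)

#' Construct a molecular geometry
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of Cartesian coordinates in angstrom.
#' @param net_charge integer net molecular charge.
#' @param label optional text label.
#' @return An object of class `solvqe_geometry` with fields `atoms`
#'   (data frame: element, Z, x, y, z in angstrom), `net_charge`,
#'   `n_electrons` and `label`.
#' @export
geometry <- function(elements, coords, net_charge = 0L, label = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) != nrow(coords))
    stop("number of elements and coordinate rows differ")
  unknown <- setdiff(elements, names(.element_Z))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  Z <- .element_Z[elements]
  ne <- sum(Z) - as.integer(net_charge)
  if (ne < 0) stop("negative electron count")
  structure(list(
    atoms = data.frame(element = elements, Z = as.integer(Z),
                       x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       stringsAsFactors = FALSE, row.names = NULL),
    net_charge = as.integer(net_charge),
    n_electrons = as.integer(ne),
    label = label), class = "solvqe_geometry")
}

#' @export
print.solvqe_geometry <- function(x, ...) {
  cat(sprintf("Geometry%s: %d atoms, charge %+d, %d electrons\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$atoms), x$net_charge, x$n_electrons))
  print(x$atoms, digits = 6)
  invisible(x)
}

coords_angstrom <- function(geom) as.matrix(geom$atoms[, c("x", "y", "z")])
coords_bohr <- function(geom) .bohr(coords_angstrom(geom))

#' Parse XYZ-format text
#'
#' Standard XYZ dialect: atom-count line, comment line (an optional token
#' `charge=n` sets the net charge), then one `element x y z` line per atom,
#' coordinates in angstrom.
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines.
#' @return A [geometry()] object.
#' @export
parse_xyz <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\\s+$", "", lines)
  if (!length(lines) || !nzchar(trimws(lines[1])))
    stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("malformed atom count on line 1: '", lines[1], "'")
  if (length(lines) < n + 2)
    stop("XYZ input truncated: expected ", n, " atom lines")
  comment <- if (length(lines) >= 2) lines[2] else ""
  charge <- 0L
  m <- regmatches(comment, regexpr("charge=(-?[0-9]+)", comment))
  if (length(m) && nzchar(m))
    charge <- as.integer(sub("charge=", "", m))
  el <- character(n); xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- lines[i + 2]
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 4)
      stop("malformed atom line ", i + 2, ": '", ln, "'")
    el[i] <- tok[1]
    v <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(v)))
      stop("non-numeric coordinate on line ", i + 2, ": '", ln, "'")
    xyz[i, ] <- v
  }
  if (any(!el %in% names(.element_Z)))
    stop("unknown element on atom line(s): ",
         paste(unique(el[!el %in% names(.element_Z)]), collapse = ", "))
  geometry(el, xyz, net_charge = charge,
           label = trimws(sub("charge=-?[0-9]+", "", comment)))
}

#' @rdname parse_xyz
#' @param path file path to read.
#' @export
read_xyz <- function(path) parse_xyz(readLines(path))

#' Write a geometry as XYZ text
#'
#' @param geom a [geometry()] object.
#' @param path optional file path; if `NULL` the text is returned invisibly.
#' @return The XYZ text, invisibly.
#' @export
write_xyz <- function(geom, path = NULL) {
  hdr <- sprintf("%d", nrow(geom$atoms))
  cmt <- trimws(paste(geom$label,
                      if (geom$net_charge != 0L)
                        sprintf("charge=%d", geom$net_charge) else ""))
  body <- sprintf("%-2s %18.10f %18.10f %18.10f",
                  geom$atoms$element, geom$atoms$x, geom$atoms$y, geom$atoms$z)
  txt <- paste(c(hdr, cmt, body), collapse = "\n")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Parametric geometry templates
#'
#' Symmetric one- or two-parameter templates for the study systems; every
#' experiment in the package is generated from these (optionally after
#' [optimize_geometry()]), never downloaded.
#'
#' * `"h2"`: bond length `r` (angstrom).
#' * `"h3plus"`: equilateral triangle, side `r`; net charge +1.
#' * `"hehplus"`: He-H distance `r`; net charge +1.
#' * `"beh2"`: linear, symmetric Be-H distance `r`.
#' * `"h2o"`: O-H distance `r` and H-O-H `angle` (degrees).
#'
#' @param name template name.
#' @param r bond-length parameter in angstrom (template-specific default).
#' @param angle bond angle in degrees (water only).
#' @return A [geometry()] object.
#' @export
molecule_fixture <- function(name = c("h2", "h3plus", "hehplus", "beh2", "h2o"),
                             r = NULL, angle = NULL) {
  name <- match.arg(name)
  switch(name,
    h2 = {
      r <- if (is.null(r)) 0.735 else r
      geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r)), 0L, "H2")
    },
    h3plus = {
      r <- if (is.null(r)) 0.986 else r
      h <- r * sqrt(3) / 2
      # equilateral triangle in the xy-plane, centroid at origin
      geometry(c("H", "H", "H"),
               rbind(c(-r / 2, -h / 3, 0), c(r / 2, -h / 3, 0), c(0, 2 * h / 3, 0)),
               1L, "H3+")
    },
    hehplus = {
      r <- if (is.null(r)) 0.775 else r
      geometry(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, r)), 1L, "HeH+")
    },
    beh2 = {
      r <- if (is.null(r)) 1.316 else r
      geometry(c("Be", "H", "H"),
               rbind(c(0, 0, 0), c(0, 0, -r), c(0, 0, r)), 0L, "BeH2")
    },
    h2o = {
      r <- if (is.null(r)) 1.028 else r
      angle <- if (is.null(angle)) 96.8 else angle
      half <- angle / 2 * pi / 180
      geometry(c("O", "H", "H"),
               rbind(c(0, 0, 0),
                     c(r * sin(half), 0, r * cos(half)),
                     c(-r * sin(half), 0, r * cos(half))), 0L, "H2O")
    })
}
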