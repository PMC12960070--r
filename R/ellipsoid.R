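# Best-fitting ellipsoid of a reference ion and concentric shell geometry.

#' Shell-analysis parameters
#'
#' Collects the tunable parameters of the ellipsoidal-shell cluster
#' criterion.
#'
#' @param delta Shell increment \eqn{\delta} in nm (default 0.4, roughly the
#'   size of one solvent molecule): shell `n` has semiaxes `a_i + n * delta`.
#' @param contact_threshold Maximum minimum-interatomic distance (nm) for an
#'   ion to count as in contact with the growing cluster (default 0.3).
#' @param semiaxis_floor Lower bound (nm) applied to each fitted semiaxis so
#'   that planar, linear or single-atom ions still define a positive-volume
#'   base ellipsoid (default 0.1).
#' @param n_max Cap on the number of shells. `NULL` (default) resolves per
#'   frame to `ceiling(min(box) / 2 / delta)`: shells beyond the half-box
#'   are not meaningful under the minimum-image convention.
#' @param heavy_only If `TRUE`, fit the reference ellipsoid on heavy atoms
#'   only (atom names starting with H excluded). Default `FALSE`: all atoms
#'   enter both the fit and the shell counts.
#' @return Object of class `shell_spec`.
#' @export
shell_spec <- function(delta = 0.4, contact_threshold = 0.3,
                       semiaxis_floor = 0.1, n_max = NULL,
                       heavy_only = FALSE) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0,
            is.numeric(contact_threshold), contact_threshold > 0,
            is.numeric(semiaxis_floor), semiaxis_floor >= 0)
  if (!is.null(n_max)) {
    n_max <- as.integer(n_max)
    stopifnot(n_max >= 1)
  }
  structure(list(delta = delta, contact_threshold = contact_threshold,
                 semiaxis_floor = semiaxis_floor, n_max = n_max,
                 heavy_only = isTRUE(heavy_only)),
            class = "shell_spec")
}

#' @export
print.shell_spec <- function(x, ...) {
  cat(sprintf(
    "<shell_spec> delta = %.3f nm, contact threshold = %.3f nm, semiaxis floor = %.3f nm, n_max = %s\n",
    x$delta, x$contact_threshold, x$semiaxis_floor,
    if (is.null(x$n_max)) "auto (half box)" else x$n_max))
  invisible(x)
}

resolve_n_max <- function(spec, box) {
  if (!is.null(spec$n_max)) return(spec$n_max)
  as.integer(ceiling(min(box) / 2 / spec$delta))
}

#' Read a shell_spec from a YAML configuration file
#'
#' Recognised keys: `delta_nm`, `contact_threshold_nm`, `semiaxis_floor_nm`,
#' `n_max` (or `auto`), `heavy_only`. Missing keys take the [shell_spec()]
#' defaults.
#'
#' @param path YAML file.
#' @return A [shell_spec()].
#' @export
read_shell_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  n_max <- cfg$n_max
  if (is.character(n_max) && identical(tolower(n_max), "auto")) n_max <- NULL
  shell_spec(
    delta = cfg$delta_nm %||% 0.4,
    contact_threshold = cfg$contact_threshold_nm %||% 0.3,
    semiaxis_floor = cfg$semiaxis_floor_nm %||% 0.1,
    n_max = n_max,
    heavy_only = cfg$heavy_only %||% FALSE)
}

#' Fit the best-fitting ellipsoid of a set of atom coordinates
#'
#' The ellipsoid is obtained by diagonalizing the 3 x 3 geometric covariance
#' matrix of the coordinates: the unweighted second-moment matrix about the
#' centroid, normalized by the atom count N (not N - 1, so a single atom
#' gives zero). Each eigenvalue \eqn{\lambda_i} yields a semiaxis
#' \eqn{a_i = 2\sqrt{\lambda_i}}, floored at `semiaxis_floor` so degenerate
#' (planar/linear/point) ions still enclose a positive volume.
#'
#' @param coords Numeric n x 3 matrix of atom positions, nm. Must already be
#'   contiguous (unwrapped); [md_frame()] guarantees this for molecules.
#' @param semiaxis_floor Minimum semiaxis length, nm.
#' @return Object of class `ellipsoid`: list with `center` (centroid),
#'   `axes` (orthonormal principal directions as columns, descending
#'   eigenvalue order) and `semiaxes` (descending, nm).
#' @examples
#' pts <- as.matrix(expand.grid(x = c(-1, 1), y = c(-2, 2), z = c(-3, 3)))
#' fit_ellipsoid(pts)$semiaxes # 6 4 2
#' @export
fit_ellipsoid <- function(coords, semiaxis_floor = 0.1) {
  coords <- rbind(coords)
  if (!is.numeric(coords) || ncol(coords) != 3 || nrow(coords) < 1) {
    stop("coords must be a non-empty n x 3 numeric matrix", call. = FALSE)
  }
  center <- colMeans(coords)
  centered <- sweep(coords, 2, center)
  cov3 <- crossprod(centered) / nrow(coords)
  eig <- eigen(cov3, symmetric = TRUE)
  semiaxes <- pmax(2 * sqrt(pmax(eig$values, 0)), semiaxis_floor)
  structure(list(center = center, axes = eig$vectors, semiaxes = semiaxes),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf(
    "<ellipsoid> center (%.3f, %.3f, %.3f) nm, semiaxes (%.3f, %.3f, %.3f) nm\n",
    x$center[1], x$center[2], x$center[3],
    x$semiaxes[1], x$semiaxes[2], x$semiaxes[3]))
  invisible(x)
}

#' Semiaxes of the n-th concentric shell
#'
#' Shell `n` of an ellipsoid with semiaxes `a_i` has semiaxes
#' `a(n) = a_i + n * delta`; `n = 0` is the base ellipsoid itself.
#'
#' @param e An [fit_ellipsoid()] result.
#' @param spec A [shell_spec()].
#' @param n Shell index, integer >= 0.
#' @return Numeric length-3 vector of shell semiaxes, nm.
#' @export
shell_semiaxes <- function(e, spec, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("shell index n must be >= 0", call. = FALSE)
  if (!is.null(spec$n_max) && n > spec$n_max) {
    stop("shell index n = ", n, " exceeds n_max = ", spec$n_max, call. = FALSE)
  }
  e$semiaxes + n * spec$delta
}

#' Test whether a point lies inside a (scaled) ellipsoid
#'
#' The displacement from the ellipsoid centre is wrapped by the minimum-image
#' convention, rotated into the principal frame, and tested against
#' \eqn{\sum_i (x_i / s_i)^2 \le 1}. The boundary is inclusive.
#'
#' @param e An [fit_ellipsoid()] result.
#' @param semiaxes Length-3 semiaxes to test against (e.g. from
#'   [shell_semiaxes()]).
#' @param point Length-3 position, nm.
#' @param box Length-3 box, nm.
#' @return Logical.
#' @export
ellipsoid_contains <- function(e, semiaxes, point, box) {
  stopifnot(all(semiaxes > 0))
  d <- minimum_image(as.numeric(point) - e$center, box)
  local <- drop(crossprod(e$axes, d))
  sum((local / semiaxes)^2) <= 1
}

# Smallest shell index containing each point (NA beyond n_max). Shells
# partition space; a point on a boundary belongs to the inner shell because
# membership is inclusive.
shell_index <- function(e, spec, points, box, n_max = NULL) {
  points <- rbind(points)
  n_max <- n_max %||% resolve_n_max(spec, box)
  d <- minimum_image(sweep(points, 2, e$center), box)
  local <- d %*% e$axes
  idx <- rep(NA_integer_, nrow(points))
  for (n in 0:n_max) {
    open <- is.na(idx)
    if (!any(open)) break
    s <- e$semiaxes + n * spec$delta
    q <- (local[open, 1] / s[1])^2 + (local[open, 2] / s[2])^2 +
      (local[open, 3] / s[3])^2
    idx[which(open)[q <= 1]] <- n
  }
  idx
}

#' Atoms occupying the n-th shell around a reference ion
#'
#' Shell `n > 0` is the region inside the `a(n)` ellipsoid but outside
#' `a(n-1)`; shell 0 is the base-ellipsoid interior. The reference ion's own
#' atoms are excluded. Occupants are grouped into ion atoms (cations and
#' anions together) and solvent atoms, which is the counting the shell-scan
#' termination rules operate on.
#'
#' @param e Ellipsoid of the reference ion.
#' @param spec A [shell_spec()].
#' @param n Shell index >= 0.
#' @param frame An [md_frame()].
#' @param reference_id Molecule id of the reference ion (its atoms are
#'   excluded from the counts).
#' @return List with tibbles `ion` and `solvent`.
#' @export
shell_occupants <- function(e, spec, n, frame, reference_id = NULL) {
  n <- as.integer(n)
  if (n < 0) stop("shell index n must be >= 0", call. = FALSE)
  atoms <- frame$atoms
  if (!is.null(reference_id)) {
    atoms <- atoms[atoms$molecule_id != reference_id, , drop = FALSE]
  }
  idx <- shell_index(e, spec, as.matrix(atoms[, c("x", "y", "z")]),
                     frame$box, n_max = max(n, resolve_n_max(spec, frame$box)))
  sel <- !is.na(idx) & idx == n
  occ <- atoms[sel, , drop = FALSE]
  list(ion = occ[occ$role != "solvent", , drop = FALSE],
       solvent = occ[occ$role == "solvent", , drop = FALSE])
}

reference_coords <- function(frame, molecule_id, spec) {
  atoms <- molecule_atoms(frame, molecule_id)
  if (isTRUE(spec$heavy_only) && "name" %in% names(atoms)) {
    heavy <- !grepl("^[0-9]*H", atoms$name)
    if (any(heavy)) atoms <- atoms[heavy, , drop = FALSE]
  }
  as.matrix(atoms[, c("x", "y", "z")])
}
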