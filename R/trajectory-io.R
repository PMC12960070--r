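# Frame container and coordinate readers.
#
# Internal length unit is nm everywhere (GRO native); PDB coordinates are
# converted from Angstrom on read. Only orthorhombic boxes are supported:
# the shell analysis needs nothing beyond exact minimum-image distances,
# and the minimum-image convention is only simple and exact for rectangular
# boxes.

ROLE_LEVELS <- c("cation", "anion", "solvent")

#' Construct a single-frame container for MD coordinates
#'
#' An `md_frame` holds one time step of a trajectory: an atom table, the
#' orthorhombic box lengths, and an optional time stamp. On construction
#' every molecule is made whole (unwrapped across periodic boundaries) so
#' that all downstream geometry -- ellipsoid fits in particular -- operates
#' on contiguous molecules.
#'
#' @param atoms A data frame with columns `atom_id` (integer), `molecule_id`
#'   (integer), `role` (one of `"cation"`, `"anion"`, `"solvent"`), and
#'   coordinates `x`, `y`, `z` in nm. An optional `name` column carries atom
#'   names for writers.
#' @param box Numeric length-3 vector of orthorhombic box edge lengths, nm.
#' @param time Optional time stamp in ps.
#' @return An object of class `md_frame`: a list with elements `atoms`
#'   (tibble), `box`, and `time`.
#' @examples
#' fr <- md_frame(
#'   tibble::tibble(
#'     atom_id = 1:3, molecule_id = c(1L, 1L, 2L),
#'     role = c("cation", "cation", "anion"),
#'     x = c(0.1, 0.2, 0.9), y = 0.5, z = 0.5
#'   ),
#'   box = c(1, 1, 1)
#' )
#' n_molecules(fr)
#' @export
md_frame <- function(atoms, box, time = NA_real_) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("atom_id", "molecule_id", "role", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) == 0) stop("frame must contain at least one atom", call. = FALSE)
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive finite edge lengths (nm)", call. = FALSE)
  }
  if (!all(atoms$role %in% ROLE_LEVELS)) {
    bad <- setdiff(unique(atoms$role), ROLE_LEVELS)
    stop("unknown role(s): ", paste(bad, collapse = ", "),
         " (must be cation, anion or solvent)", call. = FALSE)
  }
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(pos))) stop("non-finite atom coordinates", call. = FALSE)
  # all atoms of a molecule must share one role
  role_per_mol <- tapply(atoms$role, atoms$molecule_id,
                         function(r) length(unique(r)))
  if (any(role_per_mol > 1)) {
    stop("molecule(s) with inconsistent roles: ",
         paste(names(role_per_mol)[role_per_mol > 1], collapse = ", "),
         call. = FALSE)
  }
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$molecule_id <- as.integer(atoms$molecule_id)
  frame <- structure(list(atoms = atoms, box = box, time = time),
                     class = "md_frame")
  make_whole(frame)
}

#' @export
print.md_frame <- function(x, ...) {
  roles <- table(factor(x$atoms$role, levels = ROLE_LEVELS))
  cat(sprintf(
    "<md_frame> %d atoms, %d molecules, box %.3f x %.3f x %.3f nm\n",
    nrow(x$atoms), length(unique(x$atoms$molecule_id)),
    x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  atoms by role: cation %d, anion %d, solvent %d\n",
              roles[["cation"]], roles[["anion"]], roles[["solvent"]]))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble md_frame
#' @export
as_tibble.md_frame <- function(x, ...) x$atoms

#' Number of molecules in a frame
#' @param frame An [md_frame()].
#' @return Integer count of distinct molecules.
#' @export
n_molecules <- function(frame) length(unique(frame$atoms$molecule_id))

#' Molecule ids of the ions in a frame
#' @param frame An [md_frame()].
#' @return Sorted integer vector of molecule ids whose role is cation or anion.
#' @export
ion_molecules <- function(frame) {
  sort(unique(frame$atoms$molecule_id[frame$atoms$role != "solvent"]))
}

#' Apply the minimum-image convention to displacement vectors
#'
#' Wraps each component of a displacement into `[-box/2, box/2)`, i.e. the
#' displacement to the nearest periodic replica in an orthorhombic box. All
#' inter-molecular distances in the package go through this function.
#'
#' @param delta A length-3 numeric vector or an n x 3 matrix of
#'   displacements, nm.
#' @param box Numeric length-3 box edge lengths, nm.
#' @return Wrapped displacement(s), same shape as `delta`.
#' @examples
#' minimum_image(c(0.9, 0, 0), c(1, 1, 1)) # -0.1, 0, 0
#' @export
minimum_image <- function(delta, box) {
  if (is.matrix(delta)) {
    for (k in 1:3) {
      delta[, k] <- delta[, k] - box[k] * floor(delta[, k] / box[k] + 0.5)
    }
    delta
  } else {
    delta - box * floor(delta / box + 0.5)
  }
}

# Unwrap every molecule so its atoms are mutually contiguous: anchor on the
# first atom and pull every other atom to its nearest image of the anchor.
# Adequate for molecules smaller than half the box, which the constructor
# cannot check cheaply but MD solutes always satisfy.
make_whole <- function(frame) {
  atoms <- frame$atoms
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  mol <- atoms$molecule_id
  for (ids in split(seq_len(nrow(atoms)), mol)) {
    if (length(ids) == 1) next
    anchor <- pos[ids[1], ]
    rel <- sweep(pos[ids, , drop = FALSE], 2, anchor)
    pos[ids, ] <- sweep(minimum_image(rel, frame$box), 2, anchor, "+")
  }
  atoms$x <- pos[, 1]; atoms$y <- pos[, 2]; atoms$z <- pos[, 3]
  frame$atoms <- atoms
  frame
}

#' Extract the atoms of one molecule
#'
#' Molecules are already whole (see [md_frame()]), so the returned atoms are
#' mutually contiguous: no molecule spans a box face.
#'
#' @param frame An [md_frame()].
#' @param molecule_id Integer molecule id.
#' @return Tibble of the molecule's atom records.
#' @export
molecule_atoms <- function(frame, molecule_id) {
  out <- dplyr::filter(frame$atoms, .data$molecule_id == !!molecule_id)
  if (nrow(out) == 0) {
    stop("molecule_id ", molecule_id, " not present in frame", call. = FALSE)
  }
  out
}

mol_coords <- function(frame, molecule_id) {
  as.matrix(molecule_atoms(frame, molecule_id)[, c("x", "y", "z")])
}

#' Read an atom-to-role map
#'
#' Roles are supplied separately from the coordinate file because residue
#' naming in GRO/PDB files is not reliable across preparation tools. The map
#' is a CSV/TSV or YAML file with either per-molecule rows
#' (`molecule_id, role`) or per-atom rows (`atom_id, molecule_id, role`).
#'
#' @param path Path to the role-map file (`.csv`, `.tsv`, `.yaml`/`.yml`).
#' @return Tibble with columns `molecule_id`, `role`, and optionally `atom_id`.
#' @export
read_role_map <- function(path) {
  if (!file.exists(path)) stop("role map not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    raw <- yaml::read_yaml(path)
    if (!is.null(names(raw)) && all(c("molecule_id", "role") %in% names(raw))) {
      map <- tibble::as_tibble(raw)
    } else {
      map <- dplyr::bind_rows(lapply(raw, tibble::as_tibble))
    }
  } else if (ext %in% c("csv", "tsv", "txt", "")) {
    delim <- if (ext == "tsv") "\t" else ","
    map <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  } else {
    stop("unsupported role-map format: .", ext, call. = FALSE)
  }
  if (!all(c("molecule_id", "role") %in% names(map))) {
    stop("role map needs columns (molecule_id, role) or (atom_id, molecule_id, role)",
         call. = FALSE)
  }
  map$molecule_id <- as.integer(map$molecule_id)
  map$role <- as.character(map$role)
  if (!all(map$role %in% ROLE_LEVELS)) {
    stop("role map contains values outside {cation, anion, solvent}",
         call. = FALSE)
  }
  tibble::as_tibble(map)
}

apply_role_map <- function(atoms, roles) {
  if ("atom_id" %in% names(roles)) {
    idx <- match(atoms$atom_id, roles$atom_id)
    if (anyNA(idx)) {
      stop("role map missing atom id(s): ",
           paste(utils::head(atoms$atom_id[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    atoms$molecule_id <- roles$molecule_id[idx]
    atoms$role <- roles$role[idx]
  } else {
    idx <- match(atoms$molecule_id, roles$molecule_id)
    if (anyNA(idx)) {
      stop("role map missing molecule id(s): ",
           paste(utils::head(unique(atoms$molecule_id[is.na(idx)]), 5),
                 collapse = ", "),
           call. = FALSE)
    }
    atoms$role <- roles$role[idx]
  }
  atoms
}

#' Read trajectory frames from GRO, PDB or extended-XYZ files
#'
#' Supported formats:
#' * **GRO** -- fixed-column GROMACS coordinates; velocities are ignored; the
#'   final box line must be orthorhombic (three lengths, or nine values with
#'   zero off-diagonals). Multi-frame files are concatenated GRO blocks.
#' * **PDB** -- `ATOM`/`HETATM` records (parsed via the bio3d package),
#'   `CRYST1` for the box (angles must be 90 degrees), `MODEL`/`ENDMDL` for
#'   multiple frames. Coordinates are converted from Angstrom to nm.
#' * **extended XYZ** (`.xyz`) -- an internal dialect: the comment line
#'   carries `box="lx ly lz"` (nm) and per-atom columns are
#'   `element x y z molecule_id role`, so no separate role map is needed.
#'
#' For GRO and PDB a role map is required (see [read_role_map()]); molecule
#' ids are taken from the residue numbers unless the map is per-atom.
#'
#' @param path Coordinate file.
#' @param roles Role map: a path or a tibble from [read_role_map()].
#'   Optional for extended XYZ.
#' @param format `"auto"` (by extension), `"gro"`, `"pdb"` or `"xyz"`.
#' @param stride Keep every `stride`-th frame (default 1, all frames). The
#'   source trajectory's sampling interval is unknown to the reader, so the
#'   stride is exposed rather than fixed.
#' @return List of [md_frame()] objects in file order.
#' @export
read_frames <- function(path, roles = NULL,
                        format = c("auto", "gro", "pdb", "xyz"),
                        stride = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      gro = "gro", pdb = "pdb", ent = "pdb",
      xyz = "xyz", exyz = "xyz", extxyz = "xyz",
      stop("cannot infer format from extension .", ext,
           "; pass format = explicitly", call. = FALSE))
  }
  if (is.character(roles)) roles <- read_role_map(roles)
  frames <- switch(format,
    gro = read_gro_frames(path, roles),
    pdb = read_pdb_frames(path, roles),
    xyz = read_xyz_frames(path, roles))
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  if (stride > 1) frames <- frames[seq(1, length(frames), by = stride)]
  n_atoms <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (length(unique(n_atoms)) > 1) {
    stop("atom count differs between frames: ",
         paste(unique(n_atoms), collapse = ", "), call. = FALSE)
  }
  frames
}

parse_box_line <- function(values, where) {
  if (length(values) == 3) {
    box <- values
  } else if (length(values) == 9) {
    if (any(abs(values[4:9]) > 1e-9)) {
      stop("triclinic box at ", where,
           ": only orthorhombic boxes are supported", call. = FALSE)
    }
    box <- values[1:3]
  } else {
    stop("malformed box line at ", where, call. = FALSE)
  }
  if (any(!is.finite(box)) || any(box <= 0)) {
    stop("non-positive box at ", where, call. = FALSE)
  }
  box
}

read_gro_frames <- function(path, roles) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n < 1) {
      stop("GRO parse error at line ", i + 1L, ": expected atom count",
           call. = FALSE)
    }
    if (i + 1L + n + 1L > length(lines)) {
      stop("GRO file truncated: frame starting at line ", i,
           " declares ", n, " atoms", call. = FALSE)
    }
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    resid <- suppressWarnings(as.integer(substr(atom_lines, 1, 5)))
    name <- trimws(substr(atom_lines, 11, 15))
    atomid <- suppressWarnings(as.integer(substr(atom_lines, 16, 20)))
    x <- suppressWarnings(as.numeric(substr(atom_lines, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(atom_lines, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(atom_lines, 37, 44)))
    bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
    if (length(bad) > 0) {
      stop("GRO parse error at line ", i + 1L + bad[1],
           ": unparseable atom record", call. = FALSE)
    }
    if (anyNA(atomid)) atomid <- seq_len(n)
    box_vals <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]]))
    box <- parse_box_line(box_vals, paste0("line ", i + 2L + n))
    time <- NA_real_
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(tm) == 2) time <- as.numeric(tm[2])
    atoms <- tibble::tibble(
      atom_id = atomid, molecule_id = resid, role = "solvent",
      name = name, x = x, y = y, z = z)
    if (is.null(roles)) {
      stop("GRO input requires a role map (roles =)", call. = FALSE)
    }
    atoms <- apply_role_map(atoms, roles)
    frames[[length(frames) + 1L]] <- md_frame(atoms, box, time)
    i <- i + n + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (length(frames) == 0) stop("no frames found in ", path, call. = FALSE)
  frames
}

read_pdb_frames <- function(path, roles) {
  if (is.null(roles)) {
    stop("PDB input requires a role map (roles =)", call. = FALSE)
  }
  # bio3d does not expose CRYST1; grab it directly
  header <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(header) == 0) {
    stop("PDB file lacks a CRYST1 record; box is required", call. = FALSE)
  }
  cr <- header[1]
  abc <- as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24), substr(cr, 25, 33)))
  ang <- as.numeric(c(substr(cr, 34, 40), substr(cr, 41, 47), substr(cr, 48, 54)))
  if (any(abs(ang - 90) > 1e-3)) {
    stop("non-orthorhombic CRYST1 angles (", paste(ang, collapse = ", "),
         "): only orthorhombic boxes are supported", call. = FALSE)
  }
  box <- parse_box_line(abc, "CRYST1") / 10  # Angstrom -> nm
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n <- nrow(at)
  lapply(seq_len(nrow(xyz)), function(k) {
    coords <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10  # Angstrom -> nm
    atoms <- tibble::tibble(
      atom_id = as.integer(at$eleno), molecule_id = as.integer(at$resno),
      role = "solvent", name = at$elety,
      x = coords[, 1], y = coords[, 2], z = coords[, 3])
    md_frame(apply_role_map(atoms, roles), box)
  })
}

read_xyz_frames <- function(path, roles = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      stop("XYZ parse error at line ", i, ": expected atom count", call. = FALSE)
    }
    comment <- lines[i + 1L]
    bm <- regmatches(comment, regexec("box=\"([^\"]+)\"", comment))[[1]]
    if (length(bm) != 2) {
      stop("XYZ parse error at line ", i + 1L,
           ": comment must carry box=\"lx ly lz\"", call. = FALSE)
    }
    box <- parse_box_line(as.numeric(strsplit(trimws(bm[2]), "\\s+")[[1]]),
                          paste0("line ", i + 1L))
    time <- NA_real_
    tmm <- regmatches(comment, regexec("time=([-0-9.eE+]+)", comment))[[1]]
    if (length(tmm) == 2) time <- as.numeric(tmm[2])
    if (i + 1L + n > length(lines)) {
      stop("XYZ file truncated at line ", i, call. = FALSE)
    }
    recs <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    lens <- lengths(recs)
    if (any(lens < 6)) {
      stop("XYZ parse error at line ", i + 1L + which(lens < 6)[1],
           ": need columns element x y z molecule_id role", call. = FALSE)
    }
    m <- do.call(rbind, recs)
    atoms <- tibble::tibble(
      atom_id = seq_len(n),
      molecule_id = as.integer(m[, 5]),
      role = m[, 6],
      name = m[, 1],
      x = as.numeric(m[, 2]), y = as.numeric(m[, 3]), z = as.numeric(m[, 4]))
    if (anyNA(atoms$molecule_id) || anyNA(atoms$x)) {
      stop("XYZ parse error in frame starting at line ", i, call. = FALSE)
    }
    if (!is.null(roles)) atoms <- apply_role_map(atoms, roles)
    frames[[length(frames) + 1L]] <- md_frame(atoms, box, time)
    i <- i + n + 2L
  }
  if (length(frames) == 0) stop("no frames found in ", path, call. = FALSE)
  frames
}

#' Write frames to GRO or extended-XYZ files
#'
#' `write_gro()` emits standard fixed-column GRO blocks (concatenated for
#' multiple frames); roles are not representable in GRO, so pair it with
#' [write_role_map()]. `write_xyz()` emits the package's extended-XYZ
#' dialect, which is self-contained (box, molecule ids and roles embedded).
#'
#' @param frames An [md_frame()] or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    a <- fr$atoms
    nm <- if ("name" %in% names(a)) substr(a$name, 1, 5) else "X"
    writeLines(c(
      if (is.na(fr$time)) "frame" else sprintf("frame t= %.4f", fr$time),
      sprintf("%5d", nrow(a)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              a$molecule_id %% 100000L, substr(a$role, 1, 5), nm,
              a$atom_id %% 100000L, a$x, a$y, a$z),
      sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2], fr$box[3])
    ), con)
  }
  invisible(path)
}

#' @rdname write_gro
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    a <- fr$atoms
    nm <- if ("name" %in% names(a)) a$name else "X"
    comment <- sprintf('box="%.6f %.6f %.6f"', fr$box[1], fr$box[2], fr$box[3])
    if (!is.na(fr$time)) comment <- paste0(comment, sprintf(" time=%.6f", fr$time))
    writeLines(c(
      sprintf("%d", nrow(a)),
      comment,
      sprintf("%s %.6f %.6f %.6f %d %s", nm, a$x, a$y, a$z, a$molecule_id, a$role)
    ), con)
  }
  invisible(path)
}

#' @rdname write_gro
#' @export
write_role_map <- function(frames, path) {
  fr <- if (inherits(frames, "md_frame")) frames else frames[[1]]
  map <- dplyr::distinct(fr$atoms, .data$molecule_id, .data$role)
  readr::write_csv(map, path, progress = FALSE)
  invisible(path)
}
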