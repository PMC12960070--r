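# Iterative shell-expansion cluster detection.
#
# The operational definition: two ions contribute to the same cluster when
# their closest approach is not obstructed by solvent. Operationally, a
# reference ion's best-fitting ellipsoid is expanded in concentric shells of
# increment delta; ions whose atoms appear in a shell are accepted into the
# cluster when their minimum interatomic distance to the accumulated cluster
# does not exceed the contact threshold; the scan stops when a shell holds
# only solvent, or holds foreign ion atoms none of which are in contact.

# Minimum interatomic distance between two atom-coordinate sets under the
# minimum-image convention.
min_pair_dist <- function(a, b, box) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  dx <- dx - box[1] * floor(dx / box[1] + 0.5)
  dy <- dy - box[2] * floor(dy / box[2] + 0.5)
  dz <- dz - box[3] * floor(dz / box[3] + 0.5)
  d2 <- dx * dx + dy * dy + dz * dz
  k <- which.min(d2)
  i <- (k - 1) %% nrow(a) + 1
  j <- (k - 1) %/% nrow(a) + 1
  list(dist = sqrt(d2[k]), i = i, j = j,
       dvec = c(dx[i, j], dy[i, j], dz[i, j]))
}

# Per-frame geometry cache: coordinate matrix, role/molecule vectors and the
# row indices of each molecule, so repeated grow_cluster calls do no tibble
# work in the inner loop.
frame_cache <- function(frame) {
  atoms <- frame$atoms
  list(
    pos = as.matrix(atoms[, c("x", "y", "z")]),
    mol = atoms$molecule_id,
    role = atoms$role,
    is_ion = atoms$role != "solvent",
    rows_by_mol = split(seq_len(nrow(atoms)), atoms$molecule_id),
    box = frame$box)
}

mol_rows <- function(cache, id) cache$rows_by_mol[[as.character(id)]]

#' Grow the cluster associated with one reference ion
#'
#' Implements the shell-expansion loop: fit the reference ion's ellipsoid;
#' for shells n = 0, 1, 2, ... collect the occupants; every non-assigned ion
#' with at least one atom in the shell is a candidate (atom-level detection,
#' molecule-level acceptance), and a candidate is accepted when the minimum
#' interatomic distance between its atoms and the atoms of any
#' already-accepted member (reference included) is at most the contact
#' threshold. Acceptance is iterated to a fixed point within each shell so
#' contact chains inside one shell are resolved. The scan terminates when
#' (a) a shell contains solvent but no unassigned-ion atoms, or (b) a shell
#' contains unassigned-ion atoms but none is accepted, or the shell cap is
#' reached; a shell holding only already-accepted members' atoms (or nothing)
#' does not terminate the scan. Accepted ions enter as whole molecules.
#'
#' @param frame An [md_frame()].
#' @param reference_id Molecule id of the reference ion (must be an ion).
#' @param spec A [shell_spec()].
#' @param excluded Integer ids of ions already assigned to other clusters;
#'   they are never candidates.
#' @return Tibble with one row per member ion: `molecule_id`, `role`.
#' @export
grow_cluster <- function(frame, reference_id, spec = shell_spec(),
                         excluded = integer()) {
  cache <- frame_cache(frame)
  grow_cluster_impl(cache, frame, reference_id, spec, excluded)
}

grow_cluster_impl <- function(cache, frame, reference_id, spec, excluded) {
  ref_rows <- mol_rows(cache, reference_id)
  if (is.null(ref_rows)) {
    stop("reference molecule ", reference_id, " not in frame", call. = FALSE)
  }
  if (!cache$is_ion[ref_rows[1]]) {
    stop("reference molecule ", reference_id, " is not an ion", call. = FALSE)
  }
  if (reference_id %in% excluded) {
    stop("reference ion ", reference_id, " is already assigned", call. = FALSE)
  }
  e <- fit_ellipsoid(reference_coords(frame, reference_id, spec),
                     spec$semiaxis_floor)
  n_max <- resolve_n_max(spec, cache$box)
  shell_of <- shell_index(e, spec, cache$pos, cache$box, n_max = n_max)

  members <- reference_id
  member_rows <- ref_rows
  for (n in 0:n_max) {
    in_shell <- which(!is.na(shell_of) & shell_of == n)
    in_shell <- in_shell[!(cache$mol[in_shell] %in% reference_id)]
    if (length(in_shell) == 0) next
    mols_here <- unique(cache$mol[in_shell[cache$is_ion[in_shell]]])
    solvent_here <- any(!cache$is_ion[in_shell])
    new_ions <- setdiff(mols_here, members)
    candidates <- setdiff(new_ions, excluded)

    accepted_any <- FALSE
    repeat {
      progressed <- FALSE
      for (cand in candidates) {
        crows <- mol_rows(cache, cand)
        d <- min_pair_dist(cache$pos[crows, , drop = FALSE],
                           cache$pos[member_rows, , drop = FALSE],
                           cache$box)$dist
        if (d <= spec$contact_threshold) {
          members <- c(members, cand)
          member_rows <- c(member_rows, crows)
          candidates <- setdiff(candidates, cand)
          progressed <- TRUE
          accepted_any <- TRUE
        }
      }
      if (!progressed || length(candidates) == 0) break
    }

    if (accepted_any) next
    if (length(new_ions) > 0) break            # (b) ions present, none in contact
    if (solvent_here) break                    # (a) only solvent (plus members)
  }

  tibble::tibble(
    molecule_id = sort(as.integer(members)),
    role = cache$role[vapply(sort(as.integer(members)),
                             function(id) mol_rows(cache, id)[1], integer(1))])
}

#' Partition all ions of a frame into clusters
#'
#' Repeats [grow_cluster()] over reference ions in the given order, skipping
#' ions already assigned, until every ion belongs to exactly one cluster.
#' The resulting size distribution is insensitive to the reference order;
#' the default ascending-id order makes runs deterministic, and a seeded
#' random order is available to exercise that insensitivity.
#'
#' @param frame An [md_frame()].
#' @param spec A [shell_spec()].
#' @param order `"index"` (ascending molecule id), `"random"` (seeded
#'   shuffle), or an explicit integer permutation of the frame's ion ids.
#' @param seed Seed for `order = "random"`.
#' @param frame_index Optional integer recorded on the result.
#' @return A `cluster_partition`: tibble with columns `molecule_id`, `role`,
#'   `cluster` (1-based cluster labels in discovery order), carrying
#'   attributes `frame_index` and `n_ions`.
#' @export
partition_frame <- function(frame, spec = shell_spec(), order = "index",
                            seed = NULL, frame_index = NA_integer_) {
  ions <- ion_molecules(frame)
  if (length(ions) == 0) stop("frame contains no ions", call. = FALSE)
  if (is.numeric(order)) {
    order <- as.integer(order)
    if (!setequal(order, ions) || length(order) != length(ions)) {
      stop("explicit order must be a permutation of the frame's ion ids",
           call. = FALSE)
    }
    sequence <- order
  } else if (identical(order, "index")) {
    sequence <- ions
  } else if (identical(order, "random")) {
    sequence <- with_local_seed(seed, sample(ions))
  } else {
    stop("order must be \"index\", \"random\" or an id permutation",
         call. = FALSE)
  }

  cache <- frame_cache(frame)
  assigned <- integer()
  label <- integer()
  member_of <- integer()
  k <- 0L
  for (ref in sequence) {
    if (ref %in% assigned) next
    cl <- grow_cluster_impl(cache, frame, ref, spec, excluded = assigned)
    k <- k + 1L
    assigned <- c(assigned, cl$molecule_id)
    member_of <- c(member_of, cl$molecule_id)
    label <- c(label, rep(k, nrow(cl)))
  }
  if (!setequal(assigned, ions)) {
    stop("internal error: partition does not cover all ions", call. = FALSE)
  }
  ord <- order(member_of)
  out <- tibble::tibble(
    molecule_id = member_of[ord],
    role = cache$role[vapply(member_of[ord],
                             function(id) mol_rows(cache, id)[1], integer(1))],
    cluster = label[ord])
  attr(out, "frame_index") <- frame_index
  attr(out, "n_ions") <- length(ions)
  class(out) <- c("cluster_partition", class(out))
  out
}

#' Partition every frame of a trajectory
#'
#' @param frames List of [md_frame()] objects (e.g. from [read_frames()]).
#' @param spec A [shell_spec()].
#' @param order,seed Passed to [partition_frame()].
#' @param stride Analyse every `stride`-th frame.
#' @return Tibble with columns `frame`, `molecule_id`, `role`, `cluster`,
#'   one row per ion per analysed frame; attribute `n_ions`.
#' @export
partition_trajectory <- function(frames, spec = shell_spec(), order = "index",
                                 seed = NULL, stride = 1L) {
  idx <- seq(1, length(frames), by = as.integer(stride))
  parts <- lapply(idx, function(i) {
    p <- partition_frame(frames[[i]], spec, order = order, seed = seed,
                         frame_index = i)
    p$frame <- i
    p
  })
  out <- dplyr::bind_rows(lapply(parts, function(p) {
    tibble::as_tibble(p)[, c("frame", "molecule_id", "role", "cluster")]
  }))
  attr(out, "n_ions") <- attr(parts[[1]], "n_ions")
  out
}

#' Brute-force contact-graph reference partition
#'
#' Independent reference used to validate the shell-expansion detector:
#' build a graph on ion molecules with an edge when (i) the minimum
#' interatomic distance is at most `contact_threshold` and (ii) no solvent
#' atom lies within `blocking_radius` of the segment joining the closest
#' atom pair (the "closest approach not obstructed by solvent" picture);
#' connected components are the clusters.
#'
#' @param frame An [md_frame()].
#' @param contact_threshold Contact distance, nm (default 0.3).
#' @param blocking_radius Solvent obstruction radius around the
#'   closest-approach segment, nm (default 0.15).
#' @param frame_index Optional integer recorded on the result.
#' @return A `cluster_partition` tibble, same shape as [partition_frame()].
#' @export
contact_graph_oracle <- function(frame, contact_threshold = 0.3,
                                 blocking_radius = 0.15,
                                 frame_index = NA_integer_) {
  cache <- frame_cache(frame)
  ions <- ion_molecules(frame)
  solvent_pos <- cache$pos[!cache$is_ion, , drop = FALSE]
  edges <- matrix(integer(), ncol = 2)
  if (length(ions) > 1) {
    pairs <- utils::combn(ions, 2)
    keep <- apply(pairs, 2, function(pr) {
      a <- cache$pos[mol_rows(cache, pr[1]), , drop = FALSE]
      b <- cache$pos[mol_rows(cache, pr[2]), , drop = FALSE]
      mp <- min_pair_dist(a, b, cache$box)
      if (mp$dist > contact_threshold) return(FALSE)
      if (nrow(solvent_pos) == 0) return(TRUE)
      # segment from the closest atom of a towards its image of b's atom
      p0 <- a[mp$i, ]
      seg <- -mp$dvec  # displacement a -> b under minimum image
      rel <- minimum_image(sweep(solvent_pos, 2, p0), cache$box)
      L2 <- sum(seg^2)
      t <- if (L2 > 0) pmin(pmax((rel %*% seg) / L2, 0), 1) else rep(0, nrow(rel))
      closest <- rel - outer(as.numeric(t), seg)
      min(sqrt(rowSums(closest^2))) > blocking_radius
    })
    edges <- t(pairs[, keep, drop = FALSE])
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1]),
                   to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(ions)))
  comp <- igraph::components(g)$membership
  # relabel components in order of their smallest member id for determinism
  first_seen <- order(vapply(split(ions, comp[as.character(ions)]), min,
                             numeric(1)))
  relabel <- match(comp[as.character(ions)],
                   as.integer(names(split(ions, comp[as.character(ions)]))[first_seen]))
  out <- tibble::tibble(
    molecule_id = ions,
    role = vapply(ions, function(id) cache$role[mol_rows(cache, id)[1]],
                  character(1)),
    cluster = as.integer(relabel))
  attr(out, "frame_index") <- frame_index
  attr(out, "n_ions") <- length(ions)
  class(out) <- c("cluster_partition", class(out))
  out
}

#' Cluster sizes and charge compositions of a partition
#'
#' @param partition A `cluster_partition` tibble (or any tibble with
#'   `cluster` and `role` columns; with a `frame` column, sizes are computed
#'   per frame).
#' @return Tibble with one row per cluster: `cluster`, `size`, `n_cations`,
#'   `n_anions` (and `frame` when present).
#' @export
cluster_sizes <- function(partition) {
  grp <- intersect(c("frame", "cluster"), names(partition))
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(partition),
                    dplyr::across(dplyr::all_of(grp))),
    size = dplyr::n(),
    n_cations = sum(.data$role == "cation"),
    n_anions = sum(.data$role == "anion"),
    .groups = "drop")
}

#' Multiset of cluster sizes in a partition
#' @param partition A `cluster_partition` tibble.
#' @return Sorted integer vector of cluster sizes.
#' @export
size_multiset <- function(partition) {
  sort(as.integer(table(partition$cluster)))
}
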