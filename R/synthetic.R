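# Synthetic fixtures with exact ground truth.
#
# Planted frames place rigid few-atom "ions" in contact chains (consecutive
# nearest-atom distance = intra_contact, well below the 0.3 nm contact
# threshold) separated by gaps far above it, with single-atom solvent kept
# outside a skin around every ion and one solvent blocker guaranteed between
# each pair of clusters. Detection on such frames has a single unambiguous
# answer, so the planted partition is a true oracle. Chemical realism
# (electrostatics, solvation shells) is deliberately absent: the detector
# depends on geometry only.

TEMPLATE_R <- 0.08 # nm, atom offset radius of the rigid ion template

# Rigid ion template: first atom at the centroid, remaining atoms at fixed
# offsets of radius TEMPLATE_R. Deterministic for any atom count.
ion_template <- function(n_atoms) {
  stopifnot(n_atoms >= 1)
  base <- rbind(c(0, 0, 0),
                c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  if (n_atoms <= nrow(base)) return(TEMPLATE_R * base[seq_len(n_atoms), , drop = FALSE])
  extra <- n_atoms - nrow(base)
  i <- seq_len(extra)
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi
  z <- 1 - (2 * i - 1) / extra
  r <- sqrt(pmax(1 - z^2, 0))
  TEMPLATE_R * rbind(base, cbind(r * cos(theta), r * sin(theta), z))
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Specification of a planted-cluster frame
#'
#' @param sizes Integer multiset of cluster sizes to plant; must sum to
#'   `n_cations + n_anions`.
#' @param n_cations,n_anions Ion counts (defaults 22 and 22, the composition
#'   of the salt-solution systems this generator emulates).
#' @param atoms_per_ion Atoms in the rigid ion template (default 5).
#' @param intra_contact Nearest-atom distance between consecutive ions of a
#'   planted cluster, nm (default 0.25; must not exceed the 0.3 nm contact
#'   threshold for the plant to be its own ground truth).
#' @param inter_gap Minimum interatomic distance between distinct clusters,
#'   nm (default 1.2, several times the contact threshold).
#' @param solvent_density Bulk solvent number density, per nm^3 (default
#'   0.05; solvent here is a sparse single-atom placeholder whose only job
#'   is to occupy shells and obstruct inter-cluster space).
#' @param solvent_skin Exclusion distance of solvent from any ion atom, nm
#'   (default 0.35).
#' @param box Orthorhombic box lengths, nm (default 12 x 12 x 12).
#' @param n_solvent Exact total solvent-atom count (blockers included). The
#'   default `NULL` derives the count from `solvent_density` plus one
#'   blocker per cluster pair; an explicit value keeps the atom count
#'   constant across frames of a multi-frame trajectory.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return Object of class `planted_spec`.
#' @export
planted_spec <- function(sizes, n_cations = 22L, n_anions = 22L,
                         atoms_per_ion = 5L, intra_contact = 0.25,
                         inter_gap = 1.2, solvent_density = 0.05,
                         solvent_skin = 0.35, box = c(12, 12, 12),
                         n_solvent = NULL, seed = 1L) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1, all(sizes >= 1))
  if (sum(sizes) != n_cations + n_anions) {
    stop("sum(sizes) = ", sum(sizes), " must equal n_cations + n_anions = ",
         n_cations + n_anions, call. = FALSE)
  }
  stopifnot(intra_contact > 0, inter_gap > 0, solvent_skin >= 0,
            atoms_per_ion >= 1, length(box) == 3, all(box > 0))
  if (intra_contact > 0.3) {
    stop("intra_contact must not exceed the 0.3 nm contact threshold",
         call. = FALSE)
  }
  if (inter_gap <= 2 * 0.3) {
    stop("inter_gap must exceed twice the 0.3 nm contact threshold",
         call. = FALSE)
  }
  structure(list(sizes = sizes, n_cations = as.integer(n_cations),
                 n_anions = as.integer(n_anions),
                 atoms_per_ion = as.integer(atoms_per_ion),
                 intra_contact = intra_contact, inter_gap = inter_gap,
                 solvent_density = solvent_density,
                 solvent_skin = solvent_skin, box = as.numeric(box),
                 n_solvent = if (is.null(n_solvent)) NULL else as.integer(n_solvent),
                 seed = as.integer(seed)),
            class = "planted_spec")
}

# Alternate cation/anion along each chain, drawing from the remaining global
# pools; if one pool empties the other fills in (geometry is unaffected).
assign_roles <- function(sizes, n_cations, n_anions) {
  remaining <- c(cation = n_cations, anion = n_anions)
  roles <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    m <- sizes[ci]
    cur <- names(remaining)[which.max(remaining)]
    out <- character(m)
    for (j in seq_len(m)) {
      if (remaining[[cur]] == 0) cur <- setdiff(names(remaining), cur)
      out[j] <- cur
      remaining[[cur]] <- remaining[[cur]] - 1L
      cur <- setdiff(names(remaining), cur)
    }
    roles[[ci]] <- out
  }
  roles
}

#' Generate a planted-cluster frame with exact ground truth
#'
#' Clusters are straight contact chains of rigid template ions, randomly
#' oriented and placed so that any two clusters are at least `inter_gap`
#' apart (atom to atom, minimum image). Solvent atoms are scattered at the
#' bulk density outside a `solvent_skin` of every ion atom, and one extra
#' solvent blocker is placed between each pair of clusters along their
#' closest-approach segment. All planted constraints are re-verified by
#' direct distance computation before the frame is returned.
#'
#' @param spec A [planted_spec()].
#' @return List with `frame` (an [md_frame()]) and `truth` (a
#'   `cluster_partition` tibble with the planted assignment).
#' @export
plant_frame <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  with_local_seed(spec$seed, plant_frame_impl(spec))
}

plant_frame_impl <- function(spec) {
  tmpl <- ion_template(spec$atoms_per_ion)
  xmax <- max(tmpl[, 1]); xmin <- min(tmpl[, 1])
  spacing <- spec$intra_contact + xmax - xmin
  sizes <- spec$sizes
  radii <- (sizes - 1) * spacing / 2 + TEMPLATE_R + 1e-6

  # feasibility: the largest exclusion diameter must fit the half box
  need <- 2 * max(radii) + spec$inter_gap
  if (need >= min(spec$box) / 2) {
    stop("box too small: largest cluster + inter_gap (", signif(need, 3),
         " nm) exceeds half the box", call. = FALSE)
  }

  # place cluster centroids by rejection
  centers <- matrix(NA_real_, length(sizes), 3)
  for (ci in seq_along(sizes)) {
    ok <- FALSE
    for (attempt in seq_len(5000)) {
      cand <- runif(3) * spec$box
      if (ci == 1) { ok <- TRUE; break }
      prev <- centers[seq_len(ci - 1), , drop = FALSE]
      d <- sqrt(rowSums(minimum_image(sweep(prev, 2, cand), spec$box)^2))
      if (all(d >= spec$inter_gap + radii[ci] + radii[seq_len(ci - 1)])) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("could not place cluster ", ci,
           " at inter_gap = ", spec$inter_gap,
           " nm after 5000 attempts; enlarge the box", call. = FALSE)
    }
    centers[ci, ] <- cand
  }

  roles <- assign_roles(sizes, spec$n_cations, spec$n_anions)

  ion_rows <- list()
  mol_id <- 0L
  for (ci in seq_along(sizes)) {
    m <- sizes[ci]
    chain_x <- (seq_len(m) - 1) * spacing
    chain_x <- chain_x - mean(chain_x)
    R <- random_rotation()
    for (j in seq_len(m)) {
      mol_id <- mol_id + 1L
      local <- sweep(tmpl, 2, c(chain_x[j], 0, 0), "+")
      pos <- sweep(local %*% t(R), 2, centers[ci, ], "+")
      ion_rows[[mol_id]] <- tibble::tibble(
        molecule_id = mol_id, role = roles[[ci]][j], cluster = ci,
        name = paste0("X", seq_len(nrow(tmpl))),
        x = pos[, 1], y = pos[, 2], z = pos[, 3])
    }
  }
  ions <- dplyr::bind_rows(ion_rows)
  ion_pos <- as.matrix(ions[, c("x", "y", "z")])
  n_ions <- mol_id

  clear_of_ions <- function(p) {
    d <- minimum_image(sweep(ion_pos, 2, p), spec$box)
    min(sqrt(rowSums(d^2))) > spec$solvent_skin
  }

  # one guaranteed blocker between every pair of clusters
  solvent_pos <- list()
  if (length(sizes) > 1) {
    for (a in seq_len(length(sizes) - 1)) {
      for (b in (a + 1):length(sizes)) {
        pa <- ion_pos[ions$cluster == a, , drop = FALSE]
        pb <- ion_pos[ions$cluster == b, , drop = FALSE]
        mp <- min_pair_dist(pa, pb, spec$box)
        p0 <- pa[mp$i, ]
        seg <- -mp$dvec
        for (t in c(0.5, 0.4, 0.6, 0.3, 0.7, 0.25, 0.75)) {
          cand <- p0 + t * seg
          if (clear_of_ions(cand)) {
            solvent_pos[[length(solvent_pos) + 1L]] <- cand
            break
          }
        }
      }
    }
  }

  # bulk solvent: fill to the exact total when one is requested, otherwise
  # use the bulk density on top of the blockers
  n_blockers <- length(solvent_pos)
  if (!is.null(spec$n_solvent)) {
    if (spec$n_solvent < n_blockers) {
      stop("n_solvent = ", spec$n_solvent, " is below the ", n_blockers,
           " blockers needed between cluster pairs", call. = FALSE)
    }
    n_bulk <- spec$n_solvent - n_blockers
  } else {
    n_bulk <- round(spec$solvent_density * prod(spec$box))
  }
  placed <- 0L
  attempts <- 0L
  while (placed < n_bulk && attempts < 200L * max(n_bulk, 1L)) {
    attempts <- attempts + 1L
    cand <- runif(3) * spec$box
    if (clear_of_ions(cand)) {
      solvent_pos[[length(solvent_pos) + 1L]] <- cand
      placed <- placed + 1L
    }
  }
  if (placed < n_bulk) {
    stop("could not place bulk solvent outside the solvent_skin; ",
         "lower solvent_density or enlarge the box", call. = FALSE)
  }

  atoms <- ions[, c("molecule_id", "role", "name", "x", "y", "z")]
  if (length(solvent_pos) > 0) {
    sp <- do.call(rbind, solvent_pos)
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      molecule_id = n_ions + seq_len(nrow(sp)), role = "solvent",
      name = "OW", x = sp[, 1], y = sp[, 2], z = sp[, 3]))
  }
  # wrap into the primary box; md_frame re-unwraps molecules
  atoms$x <- atoms$x %% spec$box[1]
  atoms$y <- atoms$y %% spec$box[2]
  atoms$z <- atoms$z %% spec$box[3]
  atoms <- tibble::add_column(atoms, atom_id = seq_len(nrow(atoms)),
                              .before = 1)
  frame <- md_frame(atoms, spec$box)

  truth <- dplyr::distinct(ions[, c("molecule_id", "role", "cluster")])
  attr(truth, "n_ions") <- n_ions
  class(truth) <- c("cluster_partition", class(truth))

  validate_plant(frame, truth, spec)
  list(frame = frame, truth = truth)
}

# Re-verify every planted constraint by direct distance computation.
validate_plant <- function(frame, truth, spec) {
  cache <- frame_cache(frame)
  by_cluster <- split(truth$molecule_id, truth$cluster)
  for (members in by_cluster) {
    if (length(members) < 2) next
    for (j in seq_len(length(members) - 1)) {
      d <- min_pair_dist(cache$pos[mol_rows(cache, members[j]), , drop = FALSE],
                         cache$pos[mol_rows(cache, members[j + 1]), , drop = FALSE],
                         cache$box)$dist
      if (d > spec$intra_contact + 1e-9) {
        stop("planted frame invalid: intra-cluster contact ", signif(d, 4),
             " nm exceeds intra_contact", call. = FALSE)
      }
    }
  }
  if (length(by_cluster) > 1) {
    ids <- names(by_cluster)
    for (a in seq_len(length(ids) - 1)) {
      for (b in (a + 1):length(ids)) {
        ra <- unlist(lapply(by_cluster[[a]], function(id) mol_rows(cache, id)))
        rb <- unlist(lapply(by_cluster[[b]], function(id) mol_rows(cache, id)))
        d <- min_pair_dist(cache$pos[ra, , drop = FALSE],
                           cache$pos[rb, , drop = FALSE], cache$box)$dist
        if (d < spec$inter_gap - 1e-9) {
          stop("planted frame invalid: inter-cluster gap ", signif(d, 4),
               " nm below inter_gap", call. = FALSE)
        }
      }
    }
  }
  solv <- which(!cache$is_ion)
  if (length(solv) > 0) {
    d <- min_pair_dist(cache$pos[solv, , drop = FALSE],
                       cache$pos[cache$is_ion, , drop = FALSE],
                       cache$box)$dist
    if (d <= spec$solvent_skin - 1e-9) {
      stop("planted frame invalid: solvent inside the solvent_skin",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Specification of a synthetic state-vector series
#'
#' @param n_frames Number of frames to generate.
#' @param s_max Number of size classes (default 4).
#' @param base Mean state vector, length `s_max`, non-negative, summing
#'   to 1. Default `c(0.5, 0.25, 0.15, 0.10)`: about half the ions free,
#'   the rest mostly in dimers and trimers, as is typical of weakly
#'   associating salt solutions.
#' @param modes `s_max` x m matrix of fluctuation-mode vectors (columns);
#'   each column must sum to zero so the normalization
#'   `sum_i i n_i = 1` is preserved. Defaults: monomer/dimer
#'   anticorrelation `(1,-1,0,0)/sqrt(2)` and small-vs-large
#'   `(1,1,-1,-1)/2`.
#' @param amplitudes Standard deviation of each mode's coefficient.
#' @param noise Isotropic noise scale; noise is projected onto the
#'   zero-sum subspace so it also preserves normalization.
#' @param n_ions Nominal ion count attached to the series for count-unit
#'   views (default 44).
#' @param seed Integer seed.
#' @return Object of class `series_spec`.
#' @export
series_spec <- function(n_frames, s_max = 4L,
                        base = c(0.5, 0.25, 0.15, 0.10),
                        modes = cbind(c(1, -1, 0, 0) / sqrt(2),
                                      c(1, 1, -1, -1) / 2),
                        amplitudes = c(0.06, 0.03),
                        noise = 0.005, n_ions = 44L, seed = 1L) {
  s_max <- as.integer(s_max)
  modes <- as.matrix(modes)
  stopifnot(n_frames >= 1, length(base) == s_max, all(base >= 0),
            nrow(modes) == s_max, length(amplitudes) == ncol(modes),
            all(amplitudes >= 0), noise >= 0)
  if (abs(sum(base) - 1) > 1e-10) {
    stop("base state vector must sum to 1", call. = FALSE)
  }
  if (any(abs(colSums(modes)) > 1e-8)) {
    stop("every mode must sum to zero (preserve sum_i i*n_i = 1)",
         call. = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames), s_max = s_max,
                 base = base, modes = modes, amplitudes = amplitudes,
                 noise = noise, n_ions = as.integer(n_ions),
                 seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a state-vector series with known covariance
#'
#' Each frame's vector is `base + modes %*% (amplitudes * z) + e`, with `z`
#' standard normal and `e` isotropic noise projected onto the zero-sum
#' subspace; frames with any negative component are resampled (rare under
#' the default scales, and documented as a mild truncation of the
#' covariance). The analytic covariance implied by the amplitudes,
#' `M diag(a^2) M' + noise^2 (I - 11'/S)`, is returned for recovery tests.
#'
#' @param spec A [series_spec()].
#' @return List with `series` (long population-series tibble),
#'   `covariance` (analytic), `modes` and `amplitudes`.
#' @export
plant_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_frames
    S <- spec$s_max
    M <- spec$modes
    a <- spec$amplitudes
    Ma <- sweep(M, 2, a, "*")
    draw_row <- function() {
      for (try in seq_len(1000)) {
        z <- rnorm(ncol(M))
        e <- rnorm(S, sd = spec$noise)
        e <- e - mean(e)
        v <- spec$base + drop(M %*% (a * z)) + e
        if (all(v >= 0)) return(v)
      }
      stop("could not draw a non-negative state vector in 1000 tries; ",
           "reduce amplitudes or noise", call. = FALSE)
    }
    V <- t(vapply(seq_len(n), function(k) draw_row(), numeric(S)))
    series <- tibble::tibble(
      frame = rep(seq_len(n), each = S),
      class = rep(as.character(seq_len(S)), n),
      size = rep(seq_len(S), n),
      n_clusters = NA_integer_,
      component = as.numeric(t(V)))
    attr(series, "n_ions") <- spec$n_ions
    attr(series, "s_max") <- S
    class(series) <- c("population_series", class(series))
    C_true <- Ma %*% t(Ma) +
      spec$noise^2 * (diag(S) - matrix(1 / S, S, S))
    list(series = series, covariance = C_true, modes = M, amplitudes = a)
  })
}

#' Generate a toy trajectory of interconverting clusters
#'
#' Markov re-planting: the cluster-size multiset evolves frame to frame --
#' with probability `hop_rate` an ion either detaches from a cluster or a
#' free ion joins one -- and each frame's geometry is re-planted from the
#' current multiset. The full detection -> populations -> PCA chain can be
#' run against the evolving ground truth.
#'
#' @param spec A [planted_spec()] giving the initial sizes, composition and
#'   geometry constraints.
#' @param n_frames Number of frames.
#' @param hop_rate Per-frame probability of a detach/join move, in `[0, 1]`.
#' @param seed Integer seed (controls both the Markov moves and the
#'   per-frame geometry).
#' @return List with `frames` (list of [md_frame()]), `truth` (long tibble
#'   `frame`, `molecule_id`, `role`, `cluster` with attribute `n_ions`),
#'   and `sizes_history` (list of per-frame size multisets).
#' @export
toy_trajectory <- function(spec, n_frames, hop_rate, seed = 1L) {
  stopifnot(inherits(spec, "planted_spec"), hop_rate >= 0, hop_rate <= 1,
            n_frames >= 1)
  with_local_seed(seed, {
    frame_seeds <- sample.int(.Machine$integer.max - 1L, n_frames)
    sizes <- spec$sizes
    if (is.null(spec$n_solvent)) {
      # constant atom count across frames: bulk density plus the worst-case
      # blocker count (one per cluster pair when every ion is free)
      n_ions_tot <- sum(spec$sizes)
      spec$n_solvent <- as.integer(round(spec$solvent_density * prod(spec$box)) +
                                     choose(n_ions_tot, 2))
    }
    frames <- vector("list", n_frames)
    truths <- vector("list", n_frames)
    history <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      spec_i <- spec
      spec_i$sizes <- sizes
      spec_i$seed <- frame_seeds[i]
      pf <- plant_frame(spec_i)
      pf$truth$frame <- i
      frames[[i]] <- pf$frame
      truths[[i]] <- tibble::as_tibble(pf$truth)
      history[[i]] <- sort(sizes)
      if (runif(1) < hop_rate) {
        can_detach <- any(sizes >= 2)
        can_join <- sum(sizes == 1) >= 1 && length(sizes) >= 2
        move <- if (can_detach && can_join) {
          sample(c("detach", "join"), 1)
        } else if (can_detach) "detach" else if (can_join) "join" else NA
        pick1 <- function(x) x[sample.int(length(x), 1)]
        if (identical(move, "detach")) {
          j <- pick1(which(sizes >= 2))
          sizes[j] <- sizes[j] - 1L
          sizes <- c(sizes, 1L)
        } else if (identical(move, "join")) {
          mono <- pick1(which(sizes == 1))
          k <- pick1(setdiff(seq_along(sizes), mono))
          sizes[k] <- sizes[k] + 1L
          sizes <- sizes[-mono]
        }
      }
    }
    truth <- dplyr::bind_rows(truths)[, c("frame", "molecule_id", "role",
                                          "cluster")]
    attr(truth, "n_ions") <- sum(spec$sizes)
    list(frames = frames, truth = truth, sizes_history = history)
  })
}
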