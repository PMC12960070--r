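# Small in-code fixtures shared across test files.

# Frame with atoms at explicit positions; one atom per molecule unless
# molecule ids are given.
toy_frame <- function(pos, roles, molecule_id = NULL, box = c(10, 10, 10)) {
  pos <- rbind(pos)
  if (is.null(molecule_id)) molecule_id <- seq_len(nrow(pos))
  md_frame(tibble::tibble(
    atom_id = seq_len(nrow(pos)),
    molecule_id = molecule_id,
    role = roles,
    x = pos[, 1], y = pos[, 2], z = pos[, 3]), box = box)
}

# Draw a cluster-size multiset summing to n_ions with sizes in 1..max_size.
draw_sizes <- function(n_ions, max_size = 4L) {
  sizes <- integer()
  remaining <- n_ions
  while (remaining > 0) {
    s <- sample.int(min(max_size, remaining), 1)
    sizes <- c(sizes, s)
    remaining <- remaining - s
  }
  sizes
}

# Default-geometry planted spec for n cations + n anions.
planted_44 <- function(seed, sizes = NULL, box = c(12, 12, 12)) {
  if (is.null(sizes)) sizes <- withr::with_seed(seed, draw_sizes(44L))
  planted_spec(sizes = sizes, n_cations = 22L, n_anions = 22L,
               box = box, seed = seed)
}

angle_deg <- function(u, v) {
  cosang <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, cosang)) * 180 / pi
}

# Direct recount of state-vector components from a partition.
histogram_oracle <- function(partition, n_ions, s_max) {
  sizes <- as.integer(table(partition$cluster))
  comp <- vapply(seq_len(s_max),
                 function(i) i * sum(sizes == i) / n_ions, numeric(1))
  c(comp, sum(sizes[sizes > s_max]) / n_ions)
}

# Naive double-loop covariance of the i*n_i components, divisor N_frames.
covariance_oracle <- function(mat) {
  n <- nrow(mat); S <- ncol(mat)
  mu <- colMeans(mat)
  C <- matrix(0, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + (mat[k, i] - mu[i]) * (mat[k, j] - mu[j])
      C[i, j] <- acc / n
    }
  }
  C
}
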