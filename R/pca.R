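# Principal component analysis of cluster-population fluctuations.
#
# The covariance of the state-vector components i*n_i over frames,
#
#   C_ij = (1/N_frames) * sum_k (i n_{i,k} - <i n_i>) (j n_{j,k} - <j n_j>),
#
# is diagonalized; eigenvectors are the principal modes of population
# fluctuation (e.g. monomer/dimer anticorrelation = association/dissociation
# of ion pairs) and eigenvalue fractions are the variance each mode carries.
# Components are truncated to sizes 1..S_max before centering, without
# renormalization: larger clusters are neglected, and renormalizing would
# distort the fluctuations of the retained classes.

#' Population covariance matrix of a state-vector series
#'
#' @param series A population series ([state_vector_series()] or
#'   [plant_series()]).
#' @param s_max Truncation: only size classes 1..`s_max` enter (default 4).
#'   Overflow and larger classes are dropped before centering and never
#'   renormalized.
#' @return `s_max` x `s_max` symmetric matrix; the divisor is the frame
#'   count N_frames (not N_frames - 1).
#' @export
population_covariance <- function(series, s_max = 4L) {
  x <- series_matrix(series, s_max = s_max)
  if (nrow(x) < 2) stop("need at least 2 frames for a covariance", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  C <- crossprod(xc) / nrow(x)
  dimnames(C) <- list(colnames(x), colnames(x))
  C
}

#' Eigen-decomposition of a population covariance matrix
#'
#' Symmetric eigen-decomposition with eigenvalues sorted descending. The
#' sign of each eigenvector is fixed by making its largest-magnitude
#' component positive (magnitude ties resolved towards the smallest size
#' class), so reported mode compositions are reproducible across
#' linear-algebra backends.
#'
#' @param C Symmetric covariance matrix (from [population_covariance()]).
#' @param n_frames Optional frame count to record on the result.
#' @return Object of class `pop_pca`: list with `covariance`, `eigenvalues`
#'   (descending), `eigenvectors` (orthonormal columns), and
#'   `variance_fractions` (eigenvalue / trace).
#' @export
pca_decompose <- function(C, n_frames = NA_integer_) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8) {
    stop("covariance matrix must be symmetric", call. = FALSE)
  }
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    a <- abs(vecs[, j])
    # ties in magnitude resolved towards the lowest size class
    k <- which(a >= max(a) * (1 - 1e-9))[1]
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  tr <- sum(diag(C))
  structure(list(
    covariance = C,
    eigenvalues = eig$values,
    eigenvectors = vecs,
    variance_fractions = if (tr > 0) eig$values / tr else rep(NA_real_, nrow(C)),
    n_frames = n_frames,
    s_max = nrow(C)), class = "pop_pca")
}

#' PCA of a cluster-population time series
#'
#' Convenience wrapper: [population_covariance()] followed by
#' [pca_decompose()].
#'
#' @inheritParams population_covariance
#' @return A `pop_pca` object.
#' @export
pop_pca <- function(series, s_max = 4L) {
  C <- population_covariance(series, s_max = s_max)
  pca_decompose(C, n_frames = length(unique(series$frame)))
}

#' @export
print.pop_pca <- function(x, ...) {
  cat(sprintf("<pop_pca> %d cluster classes, %s frames\n", x$s_max,
              ifelse(is.na(x$n_frames), "?", x$n_frames)))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  if (!anyNA(x$variance_fractions)) {
    cat("  variance fractions:",
        paste(sprintf("%.1f%%", 100 * x$variance_fractions), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Human-readable description of a fluctuation mode's sign pattern.
# Components below a relative tolerance are treated as zero.
classify_mode <- function(v, tol = 1e-8) {
  s <- sign(v)
  s[abs(v) <= tol * max(abs(v), tol)] <- 0
  if (length(v) >= 4 && s[1] != 0 && s[1] == s[2] &&
      s[3] != 0 && s[3] == s[4] && s[1] == -s[3]) {
    return("monomer-dimer vs trimer-tetramer anticorrelation")
  }
  if (length(v) >= 2 && s[1] != 0 && s[2] != 0 && s[1] == -s[2]) {
    return("monomer-dimer anticorrelation")
  }
  "mixed"
}

#' Composition report of the leading fluctuation modes
#'
#' @param r A `pop_pca` object.
#' @param k Number of leading modes to report (default 2).
#' @return List with `loadings` (tibble: `mode`, `size`, `loading`,
#'   `eigenvalue`, `variance_fraction`, `pattern`), and
#'   `cumulative_variance` (fraction carried by the first `k` modes).
#' @export
mode_report <- function(r, k = 2L) {
  k <- as.integer(k)
  stopifnot(k >= 1, k <= r$s_max)
  loadings <- dplyr::bind_rows(lapply(seq_len(k), function(m) {
    v <- r$eigenvectors[, m]
    tibble::tibble(
      mode = m, size = seq_len(r$s_max), loading = v,
      eigenvalue = r$eigenvalues[m],
      variance_fraction = r$variance_fractions[m],
      pattern = classify_mode(v))
  }))
  list(loadings = loadings,
       cumulative_variance = sum(r$variance_fractions[seq_len(k)]))
}

#' @method tidy pop_pca
#' @export
tidy.pop_pca <- function(x, ...) {
  mode_report(x, k = x$s_max)$loadings
}

#' @method glance pop_pca
#' @export
glance.pop_pca <- function(x, ...) {
  vf <- x$variance_fractions
  tibble::tibble(
    n_classes = x$s_max,
    n_frames = x$n_frames,
    total_variance = sum(diag(x$covariance)),
    var_mode1 = vf[1],
    var_mode2 = if (length(vf) >= 2) vf[2] else NA_real_,
    cum_var_2 = if (length(vf) >= 2) vf[1] + vf[2] else vf[1])
}

#' Plot the composition of the leading PCA modes
#'
#' Bar chart of signed eigenvector components per cluster size, faceted by
#' mode and annotated with each mode's variance fraction.
#'
#' @param object A `pop_pca` object.
#' @param k Number of modes to show (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pop_pca
#' @export
autoplot.pop_pca <- function(object, k = 2L, ...) {
  rep <- mode_report(object, k = k)
  dat <- rep$loadings
  dat$panel <- sprintf("mode %d (%.1f%% variance)", dat$mode,
                       100 * dat$variance_fraction)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$size),
                                    y = .data$loading,
                                    fill = .data$loading > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = "cluster size", y = "eigenvector component") +
    ggplot2::theme_minimal()
}
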