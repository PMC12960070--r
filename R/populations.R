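# Cluster-size population state vectors and their summary statistics.
#
# For a frame with N ions partitioned into clusters, n_i = c_i / N is the
# fraction of size-i clusters (c_i clusters of size i), and the state vector
# is v(n_1, 2 n_2, 3 n_3, ...): component i equals i * n_i, the fraction of
# ions residing in size-i clusters, so sum_i i*n_i = 1 identically. Clusters
# of identical size but different net charge (e.g. A2, AC, C2) are grouped
# into one cluster class X_i; a charge-resolved tally is kept separately so
# the effect of the grouping can be reported.

pop_classes <- function(s_max) c(as.character(seq_len(s_max)), "overflow")

#' Cluster-size state vector of one partition
#'
#' @param partition A `cluster_partition` tibble ([partition_frame()]).
#' @param n_ions Total ion count N; defaults to the partition's own count.
#' @param s_max Largest size reported as its own class (default 4; larger
#'   clusters are typically negligibly populated). Sizes above `s_max` are
#'   accumulated into the `overflow` class -- never dropped -- so the
#'   normalization `sum_i i*n_i + overflow = 1` stays exact.
#' @return Tibble with one row per class: `frame`, `class` (character,
#'   `"1"`..`"s_max"`, `"overflow"`), `size` (integer, `NA` for overflow),
#'   `n_clusters` (c_i), `component` (i * n_i). Attribute `n_ions`.
#' @examples
#' p <- tibble::tibble(molecule_id = 1:4,
#'                     role = rep(c("cation", "anion"), 2),
#'                     cluster = c(1, 1, 2, 3))
#' state_vector(p) # 2 monomers + 1 dimer: components 0.5, 0.5, 0, 0
#' @export
state_vector <- function(partition, n_ions = NULL, s_max = 4L) {
  s_max <- as.integer(s_max)
  stopifnot(s_max >= 1)
  sizes <- as.integer(table(partition$cluster))
  n_ions <- n_ions %||% nrow(partition)
  if (sum(sizes) != n_ions) {
    stop("inconsistent partition: cluster sizes sum to ", sum(sizes),
         " but n_ions = ", n_ions, call. = FALSE)
  }
  counts <- vapply(seq_len(s_max), function(i) sum(sizes == i), integer(1))
  over_sizes <- sizes[sizes > s_max]
  fi <- attr(partition, "frame_index") %||% NA_integer_
  out <- tibble::tibble(
    frame = fi,
    class = pop_classes(s_max),
    size = c(seq_len(s_max), NA_integer_),
    n_clusters = c(counts, length(over_sizes)),
    component = c(seq_len(s_max) * counts, sum(over_sizes)) / n_ions)
  attr(out, "n_ions") <- n_ions
  attr(out, "s_max") <- s_max
  class(out) <- c("population_series", class(out))
  out
}

#' State-vector time series of a partitioned trajectory
#'
#' @param partitions Output of [partition_trajectory()] (tibble with a
#'   `frame` column), or a list of `cluster_partition` objects.
#' @param n_ions Ion count; defaults to the per-frame count (must be
#'   constant across frames).
#' @param s_max Reporting cap as in [state_vector()].
#' @return Long tibble of per-frame state vectors (columns as in
#'   [state_vector()]); attributes `n_ions`, `s_max`.
#' @export
state_vector_series <- function(partitions, n_ions = NULL, s_max = 4L) {
  if (is.data.frame(partitions)) {
    stopifnot("frame" %in% names(partitions))
    parts <- split(tibble::as_tibble(partitions), partitions$frame)
    parts <- lapply(parts, function(p) {
      attr(p, "frame_index") <- p$frame[1]
      p
    })
  } else {
    parts <- partitions
  }
  rows <- lapply(seq_along(parts), function(k) {
    sv <- state_vector(parts[[k]], n_ions = n_ions, s_max = s_max)
    if (is.na(sv$frame[1])) sv$frame <- k
    sv
  })
  n_per <- vapply(rows, function(r) attr(r, "n_ions"), numeric(1))
  if (length(unique(n_per)) > 1) {
    stop("ion count varies across frames: ", paste(unique(n_per), collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  attr(out, "n_ions") <- n_per[1]
  attr(out, "s_max") <- s_max
  class(out) <- c("population_series", class(out))
  out
}

# frames x classes matrix of components (sizes 1..s_max, overflow excluded),
# rows in frame order
series_matrix <- function(series, s_max = NULL) {
  s_max <- s_max %||% attr(series, "s_max") %||%
    max(series$size, na.rm = TRUE)
  dat <- series[!is.na(series$size) & series$size <= s_max, ]
  wide <- tidyr::pivot_wider(
    dat[, c("frame", "size", "component")],
    names_from = "size", values_from = "component", values_fill = 0)
  wide <- wide[order(wide$frame), ]
  m <- as.matrix(wide[, as.character(seq_len(s_max)), drop = FALSE])
  rownames(m) <- wide$frame
  m
}

#' Charge-resolved cluster-class tally
#'
#' The state vector merges clusters of equal size regardless of charge
#' composition; this tally keeps them apart (e.g. for size 2: anion-anion,
#' cation-anion, cation-cation) so the impact of the merge can be inspected.
#' The per-size totals equal the merged class counts by construction.
#'
#' @param partitions Output of [partition_trajectory()] or a single
#'   partition.
#' @return Tibble with `size`, `n_cations`, `n_anions`, `n_frames_seen`,
#'   `mean_count` (mean number of such clusters per frame).
#' @export
charge_tally <- function(partitions) {
  cs <- cluster_sizes(partitions)
  n_frames <- if ("frame" %in% names(cs)) length(unique(cs$frame)) else 1L
  dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(cs, .data$size, .data$n_cations, .data$n_anions),
      n_frames_seen = if ("frame" %in% names(cs))
        length(unique(.data$frame)) else 1L,
      mean_count = dplyr::n() / n_frames,
      .groups = "drop"),
    .data$size, .data$n_cations)
}

#' Time-average a population series with block maximum-error bars
#'
#' The mean of each state-vector component over frames is reported with a
#' conservative "maximum error": the trajectory is cut into `n_blocks`
#' contiguous equal-length blocks (any remainder folded into the last
#' block) and the error bar is the largest absolute deviation of a block
#' mean from the global mean. This deliberately over-covers compared with a
#' standard error and is the uncertainty used throughout.
#'
#' @param series A population series ([state_vector_series()]).
#' @param n_blocks Number of blocks, >= 2 (default 5).
#' @return A `population_summary` tibble: `class`, `size`, `mean`,
#'   `max_error` (component units), `mean_ions`, `max_error_ions`
#'   (ion-count units, i.e. scaled by N); attributes `n_ions`, `n_frames`,
#'   `n_blocks`.
#' @export
summarize_populations <- function(series, n_blocks = 5L) {
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_blocks >= 2)
  frames <- sort(unique(series$frame))
  n <- length(frames)
  if (n == 0) stop("empty population series", call. = FALSE)
  if (n < n_blocks) {
    stop("need at least n_blocks = ", n_blocks, " frames, got ", n,
         call. = FALSE)
  }
  n_ions <- attr(series, "n_ions")
  base <- n %/% n_blocks
  block_of <- rep(seq_len(n_blocks), times = c(rep(base, n_blocks - 1),
                                               n - base * (n_blocks - 1)))
  block_lookup <- setNames(block_of, frames)

  dat <- tibble::as_tibble(series)
  dat$block <- block_lookup[as.character(dat$frame)]
  out <- dplyr::summarise(
    dplyr::group_by(dat, .data$class, .data$size),
    mean = mean(.data$component),
    max_error = {
      bm <- tapply(.data$component, .data$block, mean)
      max(abs(bm - mean(.data$component)))
    },
    .groups = "drop")
  out <- out[order(match(out$class, pop_classes(max(out$size, na.rm = TRUE)))), ]
  if (!is.null(n_ions)) {
    out$mean_ions <- n_ions * out$mean
    out$max_error_ions <- n_ions * out$max_error
  }
  attr(out, "n_ions") <- n_ions
  attr(out, "n_frames") <- n
  attr(out, "n_blocks") <- n_blocks
  class(out) <- c("population_summary", class(out))
  out
}

#' Population difference between two systems
#'
#' Componentwise difference of two summaries (a minus b), reported both in
#' state-vector units and in ion counts. Uncertainties are the sums of the
#' two maximum errors -- conservative, consistent with the maximum-error
#' semantics -- and a component is flagged significant when the absolute
#' difference exceeds its uncertainty.
#'
#' @param a,b `population_summary` objects with identical classes and ion
#'   counts.
#' @return A `population_difference` tibble: `class`, `size`, `diff`,
#'   `uncertainty`, `diff_ions`, `uncertainty_ions`, `significant`.
#' @export
population_difference <- function(a, b) {
  if (!identical(a$class, b$class)) {
    stop("summaries have different cluster classes (unequal s_max?)",
         call. = FALSE)
  }
  na <- attr(a, "n_ions"); nb <- attr(b, "n_ions")
  if (!is.null(na) && !is.null(nb) && na != nb) {
    stop("summaries refer to different ion counts (", na, " vs ", nb, ")",
         call. = FALSE)
  }
  out <- tibble::tibble(
    class = a$class, size = a$size,
    diff = a$mean - b$mean,
    uncertainty = a$max_error + b$max_error,
    diff_ions = a$mean_ions - b$mean_ions,
    uncertainty_ions = a$max_error_ions + b$max_error_ions,
    significant = abs(a$mean - b$mean) > (a$max_error + b$max_error))
  attr(out, "n_ions") <- na %||% nb
  class(out) <- c("population_difference", class(out))
  out
}

#' Plot a cluster-size population summary
#'
#' Bar chart of the mean number of ions per cluster class with maximum-error
#' bars.
#'
#' @param object A `population_summary`.
#' @param units `"ions"` (mean ion counts) or `"fraction"` (state-vector
#'   components).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_summary
#' @export
autoplot.population_summary <- function(object, units = c("ions", "fraction"),
                                        ...) {
  units <- match.arg(units)
  dat <- tibble::as_tibble(object)
  dat$class <- factor(dat$class, levels = unique(dat$class))
  if (units == "ions" && "mean_ions" %in% names(dat)) {
    dat$y <- dat$mean_ions; dat$e <- dat$max_error_ions
    ylab <- "mean number of ions in class"
  } else {
    dat$y <- dat$mean; dat$e <- dat$max_error
    ylab <- "fraction of ions in class"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$y)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$e, ymax = .data$y + .data$e),
      width = 0.25) +
    ggplot2::labs(x = "cluster size class", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a between-system population difference
#'
#' @param object A `population_difference`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot population_difference
#' @export
autoplot.population_difference <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  dat$class <- factor(dat$class, levels = unique(dat$class))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$diff_ions,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$diff_ions - .data$uncertainty_ions,
                   ymax = .data$diff_ions + .data$uncertainty_ions),
      width = 0.25) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = "cluster size class",
                  y = "difference in mean ion count (a - b)") +
    ggplot2::theme_minimal()
}
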