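#' Assemble a difference-wave stack
#'
#' Binds per-participant difference waves (a common channel/sample grid)
#' into the participants x channels x samples array used by the cluster
#' statistics, keeping scalp channels only.
#'
#' @param waves List of `difference_wave` objects.
#' @param layout An `eeg_layout` (used to restrict to scalp channels).
#' @return A `diff_stack` object.
#' @export
diff_stack <- function(waves, layout) {
  stopifnot(length(waves) >= 1, inherits(layout, "eeg_layout"))
  times <- attr(waves[[1]], "times")
  chans <- attr(waves[[1]], "channels")
  for (w in waves)
    if (!identical(attr(w, "times"), times) ||
        !identical(attr(w, "channels"), chans))
      stop("difference waves are on different grids")
  scalp <- intersect(chans,
                     layout$channels$name[layout$channels$type == "scalp"])
  ci <- chan_idx(chans, scalp)
  data <- array(0, dim = c(length(waves), length(scalp), length(times)),
                dimnames = list(NULL, scalp, NULL))
  for (p in seq_along(waves)) data[p, , ] <- waves[[p]][ci, ]
  structure(list(data = data, channels = scalp, times = times,
                 layout = layout, effects = NULL),
            class = "diff_stack")
}

#' Pointwise paired t map over participants
#'
#' At each (channel, sample) inside the analysis window, computes
#' `t = mean(d) / (sd(d) / sqrt(n))` over the participant dimension of a
#' difference-wave stack, with `df = n - 1`. Zero-variance cells are a
#' degenerate-input case: a cell whose differences are identically zero
#' is set to t = 0, one with zero variance around a nonzero mean to
#' +/- Inf; both raise a warning, and infinite cells never enter
#' clusters.
#'
#' @param stack A `diff_stack`.
#' @param window_ms Closed analysis window in ms, or `NULL` for the whole
#'   grid (the conventional choice is the full post-stimulus epoch).
#' @param tail `"negative"` (MMN direction, default), `"positive"`, or
#'   `"two_sided"`.
#' @return An object of class `tstat_map`: list with `t` (channels x
#'   samples matrix), `df`, `times`, `channels`, `window_ms`, `tail`,
#'   `layout`.
#' @export
paired_t_map <- function(stack, window_ms = NULL, tail = "negative") {
  stopifnot(inherits(stack, "diff_stack"))
  tail <- match.arg(tail, c("negative", "positive", "two_sided"))
  n <- dim(stack$data)[1]
  if (n < 2) stop("need at least 2 participants")
  sel <- if (is.null(window_ms)) rep(TRUE, length(stack$times)) else
    in_window(stack$times, window_ms)
  if (!any(sel)) stop("analysis window contains no samples")
  d <- stack$data[, , sel, drop = FALSE]
  dm <- dim(d)
  dim(d) <- c(dm[1], dm[2] * dm[3])
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  if (any(v == 0)) {
    t[v == 0 & m == 0] <- 0
    t[v == 0 & m != 0] <- sign(m[v == 0 & m != 0]) * Inf
    warning("zero-variance cells: t set to 0 (zero mean) or +/-Inf ",
            "(excluded from clustering)")
  }
  structure(list(t = matrix(t, dm[2], dm[3],
                            dimnames = list(stack$channels, NULL)),
                 df = n - 1, times = stack$times[sel],
                 channels = stack$channels, window_ms = window_ms,
                 tail = tail, layout = stack$layout),
            class = "tstat_map")
}

#' @export
print.tstat_map <- function(x, ...) {
  cat(sprintf("<tstat_map>: %d channels x %d samples, df = %d, tail = %s\n",
              nrow(x$t), ncol(x$t), x$df, x$tail))
  invisible(x)
}

# threshold masks per tail; infinite t never enters a cluster
threshold_masks <- function(t, df, cluster_alpha, tail) {
  finite <- is.finite(t)
  if (tail == "negative") {
    list(negative = finite & t <= stats::qt(cluster_alpha, df))
  } else if (tail == "positive") {
    list(positive = finite & t >= stats::qt(1 - cluster_alpha, df))
  } else {
    crit <- stats::qt(1 - cluster_alpha / 2, df)
    list(negative = finite & t <= -crit, positive = finite & t >= crit)
  }
}

# connected-component cluster masses over a pruned mask.
# mask, t: channels x samples matrices; adj: 0/1 matrix; edges: 2-col
# index matrix of the adjacency's upper triangle.
# Returns list(masses, labels): labels is an integer matrix, 0 = none.
cluster_components <- function(t, mask, adj, edges, minnbchan) {
  C <- nrow(mask); S <- ncol(mask)
  if (minnbchan > 0) {
    nb <- adj %*% mask
    mask <- mask & (nb >= minnbchan)
  }
  cells <- which(mask)
  labels <- matrix(0L, C, S)
  if (!length(cells))
    return(list(masses = numeric(0), labels = labels))
  id <- integer(C * S)
  id[cells] <- seq_along(cells)
  parent <- seq_along(cells)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(a, b) {
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[rb] <<- ra
    }
  }
  # temporal adjacency: same channel, lag-1 samples
  if (S > 1) {
    # linear index (c, s) in the C x (S-1) submatrix equals the full-matrix
    # index of the same cell; its lag-1 partner sits C entries later
    both <- which(mask[, -S, drop = FALSE] & mask[, -1, drop = FALSE])
    if (length(both)) link(id[both], id[both + C])
  }
  # spatial adjacency: neighbour channels, same sample
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      s <- which(mask[i, ] & mask[j, ])
      if (length(s)) link(id[i + (s - 1) * C], id[j + (s - 1) * C])
    }
  }
  roots <- vapply(seq_along(cells), find, 0L)
  comp <- match(roots, unique(roots))
  labels[cells] <- comp
  masses <- as.numeric(rowsum(t[cells], comp))
  list(masses = masses, labels = labels)
}

adj_edges <- function(adj) {
  e <- which(adj & upper.tri(adj), arr.ind = TRUE)
  matrix(as.integer(e), ncol = 2)
}

#' Extract suprathreshold spatiotemporal clusters
#'
#' Four steps, in order: (1) mask the cells whose t value exceeds the
#' one-tailed critical value for `cluster_alpha` at the map's df, in the
#' tested tail; (2) prune once, per time slice: a masked cell survives
#' only if at least `minnbchan` of its spatial neighbours at the same
#' sample are also masked (`minnbchan = 0` disables pruning); (3) find
#' connected components under the adjacency "spatial neighbours at the
#' same sample, plus the same channel at lag-1 samples" (no wraparound);
#' (4) score each cluster by its mass, the sum of member t values.
#'
#' @param tmap A `tstat_map`.
#' @param cluster_alpha Cluster-forming threshold probability
#'   (one-tailed, default 0.1).
#' @param minnbchan Minimum suprathreshold spatial neighbours (default 2).
#' @param layout Layout providing the neighbour graph; defaults to the
#'   map's.
#' @return A list of clusters, each of class `eeg_cluster`: list with
#'   `members` (data frame `channel`, `sample`, `time_ms`), `mass`,
#'   `sign`.
#' @export
extract_clusters <- function(tmap, cluster_alpha = 0.1, minnbchan = 2,
                             layout = tmap$layout) {
  stopifnot(inherits(tmap, "tstat_map"),
            cluster_alpha > 0, cluster_alpha <= 0.5)
  adj <- layout$adjacency[tmap$channels, tmap$channels, drop = FALSE]
  if (!identical(rownames(adj), tmap$channels))
    stop("layout does not cover the map's channels")
  edges <- adj_edges(adj)
  masks <- threshold_masks(tmap$t, tmap$df, cluster_alpha, tmap$tail)
  out <- list()
  for (sgn in names(masks)) {
    cc <- cluster_components(tmap$t, masks[[sgn]], (adj) * 1, edges,
                             minnbchan)
    for (k in seq_along(cc$masses)) {
      cells <- which(cc$labels == k, arr.ind = TRUE)
      out[[length(out) + 1]] <- structure(list(
        members = data.frame(channel = tmap$channels[cells[, 1]],
                             sample = cells[, 2],
                             time_ms = tmap$times[cells[, 2]]),
        mass = cc$masses[k],
        sign = if (sgn == "negative") -1 else 1),
        class = "eeg_cluster")
    }
  }
  out[order(-abs(vapply(out, `[[`, 0, "mass")))]
}

#' @export
print.eeg_cluster <- function(x, ...) {
  cat(sprintf("<eeg_cluster>: %d cells, mass %.2f%s, %g-%g ms, %d channels\n",
              nrow(x$members), x$mass,
              if (!is.null(x$monte_carlo_p))
                sprintf(", p = %.4g", x$monte_carlo_p) else "",
              min(x$members$time_ms), max(x$members$time_ms),
              length(unique(x$members$channel))))
  invisible(x)
}

#' Spatiotemporal cluster-based permutation test
#'
#' Tests whether the deviant condition differs from the standard
#' condition (paired, within participants) while controlling the
#' familywise error over channels and samples. The observed t map is
#' clustered by [extract_clusters()]; the null distribution of the most
#' extreme cluster mass is built by randomly sign-flipping each
#' participant's difference wave (the exchangeability of paired condition
#' labels), recomputing the t map and the extreme cluster mass on each of
#' `n_perm` iterations. Each observed cluster receives the Monte-Carlo
#' p-value `(r + 1) / (n_perm + 1)`, where `r` counts permutation extremes
#' at least as extreme as the cluster's mass, so the observed data count
#' as one permutation and p is never zero.
#'
#' @param stack A `diff_stack` (or list of `difference_wave` plus
#'   `layout`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param cluster_alpha Cluster-forming threshold (one-tailed, 0.1).
#' @param minnbchan Spatial-neighbour pruning floor (2).
#' @param window_ms Analysis window, `NULL` = whole grid.
#' @param tail `"negative"` (default), `"positive"`, or `"two_sided"`
#'   (per-sign thresholds at `cluster_alpha / 2`; p-values doubled).
#' @param layout Layout override.
#' @return An object of class `cluster_result`: list with `clusters`
#'   (each with `monte_carlo_p`), `null_extremes` (per tested sign),
#'   `n_perm`, `seed`, `config`, `tmap`.
#' @export
permutation_test <- function(stack, n_perm = 1000, seed = NULL,
                             cluster_alpha = 0.1, minnbchan = 2,
                             window_ms = NULL, tail = "negative",
                             layout = NULL) {
  if (is.list(stack) && !inherits(stack, "diff_stack"))
    stack <- diff_stack(stack, layout)
  layout <- layout %||% stack$layout
  stopifnot(n_perm >= 1)
  tmap <- paired_t_map(stack, window_ms, tail)
  clusters <- extract_clusters(tmap, cluster_alpha, minnbchan, layout)

  n <- dim(stack$data)[1]
  C <- length(tmap$channels); S <- length(tmap$times)
  sel <- if (is.null(window_ms)) rep(TRUE, length(stack$times)) else
    in_window(stack$times, window_ms)
  D <- stack$data[, , sel, drop = FALSE]
  dim(D) <- c(n, C * S)
  ss <- colSums(D^2)
  adj <- layout$adjacency[tmap$channels, tmap$channels, drop = FALSE]
  adj_num <- adj * 1
  edges <- adj_edges(adj)

  signs <- with_seed(seed,
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  tails <- names(threshold_masks(matrix(0, 1, 1), tmap$df, cluster_alpha,
                                 tail))
  null_ex <- lapply(tails, function(s) numeric(n_perm))
  names(null_ex) <- tails
  chunk <- max(1L, floor(2e6 / (C * S)))
  for (start in seq(1, n_perm, by = chunk)) {
    rows <- start:min(start + chunk - 1, n_perm)
    M <- (signs[rows, , drop = FALSE] %*% D) / n
    for (r in seq_along(rows)) {
      m <- M[r, ]
      v <- (ss - n * m^2) / (n - 1)
      v[v <= 0] <- Inf  # degenerate cells cannot enter clusters
      tp <- matrix(m / sqrt(v / n), C, S)
      masks <- threshold_masks(tp, tmap$df, cluster_alpha, tail)
      for (sgn in tails) {
        masses <- cluster_components(tp, masks[[sgn]], adj_num, edges,
                                     minnbchan)$masses
        null_ex[[sgn]][rows[r]] <- if (!length(masses)) 0 else
          if (sgn == "negative") min(masses) else max(masses)
      }
    }
  }

  p_scale <- if (tail == "two_sided") 2 else 1
  clusters <- lapply(clusters, function(cl) {
    ex <- if (cl$sign < 0) null_ex$negative else null_ex$positive
    r <- if (cl$sign < 0) sum(ex <= cl$mass) else sum(ex >= cl$mass)
    cl$monte_carlo_p <- min(1, p_scale * (r + 1) / (n_perm + 1))
    cl
  })
  structure(list(clusters = clusters, null_extremes = null_ex,
                 n_perm = n_perm, seed = seed,
                 config = list(cluster_alpha = cluster_alpha,
                               minnbchan = minnbchan,
                               window_ms = window_ms, tail = tail),
                 tmap = tmap),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result>: %d cluster(s), %d permutations, tail = %s\n",
              length(x$clusters), x$n_perm, x$config$tail))
  if (length(x$clusters)) {
    df <- summary(x)
    print(utils::head(df, 5), row.names = FALSE)
    if (nrow(df) > 5) cat("  ...", nrow(df) - 5, "more\n")
  }
  invisible(x)
}

#' Summary table of clusters
#'
#' @param object A `cluster_result`.
#' @param ... Ignored.
#' @return Data frame: one row per cluster (size, mass, sign, time span,
#'   Monte-Carlo p).
#' @export
summary.cluster_result <- function(object, ...) {
  if (!length(object$clusters))
    return(data.frame(n_cells = integer(0), mass = numeric(0),
                      sign = integer(0), t_min_ms = numeric(0),
                      t_max_ms = numeric(0), p = numeric(0)))
  do.call(rbind, lapply(object$clusters, function(cl)
    data.frame(n_cells = nrow(cl$members), mass = cl$mass,
               sign = cl$sign, t_min_ms = min(cl$members$time_ms),
               t_max_ms = max(cl$members$time_ms),
               p = cl$monte_carlo_p)))
}

#' Minimum cluster p-value of a result
#'
#' @param result A `cluster_result`.
#' @return The smallest Monte-Carlo p, or `NA` when no cluster formed.
#' @export
min_cluster_p <- function(result) {
  if (!length(result$clusters)) return(NA_real_)
  min(vapply(result$clusters, `[[`, 0, "monte_carlo_p"))
}

#' Image plot of a t map with cluster membership
#'
#' @param x A `cluster_result`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.cluster_result <- function(x, ...) {
  tm <- x$tmap
  graphics::image(tm$times, seq_len(nrow(tm$t)), t(tm$t),
                  xlab = "time (ms)", ylab = "channel",
                  main = "paired t map", ...)
  for (cl in x$clusters)
    graphics::points(cl$members$time_ms,
                     match(cl$members$channel, tm$channels),
                     pch = ".", cex = 2)
  invisible(x)
}
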