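# Independent oracles and small fixture builders used across tests.

# exhaustive enumeration of ordered compositions of `total` into `n`
# parts, each in [min_len, max_len]
enumerate_compositions <- function(n, total, min_len, max_len) {
  if (n == 1) {
    if (total >= min_len && total <= max_len) return(list(total))
    return(list())
  }
  out <- list()
  for (v in min_len:max_len) {
    rest <- enumerate_compositions(n - 1, total - v, min_len, max_len)
    out <- c(out, lapply(rest, function(r) c(v, r)))
  }
  out
}

# brute-force cluster oracle: explicit-loop pruning plus breadth-first
# flood fill, deliberately naive and independent of the package path.
# mask/t: channels x samples; adj: logical matrix. Returns a list of
# clusters, each list(cells = sorted linear indices, mass).
oracle_clusters <- function(t, mask, adj, minnbchan) {
  C <- nrow(mask); S <- ncol(mask)
  pruned <- mask
  if (minnbchan > 0) {
    for (c in seq_len(C)) for (s in seq_len(S)) {
      if (!mask[c, s]) next
      nb <- 0
      for (c2 in seq_len(C)) if (adj[c, c2] && mask[c2, s]) nb <- nb + 1
      if (nb < minnbchan) pruned[c, s] <- FALSE
    }
  }
  seen <- matrix(FALSE, C, S)
  clusters <- list()
  for (c in seq_len(C)) for (s in seq_len(S)) {
    if (!pruned[c, s] || seen[c, s]) next
    queue <- list(c(c, s))
    cells <- integer(0)
    seen[c, s] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      cells <- c(cells, cur[1] + (cur[2] - 1) * C)
      for (c2 in seq_len(C)) {
        if (adj[cur[1], c2] && pruned[c2, cur[2]] && !seen[c2, cur[2]]) {
          seen[c2, cur[2]] <- TRUE
          queue <- c(queue, list(c(c2, cur[2])))
        }
      }
      for (s2 in c(cur[2] - 1, cur[2] + 1)) {
        if (s2 >= 1 && s2 <= S && pruned[cur[1], s2] &&
            !seen[cur[1], s2]) {
          seen[cur[1], s2] <- TRUE
          queue <- c(queue, list(c(cur[1], s2)))
        }
      }
    }
    clusters[[length(clusters) + 1]] <-
      list(cells = sort(cells), mass = sum(t[cells]))
  }
  clusters
}

# canonical form for comparing cluster partitions
canon_clusters <- function(cl) {
  out <- lapply(cl, function(x) list(cells = sort(x$cells),
                                     mass = round(x$mass, 10)))
  out[order(vapply(out, function(x) x$cells[1], 0))]
}

# package clusters -> oracle-comparable form
pkg_clusters_canon <- function(clusters, channels) {
  canon_clusters(lapply(clusters, function(cl) {
    ci <- match(cl$members$channel, channels)
    list(cells = ci + (cl$members$sample - 1) * length(channels),
         mass = cl$mass)
  }))
}

# a tstat_map with prescribed t values on a micro layout
make_tmap <- function(t, layout, df = 10, times = seq_len(ncol(t)) - 1,
                      tail = "negative") {
  structure(list(t = t, df = df, times = times,
                 channels = rownames(t), window_ms = NULL, tail = tail,
                 layout = layout),
            class = "tstat_map")
}

# epochs with prescribed data on a layout (metadata minimal)
make_epochs <- function(data, layout, times, info = NULL) {
  if (is.null(dimnames(data)[[2]]))
    dimnames(data) <- list(NULL, layout$channels$name, NULL)
  info <- info %||% data.frame(participant = "t",
                               block = 1, block_type = "-asp",
                               contrast = "vot",
                               trial = seq_len(dim(data)[1]) - 1,
                               role = "standard", segment = "pseudorandom",
                               token = "pa", iti_ms = 1000,
                               analyzable = TRUE)
  oddwave:::new_epochs(data, info, times, layout,
                       params = sim_params(sigma_trial = 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
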