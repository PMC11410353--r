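#' Write / read a channel layout as JSON
#'
#' The JSON carries the channel table and the neighbour graph as a named
#' adjacency list, so layouts are diffable and portable.
#'
#' @param layout An `eeg_layout`.
#' @param path Output file.
#' @return `path`, invisibly (writer); an `eeg_layout` (reader).
#' @export
write_layout <- function(layout, path) {
  nbr <- apply(layout$adjacency, 1, function(r)
    colnames(layout$adjacency)[r], simplify = FALSE)
  obj <- list(preset = layout$preset, channels = layout$channels,
              neighbors = nbr)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- as.data.frame(obj$channels)
  scalp <- channels$name[channels$type == "scalp"]
  adj <- matrix(FALSE, length(scalp), length(scalp),
                dimnames = list(scalp, scalp))
  for (ch in scalp) adj[ch, unlist(obj$neighbors[[ch]])] <- TRUE
  out <- structure(list(preset = obj$preset, channels = channels,
                        adjacency = adj), class = "eeg_layout")
  validate_layout(out)
  out
}

#' Write / read a session plan as JSON
#'
#' @param plan A `session_plan`.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `session_plan` (reader).
#' @export
write_session <- function(plan, path) {
  obj <- list(participant_id = plan$participant_id,
              master_seed = plan$master_seed,
              block_order = plan$block_order,
              n_order_attempts = plan$n_order_attempts,
              blocks = lapply(plan$blocks, function(b)
                list(block_type = b$block_type, contrast = b$contrast,
                     seed = b$seed, run_lengths = b$run_lengths,
                     trials = b$trials)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- lapply(seq_len(nrow(obj$blocks)), function(i) {
    tr <- as.data.frame(obj$blocks$trials[[i]])
    tr$index <- as.integer(tr$index)
    tr$iti_ms <- as.integer(tr$iti_ms)
    structure(list(block_type = obj$blocks$block_type[i],
                   contrast = obj$blocks$contrast[i],
                   trials = tr,
                   run_lengths = as.integer(obj$blocks$run_lengths[[i]]),
                   seed = obj$blocks$seed[i]),
              class = "block_plan")
  })
  structure(list(participant_id = obj$participant_id,
                 master_seed = obj$master_seed,
                 block_order = obj$block_order,
                 n_order_attempts = obj$n_order_attempts,
                 blocks = blocks),
            class = "session_plan")
}

#' Export a session plan as a flat TSV trial log
#'
#' Columns: `block`, `trial`, `block_type`, `segment`, `role`, `token`,
#' `iti_ms` (plus `analyzable` when flags are present).
#'
#' @param plan A `session_plan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(plan, path) {
  utils::write.table(as.data.frame(plan), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an epochs container
#'
#' A plain-text on-disk container: a directory holding the data matrix as
#' gzipped CSV (one row per trial x channel, one column per sample), the
#' trial metadata, sample grid and provenance as JSON, and the layout as
#' JSON. Suited to the modest epoch counts of simulation studies;
#' everything is diffable after decompression.
#'
#' @param epochs An `eeg_epochs` object.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly (writer); an `eeg_epochs` (reader).
#' @export
write_epochs <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[1] * d[2], d[3])
  df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                   channel = rep(dimnames(epochs$data)[[2]], d[1]))
  df <- cbind(df, as.data.frame(flat))
  con <- gzfile(file.path(path, "data.csv.gz"), "w")
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  meta <- list(info = epochs$info, times = epochs$times,
               params = unclass(epochs$params),
               effects = as.list(epochs$effects %||% list()),
               steps = epochs$steps)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_layout(epochs$layout, file.path(path, "layout.json"))
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  layout <- read_layout(file.path(path, "layout.json"))
  df <- utils::read.csv(gzfile(file.path(path, "data.csv.gz")),
                        check.names = FALSE)
  ch <- unique(df$channel)
  n_tr <- max(df$trial); n_ch <- length(ch)
  flat <- as.matrix(df[, -(1:2)])
  times <- as.numeric(meta$times)
  data <- aperm(array(flat, dim = c(n_ch, n_tr, length(times))),
                c(2, 1, 3))
  dimnames(data) <- list(NULL, ch, NULL)
  params <- if (length(meta$params))
    do.call(sim_params, meta$params) else NULL
  effects <- if (length(meta$effects)) unlist(meta$effects) else NULL
  info <- as.data.frame(meta$info)
  steps <- meta$steps
  if (is.data.frame(steps))
    steps <- lapply(seq_len(nrow(steps)), function(i)
      as.list(steps[i, , drop = FALSE]))
  new_epochs(data, info, times, layout, params = params,
             effects = effects, steps = steps %||% list())
}

#' Export an ERP or difference wave as CSV
#'
#' Rows are time points (first column `time_ms`), remaining columns are
#' channels, values in microvolts.
#'
#' @param wave An `erp_waveform` or `difference_wave`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_erp_csv <- function(wave, path) {
  df <- data.frame(time_ms = attr(wave, "times"))
  m <- t(unclass(wave))
  colnames(m) <- attr(wave, "channels")
  utils::write.csv(cbind(df, m), path, row.names = FALSE)
  invisible(path)
}

#' Write a rejection log as TSV
#'
#' @param log A `rejection_log`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rejection_log <- function(log, path) {
  utils::write.table(as.data.frame(log), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a cluster test result to JSON
#'
#' Clusters with member lists, masses and Monte-Carlo p-values, plus the
#' configuration echo and seed, so a result is fully reconstructable.
#'
#' @param result A `cluster_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_result <- function(result, path) {
  obj <- list(n_perm = result$n_perm, seed = result$seed,
              config = result$config,
              df = result$tmap$df,
              clusters = lapply(result$clusters, function(cl)
                list(mass = cl$mass, sign = cl$sign,
                     monte_carlo_p = cl$monte_carlo_p,
                     members = cl$members)),
              null_extremes = result$null_extremes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
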