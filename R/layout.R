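#' Channel layouts and neighbour graphs
#'
#' Builds a schematic electrode layout: channel names, 2-D head-schematic
#' coordinates (arbitrary units), and a symmetric spatial-neighbour graph
#' over the scalp channels. Mastoid reference channels (M1/M2) are carried
#' in the layout but excluded from the neighbour graph, as is conventional
#' for cluster statistics.
#'
#' Presets:
#' \describe{
#'   \item{`"grid64"`}{64 scalp channels named in extended 10/20 (10-10)
#'     nomenclature, laid out on a 9-column schematic grid with Cz at the
#'     vertex, plus M1/M2 mastoids. Neighbours are the horizontally,
#'     vertically and diagonally adjacent grid positions.}
#'   \item{`"grid12"`}{a 3 x 4 grid of channels `E01`..`E12` plus M1/M2;
#'     a small layout for simulation studies.}
#'   \item{`"chain-N"`}{N channels `A`, `B`, ... in a line, each adjacent
#'     to its immediate neighbours; no reference channels.}
#'   \item{`"complete-N"`}{N mutually adjacent channels `A`, `B`, ...;
#'     no reference channels.}
#' }
#'
#' @param preset Layout name, e.g. `"grid64"`, `"chain-4"`, `"complete-3"`.
#' @return An object of class `eeg_layout`: a list with elements
#'   `preset`, `channels` (data frame with `name`, `x`, `y`, `type`), and
#'   `adjacency` (logical scalp x scalp matrix with dimnames).
#' @export
#' @examples
#' lay <- make_layout("grid64")
#' lay
#' neighbours <- colnames(lay$adjacency)[lay$adjacency["Cz", ]]
make_layout <- function(preset = "grid64") {
  stopifnot(is.character(preset), length(preset) == 1)
  if (preset == "grid64") {
    rows <- list(
      list(y = 4,  names = c("Fp1", "Fpz", "Fp2"), x = c(-1, 0, 1)),
      list(y = 3,  names = c("AF7", "AF3", "AFz", "AF4", "AF8"),
           x = c(-3, -1, 0, 1, 3)),
      list(y = 2,  names = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6",
                             "F8"), x = -4:4),
      list(y = 1,  names = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
                             "FC6", "FT8"), x = -4:4),
      list(y = 0,  names = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
                             "T8"), x = -4:4),
      list(y = -1, names = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                             "CP6", "TP8"), x = -4:4),
      list(y = -2, names = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6",
                             "P8"), x = -4:4),
      list(y = -3, names = c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
           x = -3:3),
      list(y = -4, names = c("O1", "Oz", "O2"), x = c(-1, 0, 1)),
      list(y = -5, names = "Iz", x = 0)
    )
    scalp <- do.call(rbind, lapply(rows, function(r)
      data.frame(name = r$names, x = r$x, y = r$y)))
    refs <- data.frame(name = c("M1", "M2"), x = c(-5.5, 5.5), y = c(-1, -1))
  } else if (preset == "grid12") {
    scalp <- expand.grid(x = 1:4, y = 1:3)
    scalp <- data.frame(name = sprintf("E%02d", seq_len(12)),
                        x = scalp$x, y = scalp$y)
    refs <- data.frame(name = c("M1", "M2"), x = c(0, 5), y = c(2, 2))
  } else if (grepl("^chain-[0-9]+$", preset)) {
    n <- as.integer(sub("^chain-", "", preset))
    if (n < 2) stop("chain layouts need at least 2 channels")
    scalp <- data.frame(name = chan_names(n), x = seq_len(n), y = 0)
    refs <- NULL
  } else if (grepl("^complete-[0-9]+$", preset)) {
    n <- as.integer(sub("^complete-", "", preset))
    if (n < 2) stop("complete layouts need at least 2 channels")
    ang <- 2 * pi * (seq_len(n) - 1) / n
    scalp <- data.frame(name = chan_names(n), x = cos(ang), y = sin(ang))
    refs <- NULL
  } else {
    stop("unknown layout preset: ", preset)
  }
  scalp$type <- "scalp"
  if (!is.null(refs)) refs$type <- "ref"
  channels <- rbind(scalp, refs)
  rownames(channels) <- NULL

  if (grepl("^complete-", preset)) {
    adj <- matrix(TRUE, nrow(scalp), nrow(scalp))
    diag(adj) <- FALSE
  } else if (grepl("^chain-", preset)) {
    adj <- abs(outer(seq_len(nrow(scalp)), seq_len(nrow(scalp)), "-")) == 1
  } else {
    d <- as.matrix(stats::dist(scalp[, c("x", "y")]))
    adj <- d > 0 & d <= 1.5
  }
  dimnames(adj) <- list(scalp$name, scalp$name)

  out <- structure(list(preset = preset, channels = channels,
                        adjacency = adj),
                   class = "eeg_layout")
  validate_layout(out)
  out
}

validate_layout <- function(layout) {
  adj <- layout$adjacency
  if (!isTRUE(all(adj == t(adj)))) stop("adjacency must be symmetric")
  if (any(diag(adj))) stop("no self-neighbours allowed")
  if (any(rowSums(adj) < 1)) stop("every scalp channel needs >= 1 neighbour")
  scalp <- layout$channels$name[layout$channels$type == "scalp"]
  if (!identical(sort(rownames(adj)), sort(scalp)))
    stop("adjacency must cover exactly the scalp channels")
  invisible(layout)
}

chan_names <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else sprintf("Ch%02d", seq_len(n))
}

#' @export
print.eeg_layout <- function(x, ...) {
  n_scalp <- sum(x$channels$type == "scalp")
  n_ref <- sum(x$channels$type == "ref")
  cat(sprintf("<eeg_layout '%s'>: %d scalp channels, %d reference channels\n",
              x$preset, n_scalp, n_ref))
  deg <- rowSums(x$adjacency)
  cat(sprintf("  neighbour degree: min %d, median %g, max %d\n",
              min(deg), stats::median(deg), max(deg)))
  invisible(x)
}

# indices of layout channels within an epoch channel dimension
chan_idx <- function(channels, names) {
  i <- match(names, channels)
  if (anyNA(i)) stop("channel(s) not found: ",
                     paste(names[is.na(i)], collapse = ", "))
  i
}
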