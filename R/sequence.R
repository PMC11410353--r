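#' Token inventories for the three oddball contrasts
#'
#' Returns the word/syllable tokens serving as deviants and standards in a
#' given block type. The tense blocks contrast irregular past- and
#' present-tense verbs (3 deviant tokens, 3 critical standards that are the
#' deviants of the mirror block, and 9 extra filler standards, so that 12
#' standard types are in play and token frequency alone cannot signal the
#' oddball arrangement). The voicing blocks contrast voiced and voiceless
#' consonants in an [_a] frame (5 vs 5, no fillers), and the VOT blocks
#' contrast a single aspirated vs unaspirated syllable (1 vs 1).
#'
#' @param deviant_condition One of `"present"`, `"past"`, `"+voi"`,
#'   `"-voi"`, `"+asp"`, `"-asp"` (the six block types).
#' @return An object of class `token_inventory` with fields `contrast`,
#'   `deviant_condition`, `deviant_tokens`, `critical_standard_tokens`,
#'   `extra_standard_tokens`, and `standard_tokens` (critical + extra).
#' @export
#' @examples
#' token_inventory("past")
token_inventory <- function(deviant_condition) {
  past <- c("gave", "met", "sank")
  pres <- c("pave", "get", "thank")
  extra_past <- c("chose", "sang", "bled", "swore", "clung", "pled",
                  "grew", "drew", "brought")
  extra_pres <- c("choose", "sing", "bleed", "swear", "cling", "plead",
                  "grow", "woo", "bring")
  voiced <- c("ba", "da", "ga", "va", "za")
  voiceless <- c("pa", "ta", "ka", "fa", "sa")
  inv <- switch(deviant_condition,
    "present" = list(contrast = "tense", dev = pres, std = past,
                     extra = extra_past),
    "past"    = list(contrast = "tense", dev = past, std = pres,
                     extra = extra_pres),
    "+voi"    = list(contrast = "voicing", dev = voiced, std = voiceless,
                     extra = character(0)),
    "-voi"    = list(contrast = "voicing", dev = voiceless, std = voiced,
                     extra = character(0)),
    "+asp"    = list(contrast = "vot", dev = "pa", std = "ba",
                     extra = character(0)),
    "-asp"    = list(contrast = "vot", dev = "ba", std = "pa",
                     extra = character(0)),
    stop("unknown block type: ", deviant_condition)
  )
  structure(list(contrast = inv$contrast,
                 deviant_condition = deviant_condition,
                 deviant_tokens = inv$dev,
                 critical_standard_tokens = inv$std,
                 extra_standard_tokens = inv$extra,
                 standard_tokens = c(inv$std, inv$extra)),
            class = "token_inventory")
}

#' The six oddball block types
#' @return Character vector of the six deviant-condition labels.
#' @export
block_types <- function() c("present", "past", "+voi", "-voi", "+asp", "-asp")

#' Mirror block type of a deviant condition
#'
#' The block type in which a condition's deviant tokens serve as standards;
#' used to assemble the identity-MMN standard ERP from the same tokens.
#'
#' @param deviant_condition A block type label.
#' @return The partner block type label.
#' @export
#' @examples
#' partner_condition("past") # "present"
partner_condition <- function(deviant_condition) {
  map <- c("present" = "past", "past" = "present",
           "+voi" = "-voi", "-voi" = "+voi",
           "+asp" = "-asp", "-asp" = "+asp")
  out <- unname(map[deviant_condition])
  if (anyNA(out)) stop("unknown block type: ", deviant_condition)
  out
}

# DP table of bounded-composition counts: C[k + 1, t + 1] = number of ways
# to write t as an ordered sum of k integers each in [min_len, max_len].
composition_counts <- function(n_runs, total, min_len, max_len) {
  counts <- matrix(0, nrow = n_runs + 1, ncol = total + 1)
  counts[1, 1] <- 1
  for (k in seq_len(n_runs)) {
    for (t in seq(k * min_len, min(total, k * max_len))) {
      v <- min_len:min(max_len, t)
      prev <- t - v
      ok <- prev >= (k - 1) * min_len & prev <= (k - 1) * max_len
      counts[k + 1, t + 1] <- sum(counts[k, prev[ok] + 1])
    }
  }
  counts
}

#' Sample run lengths uniformly over bounded compositions
#'
#' Draws `n_runs` integers, each in `[min_len, max_len]`, summing exactly to
#' `total`, uniformly over all such ordered compositions. Uniformity is
#' achieved by sequential conditional draws weighted by exact
#' dynamic-programming counts of the remaining capacity. This generates the
#' lengths of the standard runs that precede each deviant in a block.
#'
#' @param n_runs Number of runs (one per deviant).
#' @param total Total number of standards to distribute across runs.
#' @param min_len,max_len Bounds on each run length (default 4 and 9).
#' @param seed Optional integer seed.
#' @return Integer vector of length `n_runs` summing to `total`.
#' @export
#' @examples
#' x <- sample_run_lengths(40, 271, 4, 9, seed = 1)
#' sum(x)    # 271
#' range(x)  # within [4, 9]
sample_run_lengths <- function(n_runs, total, min_len = 4, max_len = 9,
                               seed = NULL) {
  stopifnot(n_runs >= 1, min_len >= 1, max_len >= min_len)
  if (total < n_runs * min_len || total > n_runs * max_len) {
    stop(sprintf(
      "infeasible: %d runs of length %d-%d can only sum to [%d, %d], not %d",
      n_runs, min_len, max_len, n_runs * min_len, n_runs * max_len, total))
  }
  counts <- composition_counts(n_runs, total, min_len, max_len)
  with_seed(seed, {
    out <- integer(n_runs)
    remaining <- total
    for (i in seq_len(n_runs)) {
      left <- n_runs - i
      v <- min_len:min(max_len, remaining)
      w <- counts[left + 1, remaining - v + 1]
      keep <- w > 0
      v <- v[keep]; w <- w[keep]
      out[i] <- if (length(v) == 1) v else v[sample.int(length(v), 1,
                                                        prob = w)]
      remaining <- remaining - out[i]
    }
    out
  })
}

#' Build one oddball block
#'
#' Assembles a full block: `n_habituation` leading habituation standards,
#' then alternating standard runs (lengths drawn by
#' [sample_run_lengths()]) and single deviants, then one final standard.
#' Tokens are chosen independently and uniformly from the role's token set
#' at each trial, and inter-trial intervals (offset-to-onset) are uniform
#' integers in `iti_range` milliseconds. Defaults reproduce the published
#' design: 16 + 271 + 40 + 1 = 328 trials.
#'
#' @param block_type One of [block_types()].
#' @param inventory Optional [token_inventory()]; derived from `block_type`
#'   when omitted. Must match `block_type`.
#' @param n_deviants,n_standards,n_habituation Design counts (40, 271, 16).
#' @param run_min,run_max Bounds on pre-deviant standard runs (4, 9).
#' @param iti_range Inclusive ITI bounds in ms (900, 1100).
#' @param seed Optional integer seed.
#' @return An object of class `block_plan`: list with `block_type`,
#'   `contrast`, `trials` (data frame: `index` 0-based, `role`, `segment`,
#'   `token`, `iti_ms`), `run_lengths`, and `seed`.
#' @export
#' @examples
#' b <- build_block("past", seed = 1)
#' table(b$trials$role)
build_block <- function(block_type, inventory = NULL,
                        n_deviants = 40, n_standards = 271,
                        n_habituation = 16, run_min = 4, run_max = 9,
                        iti_range = c(900, 1100), seed = NULL) {
  inventory <- inventory %||% token_inventory(block_type)
  if (!inherits(inventory, "token_inventory"))
    stop("inventory must be a token_inventory")
  if (!identical(inventory$deviant_condition, block_type))
    stop(sprintf("inventory is for block type '%s', not '%s'",
                 inventory$deviant_condition, block_type))
  with_seed(seed, {
    runs <- sample_run_lengths(n_deviants, n_standards, run_min, run_max)
    role <- c(rep("standard", n_habituation),
              unlist(lapply(runs, function(r) c(rep("standard", r),
                                                "deviant"))),
              "standard")
    segment <- c(rep("habituation", n_habituation),
                 rep("pseudorandom", n_standards + n_deviants),
                 "final")
    n <- length(role)
    token <- character(n)
    is_dev <- role == "deviant"
    token[!is_dev] <- sample(inventory$standard_tokens, sum(!is_dev),
                             replace = TRUE)
    token[is_dev] <- sample(inventory$deviant_tokens, sum(is_dev),
                            replace = TRUE)
    iti_ms <- sample(iti_range[1]:iti_range[2], n, replace = TRUE)
    structure(list(
      block_type = block_type,
      contrast = inventory$contrast,
      trials = data.frame(index = seq_len(n) - 1L, role = role,
                          segment = segment, token = token,
                          iti_ms = iti_ms),
      run_lengths = runs,
      seed = seed
    ), class = "block_plan")
  })
}

#' Build a full experiment session
#'
#' 18 blocks: each of the six block types exactly three times, ordered by
#' rejection sampling from uniform permutations until no block type occurs
#' twice in a row. Each block is built from a named substream of
#' `master_seed` (recorded in the block), so sessions are fully
#' reproducible.
#'
#' @param master_seed Integer seed for the whole session.
#' @param participant_id Label stored with the plan.
#' @param n_repeats Repetitions of each block type (default 3).
#' @param ... Passed to [build_block()] (design-count overrides).
#' @return An object of class `session_plan`: list with `participant_id`,
#'   `master_seed`, `block_order`, `n_order_attempts`, and `blocks` (list
#'   of `block_plan`).
#' @export
#' @examples
#' plan <- build_session(1, "subj01")
#' plan
build_session <- function(master_seed, participant_id = "sim01",
                          n_repeats = 3, ...) {
  types <- rep(block_types(), n_repeats)
  order_seed <- derive_seed(master_seed, 0)
  attempts <- 0L
  block_order <- with_seed(order_seed, {
    repeat {
      attempts <- attempts + 1L
      ord <- sample(types)
      if (!any(ord[-1] == ord[-length(ord)])) break
    }
    ord
  })
  blocks <- lapply(seq_along(block_order), function(i)
    build_block(block_order[i], seed = derive_seed(master_seed, i), ...))
  structure(list(participant_id = participant_id,
                 master_seed = master_seed,
                 block_order = block_order,
                 n_order_attempts = attempts,
                 blocks = blocks),
            class = "session_plan")
}

#' Flag analyzable trials per the pre-registered exclusions
#'
#' Marks as non-analyzable: every habituation-segment trial, the first
#' deviant of each block, and the standard immediately following every
#' deviant (which removes the final standard too, as it always follows the
#' last deviant). With the default design this leaves 39 analyzable
#' deviants per block, i.e. (40 - 1) * 3 = 117 per condition over a
#' session.
#'
#' @param plan A `session_plan`.
#' @return The plan with an `analyzable` logical column added to every
#'   block's `trials`.
#' @export
#' @examples
#' plan <- mark_analyzable(build_session(1))
#' sum(plan$blocks[[1]]$trials$analyzable[
#'   plan$blocks[[1]]$trials$role == "deviant"])  # 39
mark_analyzable <- function(plan) {
  stopifnot(inherits(plan, "session_plan"))
  plan$blocks <- lapply(plan$blocks, function(b) {
    tr <- b$trials
    ok <- rep(TRUE, nrow(tr))
    ok[tr$segment == "habituation"] <- FALSE
    dev <- which(tr$role == "deviant")
    if (length(dev)) {
      ok[dev[1]] <- FALSE
      post <- dev + 1L
      post <- post[post <= nrow(tr)]
      ok[post[tr$role[post] == "standard"]] <- FALSE
    }
    b$trials$analyzable <- ok
    b
  })
  plan
}

#' @export
print.block_plan <- function(x, ...) {
  tab <- table(x$trials$role)
  cat(sprintf("<block_plan '%s' (%s)>: %d trials (%d standards, %d deviants)\n",
              x$block_type, x$contrast, nrow(x$trials),
              tab[["standard"]], tab[["deviant"]]))
  cat(sprintf("  pre-deviant runs: %d runs of %d-%d standards\n",
              length(x$run_lengths), min(x$run_lengths),
              max(x$run_lengths)))
  invisible(x)
}

#' @export
print.session_plan <- function(x, ...) {
  n_trials <- sum(vapply(x$blocks, function(b) nrow(b$trials), 0L))
  cat(sprintf("<session_plan '%s'>: %d blocks, %d trials (master seed %s)\n",
              x$participant_id, length(x$blocks), n_trials,
              format(x$master_seed)))
  cat("  block order:", paste(x$block_order, collapse = " "), "\n")
  invisible(x)
}

#' Flat trial table of a session plan
#'
#' @param x A `session_plan`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `block` (1-based), `trial` (0-based
#'   within block), `block_type`, `segment`, `role`, `token`, `iti_ms`,
#'   and `analyzable` when flags have been set.
#' @export
as.data.frame.session_plan <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  out <- do.call(rbind, lapply(seq_along(x$blocks), function(i) {
    tr <- x$blocks[[i]]$trials
    cbind(data.frame(block = i, trial = tr$index,
                     block_type = x$blocks[[i]]$block_type),
          tr[, setdiff(names(tr), "index"), drop = FALSE])
  }))
  rownames(out) <- NULL
  out
}
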