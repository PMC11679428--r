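#' Stimulation protocol specification
#'
#' Describes the block structure of the tactile attention experiment: six
#' blocks of five sub-blocks, each delivering 60 single electrical pulses to
#' the dorsal (D) and volar (V) forearm sites in pseudorandom order, with
#' 25--35 stimuli per location per sub-block and no more than three
#' consecutive stimuli at the same location. The attended location
#' alternates between blocks.
#'
#' @param n_blocks Number of blocks.
#' @param subblocks_per_block Sub-blocks per block.
#' @param stimuli_per_subblock Stimuli delivered in one sub-block.
#' @param per_location_min,per_location_max Bounds on the per-location
#'   stimulus count within one sub-block.
#' @param max_run_length Longest admissible run of identical locations.
#' @param inter_stimulus_interval Interval between consecutive pulses within
#'   a sub-block, seconds.
#' @param inter_subblock_gap,inter_block_gap Pauses inserted after each
#'   sub-block / block, seconds.
#' @param lead_in Quiet interval before the first stimulus, seconds (leaves
#'   room for the prestimulus baseline of the first epoch).
#' @param condition_schedule Character vector of attended locations, one per
#'   block ("D"/"V"). Default alternates starting at D.
#' @param seed Default RNG seed used by [generate_protocol()] when no seed is
#'   passed there.
#' @return An object of class `protocol_spec`.
#' @seealso [generate_protocol()]
#' @export
protocol_spec <- function(n_blocks = 6L, subblocks_per_block = 5L,
                          stimuli_per_subblock = 60L,
                          per_location_min = 25L, per_location_max = 35L,
                          max_run_length = 3L,
                          inter_stimulus_interval = 0.75,
                          inter_subblock_gap = 3,
                          inter_block_gap = 10,
                          lead_in = 2,
                          condition_schedule = NULL,
                          seed = 1L) {
  n_blocks <- stopifnot_scalar_count(n_blocks, "n_blocks")
  subblocks_per_block <- stopifnot_scalar_count(subblocks_per_block, "subblocks_per_block")
  stimuli_per_subblock <- stopifnot_scalar_count(stimuli_per_subblock, "stimuli_per_subblock")
  max_run_length <- stopifnot_scalar_count(max_run_length, "max_run_length")
  if (per_location_min < 0 || per_location_max < per_location_min)
    stop("need 0 <= per_location_min <= per_location_max")
  if (inter_stimulus_interval <= 0) stop("inter_stimulus_interval must be > 0")
  if (stimuli_per_subblock < 2 * per_location_min)
    stop(sprintf(paste0("infeasible constraints: stimuli_per_subblock (%d) < ",
                        "2 * per_location_min (%d); both locations cannot reach ",
                        "their minimum count"),
                 stimuli_per_subblock, 2L * as.integer(per_location_min)))
  if (stimuli_per_subblock > 2 * per_location_max)
    stop(sprintf(paste0("infeasible constraints: stimuli_per_subblock (%d) > ",
                        "2 * per_location_max (%d); the per-location maximum ",
                        "cannot absorb all stimuli"),
                 stimuli_per_subblock, 2L * as.integer(per_location_max)))
  if (is.null(condition_schedule))
    condition_schedule <- rep_len(c("D", "V"), n_blocks)
  if (length(condition_schedule) != n_blocks ||
      !all(condition_schedule %in% c("D", "V")))
    stop("condition_schedule must give 'D' or 'V' for every block")
  structure(list(
    n_blocks = n_blocks,
    subblocks_per_block = subblocks_per_block,
    stimuli_per_subblock = stimuli_per_subblock,
    per_location_min = as.integer(per_location_min),
    per_location_max = as.integer(per_location_max),
    max_run_length = max_run_length,
    inter_stimulus_interval = inter_stimulus_interval,
    inter_subblock_gap = inter_subblock_gap,
    inter_block_gap = inter_block_gap,
    lead_in = lead_in,
    condition_schedule = condition_schedule,
    seed = as.integer(seed)
  ), class = "protocol_spec")
}

# Sample one sub-block location sequence by rejection: draw a random
# arrangement with the target D count, resample until the run-length
# constraint holds. Uniform over feasible sequences for the given count.
sample_subblock <- function(n, n_d, max_run, max_tries = 100000L) {
  n_v <- n - n_d
  # a location with count m forces runs of the other shorter than needed when
  # m > max_run * (other + 1)
  if (n_d > max_run * (n_v + 1L) || n_v > max_run * (n_d + 1L))
    stop(sprintf(paste0("infeasible constraints: per-location counts %d/%d ",
                        "cannot satisfy max_run_length = %d"),
                 n_d, n_v, max_run))
  base <- c(rep("D", n_d), rep("V", n_v))
  for (i in seq_len(max_tries)) {
    s <- sample(base)
    if (max(rle(s)$lengths) <= max_run) return(s)
  }
  stop("rejection sampling failed to find a feasible sequence")
}

#' Generate a pseudorandomized stimulation protocol
#'
#' Draws the full event list for one recording session: for every sub-block,
#' a per-location count is drawn uniformly within the admissible bounds and
#' a location sequence is rejection-sampled until the run-length constraint
#' holds. Sub-block counts are drawn in complementary pairs (the second
#' sub-block of each pair receives the complement of the first), so each
#' sub-block count is uniform within its bounds while the session totals
#' stay exactly balanced between D and V (900 each under the defaults).
#' Event onsets advance by the inter-stimulus interval within a sub-block,
#' with pauses between sub-blocks and blocks. The attended location of each
#' block follows the condition schedule.
#'
#' @param spec A [protocol_spec()].
#' @param seed RNG seed; defaults to `spec$seed`. The result is deterministic
#'   given the seed.
#' @return A data frame of class `serp_protocol` with one row per stimulus:
#'   `onset` (seconds), `location`, `attended` (both "D"/"V"), `block`,
#'   `subblock`.
#' @examples
#' ev <- generate_protocol(protocol_spec(), seed = 1)
#' nrow(ev)            # 1800 events
#' table(ev$location)  # 900 D, 900 V
#' @export
generate_protocol <- function(spec = protocol_spec(), seed = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  seed <- seed %||% spec$seed
  S <- spec$stimuli_per_subblock
  lo <- max(spec$per_location_min, S - spec$per_location_max)
  hi <- min(spec$per_location_max, S - spec$per_location_min)
  local_seed(seed, {
    rows <- vector("list", spec$n_blocks * spec$subblocks_per_block)
    t_cur <- spec$lead_in
    k <- 0L
    n_d_prev <- NA_integer_
    for (b in seq_len(spec$n_blocks)) {
      att <- spec$condition_schedule[b]
      for (sb in seq_len(spec$subblocks_per_block)) {
        n_d <- if (k %% 2L == 1L && !is.na(n_d_prev)) {
          S - n_d_prev  # complement of the pair partner: session stays balanced
        } else if (lo == hi) lo else sample(lo:hi, 1L)
        n_d_prev <- n_d
        locs <- sample_subblock(S, n_d, spec$max_run_length)
        onsets <- t_cur + (seq_len(S) - 1L) * spec$inter_stimulus_interval
        k <- k + 1L
        rows[[k]] <- data.frame(onset = onsets, location = locs,
                                attended = att, block = b, subblock = sb,
                                stringsAsFactors = FALSE)
        t_cur <- onsets[S] + spec$inter_stimulus_interval +
          spec$inter_subblock_gap
      }
      t_cur <- t_cur + spec$inter_block_gap - spec$inter_subblock_gap
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "spec") <- spec
    class(out) <- c("serp_protocol", "data.frame")
    out
  })
}

# Protocol constraint checker used by the property tests: per-sub-block
# counts within bounds, run lengths within the cap, schedule respected,
# onsets strictly increasing.
check_protocol <- function(events, spec = attr(events, "spec")) {
  ok <- TRUE
  msg <- character(0)
  if (nrow(events) != spec$n_blocks * spec$subblocks_per_block *
      spec$stimuli_per_subblock) {
    ok <- FALSE; msg <- c(msg, "total event count")
  }
  if (any(diff(events$onset) <= 0)) { ok <- FALSE; msg <- c(msg, "onsets not increasing") }
  for (key in split(seq_len(nrow(events)),
                    list(events$block, events$subblock), drop = TRUE)) {
    locs <- events$location[key]
    n_d <- sum(locs == "D")
    if (n_d < spec$per_location_min || n_d > spec$per_location_max ||
        (length(locs) - n_d) < spec$per_location_min ||
        (length(locs) - n_d) > spec$per_location_max) {
      ok <- FALSE; msg <- c(msg, "per-location count out of bounds")
    }
    if (max(rle(locs)$lengths) > spec$max_run_length) {
      ok <- FALSE; msg <- c(msg, "run length exceeded")
    }
    isi <- diff(events$onset[key])
    if (any(abs(isi - spec$inter_stimulus_interval) > 1e-9)) {
      ok <- FALSE; msg <- c(msg, "inter-stimulus interval violated")
    }
  }
  sched <- vapply(seq_len(spec$n_blocks), function(b)
    unique(events$attended[events$block == b])[1], character(1))
  if (!identical(sched, spec$condition_schedule)) {
    ok <- FALSE; msg <- c(msg, "condition schedule violated")
  }
  structure(ok, problems = unique(msg))
}

#' @export
print.serp_protocol <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Stimulation protocol: %d events (%d D / %d V), %d blocks x %d sub-blocks\n",
              nrow(x), sum(x$location == "D"), sum(x$location == "V"),
              spec$n_blocks, spec$subblocks_per_block))
  cat(sprintf("attended per block: %s; duration %.1f s\n",
              paste(spec$condition_schedule, collapse = " "),
              max(x$onset) + spec$inter_stimulus_interval))
  invisible(x)
}
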