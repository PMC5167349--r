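# Generative simulator of library preparation.
#
# Each synthesis event is (s1, e1, s2, e2): first strand from s1 down to e1,
# second strand from s2 up to e2, so the double-stranded region is [s2, e2].
# Models A-C condition events on full-length selection by rejection,
# mirroring the physical PCR/template-switching enrichment.  Reads are drawn
# from accepted events with weight 1/d on (s2, e2) plus weight 1 on the
# fragment interior (s2 + h, e2 - h) intersected with the transcript
# interior (h, l - h); a uniform position is accepted with probability
# weight / (1/d + 1), which makes the marginal of accepted positions exactly
# proportional to the closed-form coverage density.

.MAX_REJECT <- 1e6

# Synthesis run lengths toward a boundary at distance run_max: exponential
# with rate theta, truncated runs that reach the boundary stop there
# (the point mass of the semi-continuous end-point density).
.rrun <- function(n, run_max, theta) {
  if (theta <= 0) return(rep(run_max, length.out = n))
  pmin(stats::rexp(n, theta), run_max)
}

# Draw up to n candidate events and return the accepted ones as a data frame
# (possibly fewer than n rows).  Selection (models A, B, C) and the
# first-strand-span priming weight (model E) are applied here.
.draw_events <- function(model, p, l, n) {
  t1 <- p$theta1; t2 <- p$theta2
  if (model == "BD") {
    b <- stats::runif(n) < p$alpha
    evB <- .draw_events("B", p, l, sum(b))
    evD <- .draw_events("D", p, l, n - sum(b))
    evB$branch <- rep("B", nrow(evB))
    evD$branch <- rep("D", nrow(evD))
    return(rbind(evB, evD))
  }
  if (model == "E") {
    r <- .e_rates(p)
    s1 <- stats::runif(n, 0, l)
    e1 <- s1 - .rrun(n, s1, r[["t1p"]])
    # constant per-base priming rate for s2 means an event's total priming
    # mass is proportional to its first-strand span
    keep <- stats::runif(n) < (s1 - e1) / l
    s1 <- s1[keep]; e1 <- e1[keep]
    s2 <- stats::runif(length(s1), e1, s1)
    e2 <- s2 + .rrun(length(s1), s1 - s2, r[["t2p"]])
    return(data.frame(s1 = s1, e1 = e1, s2 = s2, e2 = e2))
  }
  # models A-D: first strand primed at the 3' end
  s1 <- rep(l, n)
  e1 <- l - .rrun(n, l, t1)
  if (model %in% c("A", "C")) {
    keep <- e1 == 0                       # full-length first strands only
    e1 <- e1[keep]
    s2 <- rep(0, length(e1))
  } else {
    s2 <- e1                              # second strand primed at e1
  }
  e2 <- s2 + .rrun(length(s2), l - s2, t2)
  if (model %in% c("A", "B")) {
    keep <- e2 == l                       # complete second strands only
    s1 <- rep(l, sum(keep)); e1 <- e1[keep]; s2 <- s2[keep]; e2 <- e2[keep]
  } else {
    s1 <- rep(l, length(e1))
  }
  data.frame(s1 = s1, e1 = e1, s2 = s2, e2 = e2)
}

#' Sample synthesis events
#'
#' Draws realizations (s1, e1, s2, e2) of first- and second-strand cDNA
#' synthesis under a model, including the model's selection step (by
#' rejection).  Uses R's global RNG stream; call `set.seed()` for
#' reproducibility.
#'
#' @inheritParams coverage_density
#' @param n Number of events to return.
#' @return Data frame with columns `s1`, `e1`, `s2`, `e2` (and `branch` for
#'   model BD), satisfying `0 <= e1 <= s1 <= l` and `0 <= s2 <= e2 <= l`.
#' @export
sample_synthesis <- function(model, params, l, n = 1L) {
  model <- match_model(model)
  p <- .check_params(model, params)
  if (l <= 0) stop("l must be > 0")
  out <- NULL
  attempts <- 0
  rate <- 0.5
  while (is.null(out) || nrow(out) < n) {
    need <- n - if (is.null(out)) 0L else nrow(out)
    m <- min(ceiling(need / max(rate, 1e-4)) + 16L, 2e6)
    ev <- .draw_events(model, p, l, m)
    attempts <- attempts + m - nrow(ev)
    if (attempts > .MAX_REJECT * max(1, n)) {
      stop("sample_synthesis: > 1e6 rejected events for model ", model,
           "; selection probability is pathologically small for these ",
           "parameters (l = ", l, ")")
    }
    rate <- max(nrow(ev) / m, 1e-4)
    out <- if (is.null(out)) ev else rbind(out, ev)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample read start positions
#'
#' Draws synthesis events and then read start positions whose marginal
#' distribution is exactly proportional to the model's closed-form
#' [coverage_density]: a uniform position on `[0, l]` is accepted with
#' probability proportional to its fragmentation weight given the event
#' (`1/d` on the fragment, plus 1 on the fragment/transcript interior).
#' Events with zero total weight are resampled.
#'
#' @inheritParams sample_synthesis
#' @return Numeric vector of `n` positions in `(0, l)`.
#' @export
sample_read <- function(model, params, l, n = 1L) {
  .sample_reads_events(model, params, l, n)$x
}

# Internal: also returns the BD branch labels of accepted reads.
.sample_reads_events <- function(model, params, l, n) {
  model <- match_model(model)
  p <- .check_params(model, params)
  if (l <= 0) stop("l must be > 0")
  wmax <- 1 / p$d + 1
  xs <- numeric(0)
  br <- character(0)
  rate <- 0.25
  attempts <- 0
  while (length(xs) < n) {
    need <- n - length(xs)
    m <- min(ceiling(need / max(rate, 1e-4)) + 16L, 2e6)
    ev <- .draw_events(model, p, l, m)
    k <- nrow(ev)
    if (k > 0) {
      x <- stats::runif(k, 0, l)
      w <- (x > ev$s2 & x < ev$e2) / p$d +
        (x > ev$s2 + p$h & x < ev$e2 - p$h & x > p$h & x < l - p$h)
      keep <- stats::runif(k) * wmax < w
      xs <- c(xs, x[keep])
      if (model == "BD") br <- c(br, ev$branch[keep])
      acc <- sum(keep)
    } else {
      acc <- 0
    }
    attempts <- attempts + m - acc
    if (attempts > .MAX_REJECT * max(1, n)) {
      stop("sample_read: acceptance rate pathologically small for model ",
           model, " (l = ", l, ")")
    }
    rate <- max(acc / m, 1e-4)
  }
  list(x = xs[seq_len(n)],
       branch = if (model == "BD") br[seq_len(n)] else NULL)
}

#' Simulation configuration
#'
#' @param model Model id.
#' @param params [model_params] used for generation.
#' @param n_transcripts Number of transcripts.
#' @param lengths Length model: `"loguniform"` (default, with
#'   `length_range`), `"fixed"` (all transcripts of length
#'   `length_range[1]`), or a numeric vector of empirical lengths to use
#'   directly (recycled/sampled to `n_transcripts`).
#' @param length_range Two-element range in bases for `"loguniform"`;
#'   defaults to `c(500, 20000)`, a skewed distribution emulating RefSeq
#'   mRNA lengths.
#' @param reads_per_transcript Scalar or per-transcript vector of exact read
#'   counts, or `NULL` when `abundance` is given.
#' @param abundance Optional relative true abundances; reads are then
#'   allocated multinomially with probability proportional to
#'   `abundance * coverage_area(length)` (the physical yield), with
#'   `total_reads` reads in total.
#' @param total_reads Total reads when `abundance` is used.
#' @param seed Integer root seed; fully determines the output.
#' @param round_positions If `TRUE`, emit integer base coordinates
#'   (`floor(x)`) instead of continuous positions.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(model, params, n_transcripts,
                       lengths = "loguniform",
                       length_range = c(500, 20000),
                       reads_per_transcript = NULL,
                       abundance = NULL, total_reads = NULL,
                       seed = 1L, round_positions = FALSE) {
  model <- match_model(model)
  params <- .check_params(model, params)
  if (n_transcripts < 1) stop("n_transcripts must be >= 1")
  if (is.null(reads_per_transcript) && is.null(abundance)) {
    stop("give reads_per_transcript or abundance + total_reads")
  }
  if (!is.null(abundance) && is.null(total_reads)) {
    stop("total_reads is required with abundance")
  }
  structure(list(model = model, params = params,
                 n_transcripts = as.integer(n_transcripts),
                 lengths = lengths, length_range = length_range,
                 reads_per_transcript = reads_per_transcript,
                 abundance = abundance, total_reads = total_reads,
                 seed = as.integer(seed),
                 round_positions = isTRUE(round_positions)),
            class = "sim_config")
}

# Deterministic per-transcript child seed from the root seed.  Keeps every
# transcript's read stream independent of the others, so the output is
# reproducible even if transcripts were generated in parallel or in a
# different order.
.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69069 + i * 104729) %% 2147483629)
}

#' Simulate a read set
#'
#' Draws transcript lengths from the configured length model and read start
#' positions from the generative library-preparation process.  Deterministic
#' given `config$seed`; true parameters are recorded in the metadata.
#'
#' @param config A [sim_config].
#' @return A [read_set].
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- config$n_transcripts
  lens <- if (is.numeric(config$lengths)) {
    v <- config$lengths
    if (length(v) == nt) v else v[1 + (seq_len(nt) - 1) %% length(v)]
  } else if (identical(config$lengths, "fixed")) {
    rep(config$length_range[1], nt)
  } else {
    lr <- config$length_range
    round(exp(stats::runif(nt, log(lr[1]), log(lr[2]))))
  }
  counts <- if (!is.null(config$abundance)) {
    areas <- coverage_area(config$model, config$params, lens)
    prob <- config$abundance * areas
    as.integer(stats::rmultinom(1, config$total_reads, prob))
  } else {
    rep_len(as.integer(config$reads_per_transcript), nt)
  }
  ids <- sprintf("T%05d", seq_len(nt))
  reads <- vector("list", nt)
  for (i in seq_len(nt)) {
    if (counts[i] > 0) {
      set.seed(.child_seed(config$seed, i))
      x <- sample_read(config$model, config$params, lens[i], counts[i])
      if (config$round_positions) x <- floor(x)
      reads[[i]] <- x
    } else {
      reads[[i]] <- numeric(0)
    }
  }
  names(reads) <- ids
  read_set(ids, lens, reads,
           metadata = list(simulated = TRUE, model = config$model,
                           params = unclass(config$params),
                           seed = config$seed,
                           round_positions = config$round_positions))
}
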