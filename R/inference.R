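# Bayesian inference of model parameters from read start positions.
#
# Adaptive random-walk Metropolis over the identifiable parameter set of
# each model, with the per-read likelihood normalized per transcript
# (read position conditioned on its transcript).  Identifiable sets:
#   A : d, h            (exp(-l*(theta1+theta2)) cancels per transcript)
#   C : theta2, d, h    (exp(-theta1*l) cancels)
#   B, D : theta1, theta2, d, h
#   E : theta1', theta2', d, h   (modified rates; alpha1*alpha2 cancels)
#   BD: theta1, theta2, d, h, alpha
# theta and d are sampled in log space; priors are log-uniform for theta
# and uniform for d, h, alpha (see fit_config).

.MODEL_CODE <- c(A = 0L, B = 1L, C = 2L, D = 3L, E = 4L, BD = 5L)

.free_params <- function(model) {
  switch(model,
    A = c("log_d", "h"),
    C = c("log_theta2", "log_d", "h"),
    B = ,
    D = ,
    E = c("log_theta1", "log_theta2", "log_d", "h"),
    BD = c("log_theta1", "log_theta2", "log_d", "h", "alpha"))
}

.natural_names <- function(model) {
  sub("^log_", "", .free_params(model))
}

.u_to_params <- function(model, u) {
  g <- function(nm, def) if (nm %in% names(u)) unname(u[nm]) else def
  model_params(
    theta1 = exp(g("log_theta1", -Inf)),
    theta2 = exp(g("log_theta2", -Inf)),
    d = exp(g("log_d", 0)),
    h = g("h", 0),
    alpha = g("alpha", 0.5))
}

#' Fit configuration
#'
#' @param model Model id to fit.
#' @param n_iterations Total MCMC iterations (default 20000).
#' @param burn_in Iterations discarded before computing posterior summaries;
#'   proposal-covariance adaptation happens only during burn-in (default
#'   5000).
#' @param max_reads_per_transcript Per-transcript read cap applied before
#'   fitting (default 100); keeps the likelihood cheap without affecting
#'   the estimates.
#' @param length_bins_for_balancing Number of equal-count transcript-length
#'   strata whose read totals are equalized before fitting (default 10), so
#'   no length range dominates the likelihood.
#' @param seed Integer seed; fully determines the fit.
#' @param subsample If `TRUE` (default), [subsample_reads] is applied inside
#'   [mcmc_fit]; set `FALSE` if the read set is already subsampled.
#' @param polish If `TRUE` (default), the reported maximum log-likelihood is
#'   refined by a short Nelder-Mead climb from the best chain state.
#' @param priors List of prior bounds: `theta` (log-uniform range for
#'   theta1/theta2, per base), `d` (uniform, the lower bound is a numerical
#'   floor for log-space sampling), `h` (uniform, bases), `alpha` (uniform).
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(model, n_iterations = 20000L, burn_in = 5000L,
                       max_reads_per_transcript = 100L,
                       length_bins_for_balancing = 10L,
                       seed = 1L, subsample = TRUE, polish = TRUE,
                       priors = list(theta = c(1e-6, 1e-2),
                                     d = c(1e-4, 100),
                                     h = c(0, 1000),
                                     alpha = c(0, 1))) {
  model <- match_model(model)
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations")
  if (max_reads_per_transcript < 1) {
    stop("max_reads_per_transcript must be >= 1")
  }
  structure(list(model = model,
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 max_reads_per_transcript = as.integer(max_reads_per_transcript),
                 length_bins_for_balancing = as.integer(length_bins_for_balancing),
                 seed = as.integer(seed), subsample = isTRUE(subsample),
                 polish = isTRUE(polish), priors = priors),
            class = "fit_config")
}

#' Cap and length-balance reads before fitting
#'
#' Two-stage subsampling: (i) at most `max_reads_per_transcript` reads are
#' kept per transcript (sampled without replacement); (ii) transcripts are
#' partitioned into `length_bins` equal-count length strata and each
#' stratum's pooled reads are downsampled to the smallest stratum's total,
#' so every length range contributes equally to the likelihood.
#'
#' @param readset A [read_set].
#' @param max_reads_per_transcript Per-transcript cap (default 100).
#' @param length_bins Number of equal-count length strata (default 10).
#' @return A [read_set] with the same transcripts and subsampled reads.
#' @export
subsample_reads <- function(readset, max_reads_per_transcript = 100L,
                            length_bins = 10L) {
  stopifnot(inherits(readset, "read_set"))
  if (n_reads(readset) == 0) stop("read set is empty")
  nt <- nrow(readset$transcripts)
  length_bins <- min(length_bins, nt)
  reads <- readset$reads
  for (i in seq_len(nt)) {
    x <- reads[[i]]
    if (length(x) > max_reads_per_transcript) {
      reads[[i]] <- x[sample.int(length(x), max_reads_per_transcript)]
    }
  }
  ord <- order(readset$transcripts$length)
  stratum <- integer(nt)
  stratum[ord] <- if (length_bins > 1) {
    as.integer(cut(seq_len(nt), length_bins, labels = FALSE))
  } else {
    rep(1L, nt)
  }
  totals <- vapply(seq_len(length_bins), function(s) {
    sum(lengths(reads[stratum == s]))
  }, numeric(1))
  if (any(totals == 0)) {
    warning(sum(totals == 0), " length stratum/strata contain no reads; ",
            "dropped from balancing")
  }
  target <- min(totals[totals > 0])
  for (s in which(totals > target)) {
    members <- which(stratum == s)
    pool_t <- rep(members, lengths(reads[members]))
    keep <- sample.int(length(pool_t), target)
    for (i in members) {
      sel <- which(pool_t == i) %in% keep
      reads[[i]] <- reads[[i]][sel]
    }
  }
  read_set(readset$transcripts$id, readset$transcripts$length, reads,
           metadata = c(readset$metadata,
                        list(subsampled = TRUE,
                             max_reads_per_transcript = max_reads_per_transcript,
                             length_bins = length_bins)))
}

# Flatten a read set for the C++ likelihood: positions, 0-based transcript
# index per read, per-transcript lengths and counts.  Positions exactly at 0
# are nudged inward so model E's vanishing boundary density cannot produce
# spurious -Inf for base-resolution input.
.flatten_readset <- function(rs) {
  n <- vapply(rs$reads, length, integer(1))
  lens <- rs$transcripts$length
  x <- unlist(rs$reads, use.names = FALSE)
  lread <- rep(lens, n)
  x[x == 0] <- lread[x == 0] * 1e-9
  list(x = x,
       tidx = rep(seq_along(n) - 1L, n),
       ulen = as.numeric(lens),
       ucount = as.numeric(n))
}

#' Dataset log-likelihood
#'
#' Sum over reads of the per-read log-likelihood
#' `log(coverage_density(x)/coverage_area(l))`.  Returns `-Inf` for
#' degenerate parameters (zero/non-finite area or zero density at an
#' observed read), so MCMC proposals there are rejected.
#'
#' @param readset A [read_set] (empty read set gives 0).
#' @param model Model id.
#' @param params [model_params].
#' @param engine `"cpp"` (fast path, default) or `"r"` (reference closed
#'   forms); both give identical values.
#' @return Numeric scalar.
#' @export
dataset_log_likelihood <- function(readset, model, params,
                                   engine = c("cpp", "r")) {
  stopifnot(inherits(readset, "read_set"))
  engine <- match.arg(engine)
  model <- match_model(model)
  params <- .check_params(model, params)
  if (n_reads(readset) == 0) return(0)
  if (engine == "r") {
    lens <- readset$transcripts$length
    return(sum(vapply(seq_along(readset$reads), function(i) {
      x <- readset$reads[[i]]
      if (!length(x)) return(0)
      x[x == 0] <- lens[i] * 1e-9
      sum(read_log_likelihood(model, params, x, lens[i]))
    }, numeric(1))))
  }
  fl <- .flatten_readset(readset)
  p <- params
  if (model == "E") {
    r <- .e_rates(p)
    cov_loglik_cpp(.MODEL_CODE[[model]], r[["t1p"]], r[["t2p"]],
                   p$d, p$h, p$alpha, fl$x, fl$tidx, fl$ulen, fl$ucount)
  } else {
    cov_loglik_cpp(.MODEL_CODE[[model]], p$theta1, p$theta2,
                   p$d, p$h, p$alpha, fl$x, fl$tidx, fl$ulen, fl$ucount)
  }
}

# Fast likelihood closure over flattened data, in sampling (u) space.
.make_loglik_u <- function(model, fl) {
  code <- .MODEL_CODE[[model]]
  function(u) {
    p <- .u_to_params(model, u)
    cov_loglik_cpp(code, p$theta1, p$theta2, p$d, p$h, p$alpha,
                   fl$x, fl$tidx, fl$ulen, fl$ucount)
  }
}

# Log-prior in sampling space; -Inf outside the support.  The only
# non-constant term is the log-d Jacobian (d itself is uniform a priori but
# proposed in log space).
.make_logprior_u <- function(model, priors) {
  nms <- .free_params(model)
  lt <- log(priors$theta)
  ld <- log(priors$d)
  hb <- priors$h
  ab <- priors$alpha
  function(u) {
    for (nm in nms) {
      v <- u[[nm]]
      ok <- switch(nm,
        log_theta1 = ,
        log_theta2 = v >= lt[1] && v <= lt[2],
        log_d = v >= ld[1] && v <= ld[2],
        h = v >= hb[1] && v <= hb[2],
        alpha = v >= ab[1] && v <= ab[2])
      if (!ok) return(-Inf)
    }
    u[["log_d"]]
  }
}

.draw_prior_u <- function(model, priors) {
  nms <- .free_params(model)
  u <- vapply(nms, function(nm) {
    switch(nm,
      log_theta1 = ,
      log_theta2 = stats::runif(1, log(priors$theta[1]), log(priors$theta[2])),
      log_d = log(stats::runif(1, priors$d[1], priors$d[2])),
      h = stats::runif(1, priors$h[1], priors$h[2]),
      alpha = stats::runif(1, priors$alpha[1], priors$alpha[2]))
  }, numeric(1))
  names(u) <- nms
  u
}

# Split-chain potential scale reduction factor from the post-burn-in chain.
.split_rhat <- function(v) {
  m <- floor(length(v) / 2)
  h1 <- v[seq_len(m)]
  h2 <- v[seq_len(m) + m]
  W <- (stats::var(h1) + stats::var(h2)) / 2
  B <- m * stats::var(c(mean(h1), mean(h2)))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Fit a coverage model by adaptive-Metropolis MCMC
#'
#' Random-walk Metropolis over the model's identifiable parameters, with
#' proposal-covariance adaptation during burn-in (frozen afterwards).  The
#' chain is initialized at the best of a set of prior draws followed by a
#' short Nelder-Mead climb, then sampled for `n_iterations`.  Fully
#' deterministic given `config$seed`.
#'
#' @param readset A [read_set]; subsampled internally per `config` unless
#'   `config$subsample` is `FALSE`.
#' @param config A [fit_config].
#' @return Object of class `posterior_summary`: natural-scale `chains`
#'   (matrix, all iterations), per-parameter posterior `median` and `mad`
#'   (raw median absolute deviation, post-burn-in only), `max_log_likelihood`,
#'   `acceptance_rate`, split-chain `rhat`, `n_data` (reads used) and the
#'   data checksum used by [compare_models].
#' @export
mcmc_fit <- function(readset, config) {
  stopifnot(inherits(readset, "read_set"), inherits(config, "fit_config"))
  model <- config$model
  set.seed(config$seed)
  rs <- if (config$subsample) {
    subsample_reads(readset, config$max_reads_per_transcript,
                    config$length_bins_for_balancing)
  } else {
    readset
  }
  fl <- .flatten_readset(rs)
  loglik <- .make_loglik_u(model, fl)
  logprior <- .make_logprior_u(model, config$priors)
  nms <- .free_params(model)
  p <- length(nms)

  logpost <- function(u) {
    lp <- logprior(u)
    if (!is.finite(lp)) return(c(-Inf, -Inf))
    ll <- loglik(u)
    c(lp + ll, ll)
  }

  # initialization: evaluate a spread of prior draws, climb from the best
  # few by Nelder-Mead, start the chain at the overall best.  The posterior
  # can have minor modes (e.g. h ~ 0 with a large d absorbing the end
  # effect), so a multi-start climb is used rather than a single one.
  draws <- lapply(seq_len(64), function(i) .draw_prior_u(model, config$priors))
  lps <- vapply(draws, function(u) logpost(u)[1], numeric(1))
  tries <- 64
  while (all(!is.finite(lps)) && tries < 164) {
    draws <- c(draws, list(.draw_prior_u(model, config$priors)))
    lps <- c(lps, logpost(draws[[length(draws)]])[1])
    tries <- tries + 1
  }
  if (all(!is.finite(lps))) {
    stop("mcmc_fit: no finite-likelihood initialization found in ",
         tries, " prior draws for model ", model,
         "; check the read set and prior bounds")
  }
  negpost <- function(u) {
    names(u) <- nms
    v <- logpost(u)[1]
    if (is.finite(v)) -v else 1e12
  }
  starts <- draws[order(-lps)[seq_len(min(3, sum(is.finite(lps))))]]
  best <- starts[[1]]
  best_lp <- max(lps, na.rm = TRUE)
  for (s in starts) {
    # restarted Nelder-Mead: single runs stall before reaching the right
    # basin in >= 4 dimensions, which can strand the chain in a minor mode
    u <- s
    prev <- Inf
    for (round in 1:6) {
      opt <- tryCatch(
        stats::optim(u, negpost, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value)) break
      u <- opt$par
      names(u) <- nms
      if (prev - opt$value < 0.5) break
      prev <- opt$value
    }
    if (!is.null(opt) && is.finite(opt$value) && -opt$value > best_lp) {
      best_lp <- -opt$value
      best <- u
    }
  }

  n_iter <- config$n_iterations
  burn <- config$burn_in
  U <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, nms))
  LL <- numeric(n_iter)
  cur <- best
  curv <- logpost(cur)
  # robust adaptive Metropolis: the proposal Cholesky factor is updated by
  # rank-one corrections toward a 23% acceptance rate during burn-in and
  # frozen afterwards
  scales <- vapply(nms, function(nm) {
    switch(nm, h = 10, alpha = 0.05, 0.1)
  }, numeric(1))
  L <- diag(scales, p)
  target <- 0.234
  accepted <- 0
  for (it in seq_len(n_iter)) {
    z <- stats::rnorm(p)
    prop <- cur + as.numeric(L %*% z)
    names(prop) <- nms
    pv <- logpost(prop)
    aprob <- if (is.finite(pv[1])) min(1, exp(pv[1] - curv[1])) else 0
    if (stats::runif(1) < aprob) {
      cur <- prop
      curv <- pv
      accepted <- accepted + 1
    }
    U[it, ] <- cur
    LL[it] <- curv[2]
    if (it <= burn) {
      eta <- min(0.7, p * it^(-2 / 3))
      zz <- z / sqrt(sum(z^2))
      M <- L %*% (diag(p) + eta * (aprob - target) * tcrossprod(zz)) %*% t(L)
      ch <- tryCatch(chol(M), error = function(e) NULL)
      if (!is.null(ch)) L <- t(ch)
    }
  }

  post <- U[(burn + 1):n_iter, , drop = FALSE]
  natural <- U
  chains <- matrix(NA_real_, n_iter, p,
                   dimnames = list(NULL, .natural_names(model)))
  for (j in seq_len(p)) {
    chains[, j] <- if (grepl("^log_", nms[j])) exp(natural[, j]) else
      natural[, j]
  }
  post_nat <- chains[(burn + 1):n_iter, , drop = FALSE]
  med <- apply(post_nat, 2, stats::median)
  mad_ <- apply(post_nat, 2, function(v) stats::median(abs(v - stats::median(v))))
  rhat <- apply(post, 2, .split_rhat)
  names(rhat) <- .natural_names(model)
  if (any(is.finite(rhat) & rhat > 1.1)) {
    warning("mcmc_fit(", model, "): split-chain R-hat > 1.1 for ",
            paste(names(rhat)[is.finite(rhat) & rhat > 1.1], collapse = ", "),
            "; consider longer chains")
  }

  max_ll <- max(LL)
  if (config$polish) {
    negll <- function(u) {
      names(u) <- nms
      if (!is.finite(logprior(u))) return(1e12)
      v <- loglik(u)
      if (is.finite(v)) -v else 1e12
    }
    # restarted Nelder-Mead: a single run stalls in >= 4 dimensions when
    # the simplex degenerates, which biases likelihood-ratio comparisons
    u0 <- U[which.max(LL), ]
    names(u0) <- nms
    prev <- -max_ll
    for (round in 1:5) {
      popt <- tryCatch(
        stats::optim(u0, negll, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(popt) || !is.finite(popt$value)) break
      u0 <- popt$par
      names(u0) <- nms
      if (prev - popt$value < 0.01) { prev <- min(prev, popt$value); break }
      prev <- popt$value
    }
    max_ll <- max(max_ll, -prev)
  }

  structure(list(model = model,
                 chains = chains,
                 burn_in = burn,
                 n_iterations = n_iter,
                 median = med,
                 mad = mad_,
                 max_log_likelihood = max_ll,
                 acceptance_rate = accepted / n_iter,
                 rhat = rhat,
                 n_data = n_reads(rs),
                 n_free = p,
                 data_checksum = .readset_checksum(rs),
                 seed = config$seed),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("posterior_summary: model ", x$model, ", ", x$n_data, " reads, ",
      x$n_iterations, " iterations (burn-in ", x$burn_in, ")\n", sep = "")
  tab <- rbind(median = signif(x$median, 4), mad = signif(x$mad, 4),
               rhat = round(x$rhat, 3))
  print(tab)
  cat("max log-likelihood:", format(x$max_log_likelihood),
      " acceptance rate:", round(x$acceptance_rate, 3), "\n")
  invisible(x)
}

#' Rank fitted models by likelihood
#'
#' Orders fits by maximum log-likelihood and reports pairwise log-likelihood
#' ratios.  A model with more free parameters outranks one with fewer only
#' if its log-likelihood advantage is significant by a likelihood-ratio test
#' at `conf_level` (twice the advantage exceeding the chi-square quantile at
#' the difference in free-parameter counts); otherwise the tie is broken
#' toward the more parsimonious model.
#'
#' @param readset The [read_set] all fits were computed on (used to verify
#'   identity), or `NULL` to verify the fits against each other only.
#' @param fits List of `posterior_summary` objects.
#' @param conf_level Confidence level of the parsimony tie-break (default
#'   0.95).
#' @return Object of class `model_ranking`: a data frame with columns
#'   `rank`, `model`, `max_log_likelihood`, `n_free`, `log_ratio_vs_best`,
#'   plus a `pairwise` attribute with the matrix of log-likelihood ratios.
#' @export
compare_models <- function(readset = NULL, fits, conf_level = 0.95) {
  if (inherits(fits, "posterior_summary")) fits <- list(fits)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "posterior_summary")))
  sums <- vapply(fits, `[[`, character(1), "data_checksum")
  if (length(unique(sums)) != 1L) {
    stop("fits were computed on different (subsampled) read sets; refit ",
         "all models on one shared read set")
  }
  if (!is.null(readset)) {
    stopifnot(inherits(readset, "read_set"))
    if (.readset_checksum(readset) != sums[1]) {
      stop("supplied read set does not match the data the fits used")
    }
  }
  models <- vapply(fits, `[[`, character(1), "model")
  ll <- vapply(fits, `[[`, numeric(1), "max_log_likelihood")
  npar <- vapply(fits, `[[`, numeric(1), "n_free")
  ord <- order(-ll)
  k <- length(ord)
  repeat {
    swapped <- FALSE
    for (i in seq_len(k - 1)) {
      a <- ord[i]; b <- ord[i + 1]
      if (npar[a] > npar[b] &&
          2 * (ll[a] - ll[b]) <
            stats::qchisq(conf_level, max(npar[a] - npar[b], 1))) {
        ord[i] <- b; ord[i + 1] <- a
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  out <- data.frame(rank = seq_len(k),
                    model = models[ord],
                    max_log_likelihood = ll[ord],
                    n_free = npar[ord],
                    log_ratio_vs_best = ll[ord] - ll[ord[1]],
                    stringsAsFactors = FALSE)
  pw <- outer(ll[ord], ll[ord], `-`)
  dimnames(pw) <- list(models[ord], models[ord])
  attr(out, "pairwise") <- pw
  class(out) <- c("model_ranking", "data.frame")
  out
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("model ranking (best first):\n")
  print.data.frame(x)
  invisible(x)
}

#' Serialize a fit
#'
#' Writes the posterior summary as JSON and, optionally, the full
#' natural-scale chains as TSV.
#'
#' @param fit A `posterior_summary`.
#' @param path JSON output file.
#' @param chains_path Optional TSV for the chains.
#' @export
write_fit_summary <- function(fit, path, chains_path = NULL) {
  stopifnot(inherits(fit, "posterior_summary"))
  out <- fit[c("model", "burn_in", "n_iterations", "median", "mad",
               "max_log_likelihood", "acceptance_rate", "rhat",
               "n_data", "n_free", "data_checksum", "seed")]
  out$median <- as.list(out$median)
  out$mad <- as.list(out$mad)
  out$rhat <- as.list(out$rhat)
  .atomic_write(path, function(tmp) {
    jsonlite::write_json(out, tmp, auto_unbox = TRUE, digits = NA)
  })
  if (!is.null(chains_path)) {
    .atomic_write(chains_path, function(tmp) {
      data.table::fwrite(as.data.frame(fit$chains), tmp, sep = "\t")
    })
  }
  invisible(path)
}

#' @rdname write_fit_summary
#' @param path JSON file written by `write_fit_summary`.
#' @export
read_fit_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$median <- unlist(x$median)
  x$mad <- unlist(x$mad)
  x$rhat <- unlist(x$rhat)
  x$chains <- NULL
  structure(x, class = "posterior_summary")
}
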