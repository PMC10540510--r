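## Marginal likelihoods via sequential data-block bridging with a
## Wang-Landau mixture estimator, and Bayes-factor model selection.

#' Marginal likelihood of a locus under one model
#'
#' Partitions the alignment into equally sized site blocks and applies the
#' Wang-Landau mixture method recursively: step i runs a two-component
#' mixture chain whose surrogate is the posterior given blocks 1..(i-1)
#' (the prior at i = 1) and whose target is the posterior given blocks
#' 1..i.  An adaptive log-weight is tuned by a flat-histogram schedule to
#' equalize component occupancy; at convergence it estimates
#' log P(Y_1:i) - log P(Y_1:(i-1)).  The block estimates sum to
#' log P(Y | M).
#'
#' @inheritParams run_chain
#' @return list with \code{logml}, \code{se}, \code{block_ratios},
#'   \code{converged} (per block), \code{model_id}, \code{method}.
#' @export
marginal_likelihood_wl <- function(locus, st, model_id = "M0",
                                   config = chain_config(), seed = 1L,
                                   method = c("gt", "st")) {
  method <- match.arg(method)
  set.seed(seed)
  l <- locus$length
  if (is.null(l) || l == 0L) {
    return(list(logml = 0, se = 0, block_ratios = numeric(0),
                converged = logical(0), model_id = model_id,
                method = method))
  }
  b <- max(1L, ceiling(l / config$block_size))
  blocks <- if (b == 1L) list(seq_len(l)) else
    split(seq_len(l), cut(seq_len(l), b, labels = FALSE))
  state <- .init_state(locus, st, model_id, config, method)
  state <- .prior_state_draw(state)
  ratios <- numeric(b)
  ses <- numeric(b)
  conv <- logical(b)
  block_ll <- function(sites) {
    if (method == "gt") {
      locus_loglik_pruning(state$locus, state$G, state$st, state$Z,
                           c(1, state$r1, state$r2), state$model,
                           cmap = state$cmap, sites = sites)
    } else {
      species_tree_loglik(state$locus, state$st, state$Z,
                          c(1, state$r1, state$r2), state$model,
                          sites = sites)
    }
  }
  for (i in seq_len(b)) {
    surro <- if (i == 1L) integer(0) else unlist(blocks[seq_len(i - 1L)])
    target <- unlist(blocks[seq_len(i)])
    blk <- blocks[[i]]
    ## initialize the log-weight near the target ratio with a short
    ## posterior-conditioned sweep (the schedule converges from any start;
    ## this only removes the initial random-walk transient)
    state$sites <- target
    state <- .gibbs_sweep(state)
    w <- block_ll(blk)
    delta <- config$wl_step0
    n0 <- 0; n1 <- 0; cnt <- 0L
    comp <- 1L
    stage_ends <- numeric(0)   # w at each flattening event
    it <- 0L
    while (it < config$wl_max_iter) {
      it <- it + 1L
      state$sites <- if (comp == 1L) target else surro
      state <- if (length(state$sites) == 0L) .prior_sweep(state) else
        .gibbs_sweep(state)
      llb <- block_ll(blk)
      p1 <- stats::plogis(llb - w)
      comp <- as.integer(stats::runif(1L) < p1)
      ## Rao-Blackwellized weight update: the expected occupancy
      ## (2*p1 - 1) replaces the sampled indicator, removing the binary
      ## noise while keeping the flat-histogram fixed point E[p1] = 1/2
      w <- w + delta * (2 * p1 - 1)
      n1 <- n1 + p1
      n0 <- n0 + (1 - p1)
      cnt <- cnt + 1L
      if (cnt >= config$wl_check) {
        ## windowed flat-histogram criterion
        if (abs(n1 - n0) / (n0 + n1) < config$wl_flat) {
          delta <- delta / 2
          stage_ends <- c(stage_ends, w)
        }
        n0 <- 0; n1 <- 0; cnt <- 0L
        if (delta < config$wl_step_min) break
      }
    }
    conv[i] <- delta < config$wl_step_min
    ## average the late-stage weights: the endpoint alone is noisier
    ratios[i] <- mean(c(utils::tail(stage_ends, 3L), w))
    tail_w <- utils::tail(stage_ends, 5L)
    ses[i] <- if (length(tail_w) > 1L) stats::sd(tail_w) else
      max(delta, config$wl_step0 / 4)
    if (!conv[i]) ses[i] <- ses[i] * 5   # occupancy never flattened
  }
  list(logml = sum(ratios), se = sqrt(sum(ses^2)), block_ratios = ratios,
       converged = conv, model_id = model_id, method = method)
}

#' Bayes factors and model selection
#'
#' \code{logBF1 = logP(Y|M1) - logP(Y|M0)} (target-restricted vs null),
#' \code{logBF2 = logP(Y|M1) - logP(Y|M2)} (target-restricted vs full),
#' \code{logBF3 = logP(Y|M2) - logP(Y|M0) = logBF1 - logBF2}.  With a
#' target set, M1 is selected when logBF1 and logBF2 exceed their
#' cutoffs; without targets, "accelerated somewhere" (M2) is called when
#' logBF3 exceeds its cutoff; otherwise the model with the maximum
#' marginal likelihood is reported.
#'
#' @param logml named numeric of log marginal likelihoods: entries among
#'   \code{M0}, \code{M1}, \code{M2}.
#' @param se optional named numeric of MC standard errors.
#' @param cutoffs numeric \code{c(bf1, bf2, bf3)} log-scale cutoffs;
#'   defaults \code{c(10, 0, 0)} for the gene-tree mode (use
#'   \code{c(20, 0, 0)} for species-tree mode).
#' @param has_targets whether a target set was specified.
#' @return an \code{evidence_result} list: the marginals, logBF1/2/3,
#'   \code{selected}, and \code{se}.
#' @export
bayes_factors <- function(logml, se = NULL, cutoffs = c(10, 0, 0),
                          has_targets = TRUE) {
  need <- if (has_targets) c("M0", "M1", "M2") else c("M0", "M2")
  miss <- setdiff(need, names(logml))
  if (length(miss)) stop("missing marginal for ", paste(miss, collapse = ","))
  bf1 <- if (all(c("M0", "M1") %in% names(logml)))
    logml[["M1"]] - logml[["M0"]] else NA_real_
  bf2 <- if (all(c("M1", "M2") %in% names(logml)))
    logml[["M1"]] - logml[["M2"]] else NA_real_
  bf3 <- if (all(c("M0", "M2") %in% names(logml)))
    logml[["M2"]] - logml[["M0"]] else NA_real_
  selected <- if (has_targets && !is.na(bf1) && !is.na(bf2) &&
                  bf1 > cutoffs[1L] && bf2 > cutoffs[2L]) {
    "M1"
  } else if (!has_targets && !is.na(bf3) && bf3 > cutoffs[3L]) {
    "M2"
  } else {
    names(logml)[which.max(unlist(logml))]
  }
  structure(list(logml = logml, logBF1 = bf1, logBF2 = bf2, logBF3 = bf3,
                 selected = selected, se = se, cutoffs = cutoffs,
                 has_targets = has_targets),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat("Model evidence (log marginal likelihoods):\n")
  for (m in names(x$logml)) cat(sprintf("  %s: %.3f\n", m, x$logml[[m]]))
  cat(sprintf("  logBF1 = %.3f  logBF2 = %.3f  logBF3 = %.3f\n",
              x$logBF1, x$logBF2, x$logBF3))
  cat("  selected:", x$selected, "\n")
  invisible(x)
}

#' Fit one locus: marginal likelihoods, Bayes factors, acceleration calls
#'
#' Runs the requested models (all three when targets are specified, M0 and
#' M2 otherwise), computes Bayes factors, and estimates per-branch
#' posterior acceleration probabilities with a posterior chain under the
#' relevant alternative model.
#'
#' @inheritParams run_chain
#' @param cutoffs log Bayes-factor cutoffs (see \code{\link{bayes_factors}}).
#' @param models optional character subset of models to run.
#' @return list with \code{evidence}, \code{pp_accel}, \code{calls}
#'   (from \code{\link{call_acceleration}}), \code{chain} (the posterior
#'   chain summary), \code{method}.
#' @export
fit_locus <- function(locus, st, config = chain_config(), seed = 1L,
                      method = c("gt", "st"), cutoffs = NULL,
                      models = NULL) {
  method <- match.arg(method)
  has_targets <- length(st$target) > 0L
  if (is.null(models)) {
    models <- if (has_targets) c("M0", "M1", "M2") else c("M0", "M2")
  }
  if (is.null(cutoffs)) {
    cutoffs <- if (method == "gt") c(10, 0, 0) else c(20, 0, 0)
  }
  logml <- numeric(0)
  se <- numeric(0)
  for (k in seq_along(models)) {
    m <- models[k]
    ml <- marginal_likelihood_wl(locus, st, m, config, seed + k, method)
    logml[m] <- ml$logml
    se[m] <- ml$se
  }
  alt <- if (has_targets && "M1" %in% models) "M1" else "M2"
  ch <- run_chain(locus, st, alt, config, seed + 97L, method)
  ev <- bayes_factors(logml, se, cutoffs, has_targets)
  calls <- call_acceleration(ch$pp_accel, st)
  list(evidence = ev, pp_accel = ch$pp_accel, calls = calls, chain = ch,
       method = method)
}
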