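# Black-box optimization of the five pipeline parameters (maxdiffs,
# maxdiffpct, maxee, minampsize, identity), maximizing reads matched to the
# amplicon database.  Sequential model-based minimization with a Gaussian
# process surrogate and expected-improvement acquisition; a seeded
# random-search fallback is selectable.

#' Parameter space for pipeline optimization
#'
#' Bounds default to the published search intervals: maxdiffs (5, 82),
#' maxdiffpct (2, 30), maxee (0.25, 1.5), minampsize (2, 30),
#' identity (0.99, 1).  maxdiffs and minampsize are flagged integral and
#' floored at use.
#'
#' @param bounds named list parameter -> c(low, high).
#' @param integral character vector of parameters floored to integers when
#'   the objective is evaluated.
#' @return object of class `param_space`.
#' @export
param_space <- function(bounds = list(maxdiffs = c(5, 82),
                                      maxdiffpct = c(2, 30),
                                      maxee = c(0.25, 1.5),
                                      minampsize = c(2, 30),
                                      identity = c(0.99, 1)),
                        integral = c("maxdiffs", "minampsize")) {
  stopifnot(length(bounds) >= 1)
  for (b in bounds) stopifnot(length(b) == 2, b[1] < b[2])
  structure(list(bounds = bounds, integral = integral), class = "param_space")
}

params_from_vector <- function(x, space) {
  p <- as.list(x)
  names(p) <- names(space$bounds)
  p
}

#' Pipeline objective: negative reads matched to the amplicon database
#'
#' Runs [run_chain()] with the given parameter values and returns minus the
#' total number of reads contained in Amps that match the amplicon
#' database, so that minimizing the objective maximizes matched reads.
#' Stage failures return the worst score (0 matched reads) with a warning,
#' keeping the objective total for the optimizer.
#'
#' @param params named list/vector with `maxdiffs`, `maxdiffpct`, `maxee`,
#'   `minampsize`, `identity` (any subset; missing ones use defaults).
#' @param samples,db as in [run_chain()].  For optimization mirroring the
#'   published protocol, pass WT lines only (`wt_only` with `meta` enforces
#'   this).
#' @param meta optional [line_metadata()]; with `wt_only = TRUE`, samples
#'   are restricted to lines whose generation is `"WT"`.
#' @param wt_only restrict to WT lines (requires `meta`).
#' @return negative matched-read count (scalar).
#' @export
pipeline_objective <- function(params, samples, db, meta = NULL,
                               wt_only = FALSE) {
  if (wt_only) {
    if (is.null(meta)) stop("wt_only = TRUE requires `meta`")
    wt_ids <- meta$line_id[meta$generation == "WT"]
    samples <- Filter(function(s) s$line_id %in% wt_ids, samples)
    if (!length(samples)) stop("no WT samples to optimize on")
  }
  p <- as.list(params)
  pp <- pipeline_params(
    merge = merge_params(maxdiffs = floor(p$maxdiffs %||% 5),
                         maxdiffpct = p$maxdiffpct %||% 25),
    filter = filter_params(maxee = p$maxee %||% 1),
    denoise = denoise_params(minampsize = floor(p$minampsize %||% 8)),
    search = search_params(identity = p$identity %||% 0.99))
  res <- tryCatch(run_chain(samples, pp, db = db),
                  error = function(e) {
                    warning("objective evaluation failed: ",
                            conditionMessage(e))
                    NULL
                  })
  if (is.null(res) || is.na(res$matched_reads)) return(0)
  -res$matched_reads
}

# --- Gaussian-process surrogate (zero mean, squared-exponential kernel) ---

gp_fit <- function(X, y) {
  # X in [0,1]^d; y standardized internally.  Length-scale and noise chosen
  # by grid-search marginal likelihood: small, robust, dependency-free.
  mu <- mean(y); sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- 1
  ys <- (y - mu) / sdy
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  best <- NULL
  for (ell in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    for (sn2 in c(1e-6, 1e-4, 1e-2)) {
      K <- exp(-D2 / (2 * ell^2)) + diag(sn2, n)
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) next
      alpha <- backsolve(ch, forwardsolve(t(ch), ys))
      nll <- 0.5 * sum(ys * alpha) + sum(log(diag(ch)))
      if (is.null(best) || nll < best$nll)
        best <- list(ell = ell, sn2 = sn2, ch = ch, alpha = alpha, nll = nll)
    }
  }
  c(best, list(X = X, mu = mu, sdy = sdy))
}

gp_predict <- function(fit, Xnew) {
  # cross-covariances: exp(-||x - x'||^2 / (2 ell^2))
  cross <- matrix(0, nrow(Xnew), nrow(fit$X))
  for (j in seq_len(nrow(fit$X))) {
    d2 <- rowSums((Xnew - matrix(fit$X[j, ], nrow(Xnew), ncol(Xnew),
                                 byrow = TRUE))^2)
    cross[, j] <- exp(-d2 / (2 * fit$ell^2))
  }
  mean_s <- cross %*% fit$alpha
  v <- forwardsolve(t(fit$ch), t(cross))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = as.numeric(mean_s) * fit$sdy + fit$mu,
       sd = sqrt(var_s) * fit$sdy)
}

expected_improvement <- function(mu, sd, best) {
  imp <- best - mu
  z <- imp / sd
  ei <- imp * pnorm(z) + sd * dnorm(z)
  ei[sd <= 0] <- 0
  ei
}

#' Bayesian optimization over a bounded parameter box
#'
#' Sequential model-based minimization: a seeded Latin-hypercube initial
#' design, a Gaussian-process surrogate refit after every evaluation, and
#' an expected-improvement acquisition optimized over seeded random
#' candidates.  `method = "random"` gives plain seeded random search (the
#' documented fallback).  Deterministic for a fixed seed.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a scalar to minimize.
#' @param space a [param_space()].
#' @param budget total number of objective evaluations (must be at least
#'   dimension + 2).
#' @param seed integer seed.
#' @param method `"gp"` (default) or `"random"`.
#' @param n_init initial design size (default `max(5, 2 * d)`, capped at
#'   budget - 1).
#' @param n_candidates acquisition candidate count per iteration.
#' @return object of class `opt_result`: list with `best_params`,
#'   `best_score`, and `trace` (data.frame `iteration`, one column per
#'   parameter, `score`).
#' @export
bayes_optimize <- function(objective, space = param_space(), budget = 50,
                           seed = 1, method = c("gp", "random"),
                           n_init = NULL, n_candidates = 500) {
  method <- match.arg(method)
  d <- length(space$bounds)
  if (budget < d + 2) stop("budget too small: need at least dimension + 2")
  lo <- vapply(space$bounds, `[`, numeric(1), 1)
  hi <- vapply(space$bounds, `[`, numeric(1), 2)
  unscale <- function(U) sweep(sweep(U, 2, hi - lo, "*"), 2, lo, "+")
  eval_at <- function(u) {
    x <- as.numeric(lo + u * (hi - lo))
    objective(params_from_vector(x, space))
  }

  with_seed(split_seed(seed, 4L), {
    if (is.null(n_init)) n_init <- min(max(5L, 2L * d), budget - 1L)
    if (method == "random") n_init <- budget
    # Latin hypercube initial design
    U <- vapply(seq_len(d), function(j) (sample(n_init) - runif(n_init)) / n_init,
                numeric(n_init))
    U <- matrix(U, nrow = n_init)
    y <- apply(U, 1, eval_at)

    if (method == "gp") {
      while (nrow(U) < budget) {
        fit <- gp_fit(U, y)
        cand <- matrix(runif(n_candidates * d), ncol = d)
        pr <- gp_predict(fit, cand)
        ei <- expected_improvement(pr$mean, pr$sd, min(y))
        pick <- which.max(ei)
        u <- cand[pick, , drop = FALSE]
        U <- rbind(U, u)
        y <- c(y, eval_at(as.numeric(u)))
      }
    }

    X <- unscale(U)
    colnames(X) <- names(space$bounds)
    trace <- data.frame(iteration = seq_along(y), X, score = y)
    best <- which.min(y)
    structure(list(best_params = params_from_vector(X[best, ], space),
                   best_score = y[best], trace = trace),
              class = "opt_result")
  })
}

#' @export
print.opt_result <- function(x, ...) {
  cat("Optimization result over", nrow(x$trace), "evaluations\n")
  cat("  best score:", x$best_score, "\n  best parameters:\n")
  for (nm in names(x$best_params))
    cat(sprintf("    %-12s %g\n", nm, x$best_params[[nm]]))
  invisible(x)
}

#' Convergence trace of an optimization run
#'
#' @param x an `opt_result`.
#' @return data.frame `iteration`, `score`, `best_so_far`.
#' @export
convergence_trace <- function(x) {
  stopifnot(inherits(x, "opt_result"))
  data.frame(iteration = x$trace$iteration, score = x$trace$score,
             best_so_far = cummin(x$trace$score))
}
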