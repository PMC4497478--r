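## Shuffled Complex Evolution (SCE-UA, Duan et al. 1992/1993) global
## maximizer. Population of p complexes of m points; each complex evolves by
## competitive complex evolution (simplex reflection / contraction / random
## replacement on triangularly-weighted subcomplexes), then complexes are
## shuffled. Deterministic under a fixed seed.

#' SCE configuration
#'
#' @param n_complexes number of complexes (>= 1).
#' @param points_per_complex points per complex; default `2 * dim + 1`
#'   when `NULL` (resolved inside [sce_maximize()]).
#' @param max_evaluations objective evaluation budget.
#' @param convergence_tolerance relative improvement of the incumbent over
#'   `convergence_loops` shuffling loops below which the search stops.
#' @param convergence_loops window for the convergence check.
#' @param rng_seed integer seed; identical seed gives an identical trace.
#' @param transform optional function applied to a parameter vector before
#'   each objective evaluation (e.g. snapping a rooting depth to the layer
#'   grid); the trace stores raw (untransformed) parameters.
#' @return object of class `sce_config`.
#' @export
sce_config <- function(n_complexes = 3, points_per_complex = NULL,
                       max_evaluations = 3000,
                       convergence_tolerance = 1e-8,
                       convergence_loops = 10,
                       rng_seed = 1L, transform = NULL) {
  if (n_complexes < 1) stop("n_complexes must be >= 1")
  structure(list(n_complexes = n_complexes,
                 points_per_complex = points_per_complex,
                 max_evaluations = max_evaluations,
                 convergence_tolerance = convergence_tolerance,
                 convergence_loops = convergence_loops,
                 rng_seed = rng_seed, transform = transform),
            class = "sce_config")
}

#' Shuffled complex evolution maximization
#'
#' Maximizes `objective` over a box. Points proposed outside the bounds are
#' replaced by uniform draws inside the box; objectives returning non-finite
#' values are treated as failures and the point is discarded with a warning
#' counter. The running best score is non-decreasing by construction.
#'
#' @param objective function mapping a parameter vector to a finite score
#'   (larger is better).
#' @param lower,upper numeric bounds of equal length.
#' @param config an [sce_config()].
#' @param init optional matrix (rows = points) injected into the initial
#'   population, e.g. an incumbent from a previous optimization.
#' @return list with `best_par`, `best_score`, `n_evaluations`,
#'   `n_failures` and `trace` (data.frame: evaluation index, score, running
#'   best).
#' @export
sce_maximize <- function(objective, lower, upper, config = sce_config(),
                         init = NULL) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  d <- length(lower)
  p <- config$n_complexes
  m <- if (is.null(config$points_per_complex)) 2L * d + 1L
       else as.integer(config$points_per_complex)
  if (m < d + 1L) stop("points_per_complex must be at least dim + 1")
  q <- d + 1L                       # subcomplex size
  alpha_steps <- 1L                 # evolution steps per subcomplex
  beta_steps <- m                   # subcomplexes evolved per complex pass
  trans <- if (is.null(config$transform)) identity else config$transform

  n_eval <- 0L
  n_fail <- 0L
  tr_idx <- integer(0); tr_score <- numeric(0); tr_best <- numeric(0)
  best_score <- -Inf
  best_par <- rep(NA_real_, d)
  evalf <- function(x) {
    s <- tryCatch(objective(trans(x)), error = function(e) NaN)
    n_eval <<- n_eval + 1L
    if (!is.finite(s)) { n_fail <<- n_fail + 1L; s <- -Inf }
    if (s > best_score) { best_score <<- s; best_par <<- x }
    tr_idx <<- c(tr_idx, n_eval); tr_score <<- c(tr_score, s)
    tr_best <<- c(tr_best, best_score)
    s
  }

  with_seed(config$rng_seed, {
    npop <- p * m
    X <- matrix(runif(npop * d, rep(lower, each = npop),
                      rep(upper, each = npop)), npop, d)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      take <- min(nrow(init), npop)
      X[seq_len(take), ] <- init[seq_len(take), , drop = FALSE]
    }
    f <- apply(X, 1, evalf)
    loop_best <- best_score
    stall <- 0L
    while (n_eval + 3 <= config$max_evaluations) {
      ord <- order(f, decreasing = TRUE)
      X <- X[ord, , drop = FALSE]; f <- f[ord]
      for (k in seq_len(p)) {
        sel <- seq(k, npop, by = p)       # systematic partition by rank
        cx <- X[sel, , drop = FALSE]; cf <- f[sel]
        for (b in seq_len(beta_steps)) {
          # a single evolution step spends at most 3 evaluations
          if (n_eval + 3 > config$max_evaluations) break
          # triangular selection probabilities on ranks within the complex
          rnk <- order(cf, decreasing = TRUE)
          w <- 2 * (m + 1 - seq_len(m)) / (m * (m + 1))
          pick <- sample(m, q, prob = w[order(rnk)])
          sub <- pick[order(cf[pick], decreasing = TRUE)]
          worst <- sub[q]
          cen <- colMeans(cx[sub[-q], , drop = FALSE])
          for (a in seq_len(alpha_steps)) {
            refl <- 2 * cen - cx[worst, ]
            if (any(refl < lower | refl > upper))
              refl <- runif(d, lower, upper)
            fr <- evalf(refl)
            if (fr > cf[worst]) {
              cx[worst, ] <- refl; cf[worst] <- fr
            } else {
              ctr <- (cen + cx[worst, ]) / 2
              fc <- evalf(ctr)
              if (fc > cf[worst]) {
                cx[worst, ] <- ctr; cf[worst] <- fc
              } else {
                rnd <- runif(d, lower, upper)
                frnd <- evalf(rnd)
                cx[worst, ] <- rnd; cf[worst] <- frnd
              }
            }
          }
        }
        X[sel, ] <- cx; f[sel] <- cf
      }
      improve <- (best_score - loop_best) /
        max(abs(loop_best), .Machine$double.eps)
      stall <- if (is.finite(improve) &&
                   improve < config$convergence_tolerance) stall + 1L else 0L
      loop_best <- best_score
      if (stall >= config$convergence_loops) break
    }
  })
  list(best_par = best_par, best_score = best_score,
       n_evaluations = n_eval, n_failures = n_fail,
       trace = data.frame(evaluation = tr_idx, score = tr_score,
                          best = tr_best))
}
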