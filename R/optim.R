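#' Box-constrained search space
#'
#' @param lower,upper numeric bound vectors, `lower < upper` elementwise.
#'   The study's SVM hyperparameter box is
#'   `search_space(c(0.001, 0.001), c(100, 100))`.
#' @return An object of class `search_space`.
#' @export
search_space <- function(lower, upper) {
  if (length(lower) != length(upper) || any(lower >= upper)) {
    abort("`lower` must be elementwise below `upper`")
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 dim = length(lower)), class = "search_space")
}

#' Pure update rules of the four metaheuristics
#'
#' Small deterministic kernels used by [mh_optimize()], exported so the
#' update arithmetic can be verified directly.
#'
#' `gwo_candidate()` computes the grey-wolf move: for each leader
#' (alpha, beta, delta) the displacement `D = |C * X_leader - x|` with
#' `C = 2 * lambda2` gives `X_k = X_leader - A * D` with
#' `A = 2 * a * lambda1 - a`, and the candidate is the mean of the three.
#'
#' @param x current position.
#' @param alpha,beta,delta leader positions (best three solutions).
#' @param a control scalar, decreasing linearly from 2 to 0.
#' @param lambda1,lambda2 lists of three uniform \[0,1\] vectors (one per
#'   leader).
#' @return The candidate position (no bound clipping).
#' @export
gwo_candidate <- function(x, alpha, beta, delta, a, lambda1, lambda2) {
  leaders <- list(alpha, beta, delta)
  xs <- lapply(1:3, function(k) {
    A <- 2 * a * lambda1[[k]] - a
    C <- 2 * lambda2[[k]]
    D <- abs(C * leaders[[k]] - x)
    leaders[[k]] - A * D
  })
  (xs[[1]] + xs[[2]] + xs[[3]]) / 3
}

#' @rdname gwo_candidate
#'
#' @details `pso_update()` applies the particle-swarm velocity and
#' position rules
#' `v' = omega * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)` and
#' `x' = x + v'`.
#'
#' @param v current velocity.
#' @param pbest,gbest personal and global best positions.
#' @param omega inertia weight.
#' @param c1,c2 acceleration constants.
#' @param r1,r2 uniform \[0,1\] draws.
#' @return `pso_update()` returns `list(position, velocity)`.
#' @export
pso_update <- function(x, v, pbest, gbest, omega, c1, c2, r1, r2) {
  v_new <- omega * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)
  list(position = x + v_new, velocity = v_new)
}

#' @rdname gwo_candidate
#'
#' @details `ga_selection_prob()` is roulette-wheel selection,
#' `P(i) = f_sel(i) / sum(f_sel)`, on a positive selection fitness;
#' `ga_crossover()` is arithmetic crossover
#' `child = alpha * p1 + (1 - alpha) * p2`.
#'
#' @param f_sel positive selection-fitness values.
#' @export
ga_selection_prob <- function(f_sel) {
  if (any(f_sel < 0)) abort("selection fitness must be non-negative")
  if (sum(f_sel) == 0) return(rep(1 / length(f_sel), length(f_sel)))
  f_sel / sum(f_sel)
}

#' @rdname gwo_candidate
#' @param p1,p2 parent positions.
#' @param alpha_c crossover coefficient in \[0,1\].
#' @export
ga_crossover <- function(p1, p2, alpha_c) alpha_c * p1 + (1 - alpha_c) * p2

#' @rdname gwo_candidate
#'
#' @details `zoa_forage()` moves a zebra toward the pioneer (best) zebra,
#' `x + r * (pz - I * x)`; `zoa_defense()` is the defense phase: against a
#' predator (`mode = 1`) a shrinking local perturbation
#' `x + R_step * (2 * r - 1) * (1 - t / t_max) * x`, otherwise a move
#' toward a random herd member `x + r * (az - I * x)`.
#'
#' @param pz pioneer (best) zebra position.
#' @param az position of a random herd member.
#' @param r uniform \[0,1\] vector.
#' @param I intensity in `{1, 2}`.
#' @param mode defense mode, 1 (predator) or 2 (move to herd member).
#' @param t,t_max iteration counter and budget.
#' @param R_step local step factor (default 0.01).
#' @export
zoa_forage <- function(x, pz, r, I) x + r * (pz - I * x)

#' @rdname gwo_candidate
#' @export
zoa_defense <- function(x, az, r, I, mode, t, t_max, R_step = 0.01) {
  if (mode == 1) x + R_step * (2 * r - 1) * (1 - t / t_max) * x
  else x + r * (az - I * x)
}

new_optimizer_result <- function(algorithm, best_position, best_fitness,
                                 trace, evaluations, seed) {
  structure(list(algorithm = algorithm, best_position = best_position,
                 best_fitness = best_fitness, trace = trace,
                 evaluations = evaluations, seed = seed),
            class = "optimizer_result")
}

#' Minimize a fitness function with a population metaheuristic
#'
#' One interface over four population algorithms — grey wolf (GWO),
#' particle swarm (PSO), genetic (GA) and zebra (ZOA) — under the study
#' budget: population 15, 30 iterations, box-constrained search.
#' Positions are clipped to the box after every update; the best-so-far
#' fitness is recorded each iteration, so the trace is monotone
#' non-increasing. Deterministic given `seed`.
#'
#' Algorithm constants (all configurable via `control`): PSO inertia
#' `omega = 0.729` and accelerations `c1 = c2 = 1.49445`; GA crossover
#' rate 0.9, per-gene mutation rate 0.1 with `N(0, 0.1 * range)`
#' perturbations, elitism 1; ZOA local step factor `R_step = 0.01`.
#' `init` optionally fixes the first population member (the remaining
#' members are drawn uniformly in the box).
#'
#' @param algorithm one of `"gwo"`, `"pso"`, `"ga"`, `"zoa"`.
#' @param fitness function mapping a position vector to a finite scalar
#'   (minimized).
#' @param space a [search_space()].
#' @param pop_size population size (default 15).
#' @param max_iter iteration budget (default 30).
#' @param seed integer RNG seed.
#' @param init optional position for the first population member.
#' @param control named list overriding algorithm constants.
#' @return An `optimizer_result`: `best_position`, `best_fitness`,
#'   per-iteration best-so-far `trace` (length `max_iter`), the exact
#'   number of fitness `evaluations`, and the seed.
#' @export
mh_optimize <- function(algorithm = c("gwo", "pso", "ga", "zoa"),
                        fitness, space, pop_size = 15, max_iter = 30,
                        seed = 1L, init = NULL, control = list()) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(space, "search_space"))
  pop_size <- check_count(pop_size, "pop_size", min = 2L)
  max_iter <- check_count(max_iter, "max_iter")
  ctrl <- utils::modifyList(list(
    omega = 0.729, c1 = 1.49445, c2 = 1.49445,
    crossover_rate = 0.9, mutation_rate = 0.1, mutation_sd_frac = 0.1,
    elitism = 1L, R_step = 0.01
  ), control)
  lo <- space$lower; hi <- space$upper; m <- space$dim
  evals <- 0L
  eval_fit <- function(x) {
    evals <<- evals + 1L
    f <- fitness(x)
    if (!is.finite(f)) {
      abort(sprintf("non-finite fitness at position (%s)",
                    paste(signif(x, 6), collapse = ", ")))
    }
    f
  }
  withr::with_seed(seed, {
    P <- matrix(runif(pop_size * m, rep(lo, each = pop_size),
                      rep(hi, each = pop_size)), pop_size, m)
    if (!is.null(init)) P[1, ] <- clip_box(init, lo, hi)
    f <- apply(P, 1, eval_fit)
    best_i <- which.min(f)
    best_x <- P[best_i, ]; best_f <- f[best_i]
    trace <- numeric(max_iter)
    V <- matrix(0, pop_size, m)            # PSO velocities
    Pb <- P; fb <- f                       # PSO personal bests
    for (t in seq_len(max_iter)) {
      if (algorithm == "gwo") {
        ord <- order(f)
        al <- P[ord[1], ]; be <- P[ord[2], ]; de <- P[ord[3], ]
        a <- 2 * (1 - t / max_iter)
        for (i in seq_len(pop_size)) {
          l1 <- lapply(1:3, function(k) runif(m))
          l2 <- lapply(1:3, function(k) runif(m))
          P[i, ] <- clip_box(gwo_candidate(P[i, ], al, be, de, a, l1, l2),
                             lo, hi)
          f[i] <- eval_fit(P[i, ])
        }
      } else if (algorithm == "pso") {
        g <- Pb[which.min(fb), ]
        for (i in seq_len(pop_size)) {
          up <- pso_update(P[i, ], V[i, ], Pb[i, ], g, ctrl$omega,
                           ctrl$c1, ctrl$c2, runif(m), runif(m))
          P[i, ] <- clip_box(up$position, lo, hi)
          V[i, ] <- up$velocity
          f[i] <- eval_fit(P[i, ])
          if (f[i] < fb[i]) { fb[i] <- f[i]; Pb[i, ] <- P[i, ] }
        }
      } else if (algorithm == "ga") {
        f_sel <- (max(f) - f) + 1e-12       # minimization -> positive fitness
        prob <- ga_selection_prob(f_sel)
        newP <- P; newf <- f
        elite <- order(f)[seq_len(ctrl$elitism)]
        newP[seq_along(elite), ] <- P[elite, , drop = FALSE]
        newf[seq_along(elite)] <- f[elite]
        for (i in seq(ctrl$elitism + 1L, pop_size)) {
          par <- sample.int(pop_size, 2, replace = TRUE, prob = prob)
          child <- if (runif(1) < ctrl$crossover_rate) {
            ga_crossover(P[par[1], ], P[par[2], ], runif(1))
          } else P[par[1], ]
          mut <- runif(m) < ctrl$mutation_rate
          if (any(mut)) {
            child[mut] <- child[mut] +
              rnorm(sum(mut), 0, ctrl$mutation_sd_frac * (hi - lo)[mut])
          }
          newP[i, ] <- clip_box(child, lo, hi)
          newf[i] <- eval_fit(newP[i, ])
        }
        P <- newP; f <- newf
      } else {                              # zoa
        pz <- P[which.min(f), ]
        for (i in seq_len(pop_size)) {      # phase 1: foraging
          cand <- clip_box(
            zoa_forage(P[i, ], pz, runif(m), sample(1:2, 1)), lo, hi)
          fc <- eval_fit(cand)
          if (fc < f[i]) { P[i, ] <- cand; f[i] <- fc }
        }
        pz <- P[which.min(f), ]
        for (i in seq_len(pop_size)) {      # phase 2: defense
          mode <- if (runif(1) <= 0.5) 1 else 2
          az <- P[sample.int(pop_size, 1), ]
          cand <- clip_box(
            zoa_defense(P[i, ], az, runif(m), sample(1:2, 1), mode,
                        t, max_iter, ctrl$R_step), lo, hi)
          fc <- eval_fit(cand)
          if (fc < f[i]) { P[i, ] <- cand; f[i] <- fc }
        }
      }
      it_best <- which.min(f)
      if (f[it_best] < best_f) { best_f <- f[it_best]; best_x <- P[it_best, ] }
      trace[t] <- best_f
    }
  })
  new_optimizer_result(algorithm, best_x, best_f, trace, evals,
                       as.integer(seed))
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat(sprintf("%s: best fitness %.6g at (%s) after %d evaluations\n",
              toupper(x$algorithm), x$best_fitness,
              paste(signif(x$best_position, 6), collapse = ", "),
              x$evaluations))
  invisible(x)
}
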