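#' Das-Dennis structured reference directions on the simplex
#'
#' @param n_obj number of objectives.
#' @param partitions number of divisions per axis (p); yields
#'   `choose(p + n_obj - 1, n_obj - 1)` directions.
#' @return numeric matrix (n_ref x n_obj), rows summing to one.
#' @export
das_dennis <- function(n_obj = 3L, partitions = 12L) {
  rec <- function(left, depth) {
    if (depth == n_obj - 1L) return(matrix(left, 1, 1))
    out <- NULL
    for (v in 0:left) {
      sub <- rec(left - v, depth + 1L)
      out <- rbind(out, cbind(v, sub))
    }
    out
  }
  pts <- rec(partitions, 0L) / partitions
  unname(pts)
}

# TRUE if objective vector a Pareto-dominates b (minimization)
dominates <- function(a, b) all(a <= b) && any(a < b)

#' Fast non-dominated sorting
#'
#' @param obj numeric matrix (n x m) of objective vectors (minimized).
#' @return list of integer index vectors, one per front (best first).
#' @export
nondominated_sort <- function(obj) {
  n <- nrow(obj)
  S <- vector("list", n)
  ncount <- integer(n)
  fronts <- list()
  f1 <- integer(0)
  for (p in seq_len(n)) {
    Sp <- integer(0)
    for (q in seq_len(n)) {
      if (p == q) next
      if (dominates(obj[p, ], obj[q, ])) Sp <- c(Sp, q)
      else if (dominates(obj[q, ], obj[p, ])) ncount[p] <- ncount[p] + 1L
    }
    S[[p]] <- Sp
    if (ncount[p] == 0L) f1 <- c(f1, p)
  }
  fronts[[1]] <- f1
  i <- 1L
  while (length(fronts[[i]]) > 0L) {
    nxt <- integer(0)
    for (p in fronts[[i]]) for (q in S[[p]]) {
      ncount[q] <- ncount[q] - 1L
      if (ncount[q] == 0L) nxt <- c(nxt, q)
    }
    i <- i + 1L
    fronts[[i]] <- nxt
  }
  fronts[lengths(fronts) > 0L]
}

# hyperplane normalization of Deb & Jain: ideal point, extreme points by
# achievement scalarizing, axis intercepts (nadir fallback: front maxima)
nsga3_normalize <- function(obj, front1) {
  m <- ncol(obj)
  ideal <- apply(obj, 2, min)
  shifted <- sweep(obj, 2, ideal)
  extremes <- integer(m)
  for (j in seq_len(m)) {
    w <- rep(1e-6, m)
    w[j] <- 1
    asf <- apply(sweep(shifted, 2, w, "/"), 1, max)
    extremes[j] <- which.min(asf)
  }
  E <- shifted[extremes, , drop = FALSE]
  a <- rep(NA_real_, m)
  ok <- FALSE
  if (abs(det(E)) > 1e-12) {
    b <- tryCatch(solve(E, rep(1, m)), error = function(e) NULL)
    if (!is.null(b) && all(b > 1e-12)) {
      a <- 1 / b
      ok <- TRUE
    }
  }
  if (!ok) a <- apply(obj[front1, , drop = FALSE], 2, max) - ideal
  a[a < 1e-12] <- 1e-12
  sweep(shifted, 2, a, "/")
}

# associate each row of fn with its nearest reference line; returns the
# index and the perpendicular distance
associate_refs <- function(fn, refs) {
  rn <- refs / sqrt(rowSums(refs^2))
  proj <- fn %*% t(rn)                 # n x n_ref projections
  d2 <- matrix(rowSums(fn^2), nrow(fn), nrow(refs)) - proj^2
  d2[d2 < 0] <- 0
  idx <- max.col(-d2, ties.method = "first")
  list(ref = idx, dist = sqrt(d2[cbind(seq_len(nrow(fn)), idx)]))
}

# NSGA-III environmental selection: fill from fronts, resolve the last
# front by reference-direction niching
nsga3_select <- function(obj, fronts, pop_size, refs) {
  chosen <- integer(0)
  i <- 1L
  while (length(chosen) + length(fronts[[i]]) <= pop_size) {
    chosen <- c(chosen, fronts[[i]])
    i <- i + 1L
    if (i > length(fronts)) return(chosen)
  }
  last <- fronts[[i]]
  k <- pop_size - length(chosen)
  if (k == 0L) return(chosen)
  cand <- c(chosen, last)
  fn <- nsga3_normalize(obj[cand, , drop = FALSE],
                        seq_along(fronts[[1]]))
  asc <- associate_refs(fn, refs)
  n_sel <- length(chosen)
  rho <- tabulate(asc$ref[seq_len(n_sel)], nbins = nrow(refs))
  last_pos <- n_sel + seq_along(last)
  avail <- rep(TRUE, length(last))
  active <- rep(TRUE, nrow(refs))
  picked <- integer(0)
  while (length(picked) < k) {
    jset <- which(active)
    j <- jset[which(rho[jset] == min(rho[jset]))]
    if (length(j) > 1L) j <- j[sample.int(length(j), 1L)]
    members <- which(avail & asc$ref[last_pos] == j)
    if (length(members) == 0L) {
      active[j] <- FALSE
      next
    }
    pick <- if (rho[j] == 0L) {
      members[which.min(asc$dist[last_pos][members])]
    } else members[sample.int(length(members), 1L)]
    picked <- c(picked, last[pick])
    avail[pick] <- FALSE
    rho[j] <- rho[j] + 1L
  }
  c(chosen, picked)
}

# simulated binary crossover (eta_c) on a pair of parents, box-bounded
sbx_pair <- function(p1, p2, lower, upper, eta = 15, p_cross = 0.9) {
  c1 <- p1
  c2 <- p2
  if (stats::runif(1) <= p_cross) {
    for (i in seq_along(p1)) {
      if (stats::runif(1) > 0.5 || abs(p1[i] - p2[i]) < 1e-14) next
      x1 <- min(p1[i], p2[i])
      x2 <- max(p1[i], p2[i])
      u <- stats::runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else
        (1 / (2 * (1 - u)))^(1 / (eta + 1))
      c1[i] <- 0.5 * ((x1 + x2) - beta * (x2 - x1))
      c2[i] <- 0.5 * ((x1 + x2) + beta * (x2 - x1))
      if (stats::runif(1) < 0.5) {
        tmp <- c1[i]; c1[i] <- c2[i]; c2[i] <- tmp
      }
    }
  }
  list(pmin(upper, pmax(lower, c1)), pmin(upper, pmax(lower, c2)))
}

# polynomial mutation (eta_m), per-variable probability p_mut
poly_mutate <- function(x, lower, upper, eta = 20, p_mut = NULL) {
  if (is.null(p_mut)) p_mut <- 1 / length(x)
  for (i in seq_along(x)) {
    if (stats::runif(1) > p_mut) next
    u <- stats::runif(1)
    span <- upper[i] - lower[i]
    if (u < 0.5) {
      delta <- (2 * u)^(1 / (eta + 1)) - 1
      x[i] <- x[i] + delta * (x[i] - lower[i])
    } else {
      delta <- 1 - (2 * (1 - u))^(1 / (eta + 1))
      x[i] <- x[i] + delta * (upper[i] - x[i])
    }
  }
  pmin(upper, pmax(lower, x))
}

#' NSGA-III optimizer configuration
#'
#' @param population_size individuals per generation (at least the number
#'   of reference directions).
#' @param n_generations generations to run.
#' @param reference_partitions Das-Dennis partitions on the 3-objective
#'   simplex.
#' @param seed RNG seed (recorded in the result).
#' @param eta_crossover,p_crossover SBX settings.
#' @param eta_mutation polynomial-mutation distribution index.
#' @return list of class `optimization_config`.
#' @export
optimization_config <- function(population_size = 92L, n_generations = 100L,
                                reference_partitions = 12L, seed = 1L,
                                eta_crossover = 15, p_crossover = 0.9,
                                eta_mutation = 20) {
  n_ref <- choose(reference_partitions + 2L, 2L)
  if (population_size < n_ref)
    stop(sprintf("population (%d) must be >= reference directions (%d)",
                 population_size, n_ref))
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 reference_partitions = as.integer(reference_partitions),
                 seed = as.integer(seed), eta_crossover = eta_crossover,
                 p_crossover = p_crossover, eta_mutation = eta_mutation),
            class = "optimization_config")
}

#' Run NSGA-III on a box-constrained multi-objective problem
#'
#' Standard NSGA-III (structured Das-Dennis reference directions,
#' non-dominated sorting with reference-direction niching, SBX crossover
#' and polynomial mutation). The initial population always contains the
#' all-ones individual (the maximum milling area) plus seeded uniform
#' draws inside the box.
#'
#' @param fn objective function: numeric parameter vector -> numeric
#'   objective vector (minimized).
#' @param n_var number of decision variables.
#' @param config an [optimization_config()].
#' @param lower,upper box bounds (defaults `(1e-3, 1]`).
#' @param init optional matrix of seed individuals (rows).
#' @return An object of class `pareto_result`: `parameters` (matrix, one
#'   row per non-dominated solution), `objectives` (matrix), `seed`,
#'   `config`.
#' @export
run_nsga3 <- function(fn, n_var, config = optimization_config(),
                      lower = rep(1e-3, n_var), upper = rep(1, n_var),
                      init = NULL) {
  set.seed(config$seed)
  np <- config$population_size
  refs <- das_dennis(3L, config$reference_partitions)
  pop <- matrix(stats::runif(np * n_var, lower, upper), np, n_var,
                byrow = TRUE)
  pop[1, ] <- upper                       # all-ones seeding
  if (!is.null(init)) {
    init <- rbind(init)
    take <- min(nrow(init), np - 1L)
    if (take > 0) pop[1L + seq_len(take), ] <- init[seq_len(take), ]
  }
  obj <- t(apply(pop, 1, fn))
  for (gen in seq_len(config$n_generations)) {
    perm <- sample.int(np)
    children <- vector("list", np)
    ci <- 1L
    for (q in seq(1L, np - 1L, by = 2L)) {
      pr <- sbx_pair(pop[perm[q], ], pop[perm[q + 1L], ], lower, upper,
                     eta = config$eta_crossover,
                     p_cross = config$p_crossover)
      children[[ci]] <- poly_mutate(pr[[1]], lower, upper,
                                    eta = config$eta_mutation)
      children[[ci + 1L]] <- poly_mutate(pr[[2]], lower, upper,
                                         eta = config$eta_mutation)
      ci <- ci + 2L
    }
    if (np %% 2L == 1L)
      children[[np]] <- poly_mutate(pop[perm[np], ], lower, upper,
                                    eta = config$eta_mutation)
    off <- do.call(rbind, children)
    off_obj <- t(apply(off, 1, fn))
    all_pop <- rbind(pop, off)
    all_obj <- rbind(obj, off_obj)
    fronts <- nondominated_sort(all_obj)
    sel <- nsga3_select(all_obj, fronts, np, refs)
    pop <- all_pop[sel, , drop = FALSE]
    obj <- all_obj[sel, , drop = FALSE]
  }
  f1 <- nondominated_sort(obj)[[1]]
  # drop duplicated parameter rows from the reported front
  keep <- f1[!duplicated(pop[f1, , drop = FALSE])]
  structure(list(parameters = pop[keep, , drop = FALSE],
                 objectives = obj[keep, , drop = FALSE],
                 seed = config$seed, config = config),
            class = "pareto_result")
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(sprintf("<pareto_result: %d non-dominated solutions (seed %d)>\n",
              nrow(x$parameters), x$seed))
  invisible(x)
}

#' Pareto front as a data frame
#' @param front a `pareto_result`.
#' @return data frame with objective columns `Q_c`, `Q_a`, `Q_i` and one
#'   parameter column per decision variable.
#' @export
front_to_df <- function(front) {
  obj <- as.data.frame(front$objectives)
  names(obj) <- c("Q_c", "Q_a", "Q_i")
  par <- as.data.frame(front$parameters)
  names(par) <- paste0("p", seq_len(ncol(par)))
  cbind(obj, par)
}

#' Plot a Pareto front (requires ggplot2)
#'
#' @param front a `pareto_result`.
#' @param selected optional index highlighted as the chosen plan.
#' @return a ggplot object: Q_a vs Q_i, colored by Q_c.
#' @export
plot_pareto_front <- function(front, selected = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- front_to_df(front)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Q_a, y = .data$Q_i,
                                        color = .data$Q_c)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Q_a (negated accessibility)",
                  y = "Q_i (weighted injury)", color = "Q_c") +
    ggplot2::theme_minimal()
  if (!is.null(selected))
    p <- p + ggplot2::geom_point(data = df[selected, , drop = FALSE],
                                 shape = 1, size = 4, color = "black")
  p
}
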