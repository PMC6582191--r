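# Global multi-objective stage: evolve the Pareto front of
# (ssr_subs, ssr_cells) and select the best compromise solution.

#' Configuration for the multi-objective stage
#'
#' The published run conditions fix the population at N = 100 and the
#' budget at 20,000 generations; desk-scale runs use far fewer generations
#' (the front on these two-objective problems stabilizes orders of
#' magnitude earlier), so `n_generations` is freely scalable.
#'
#' @param n_generations number of generations (>= 1).
#' @param pop_size population size (even).
#' @param seed RNG seed.
#' @param eta_c,eta_m distribution indices of simulated binary crossover
#'   and polynomial mutation.
#' @param p_c crossover probability per pair.
#' @param archive_cap maximum archive size (crowding-pruned beyond it).
#' @return A list of class `mo_config`.
#' @export
mo_config <- function(n_generations = 20000, pop_size = 100, seed = 1,
                      eta_c = 15, eta_m = 20, p_c = 0.9,
                      archive_cap = 500) {
  stopifnot(n_generations >= 1, pop_size >= 4, pop_size %% 2 == 0)
  structure(list(n_generations = as.integer(n_generations),
                 pop_size = as.integer(pop_size), seed = as.integer(seed),
                 eta_c = eta_c, eta_m = eta_m, p_c = p_c,
                 archive_cap = as.integer(archive_cap)),
            class = "mo_config")
}

# Pairwise strict Pareto non-domination (minimization, 2+ objectives).
# Returns logical: keep[i] TRUE if no other row dominates row i.
.nondominated <- function(objs) {
  n <- nrow(objs)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    dominated <- rep(TRUE, n)
    for (k in seq_len(ncol(objs)))
      dominated <- dominated & objs[, k] <= objs[i, k]
    strict <- rep(FALSE, n)
    for (k in seq_len(ncol(objs)))
      strict <- strict | objs[, k] < objs[i, k]
    if (any(dominated & strict)) keep[i] <- FALSE
  }
  keep
}

# Fast non-dominated sorting; returns integer rank per row (1 = best).
.nds_ranks <- function(objs) {
  n <- nrow(objs)
  m <- ncol(objs)
  le <- matrix(TRUE, n, n); lt <- matrix(FALSE, n, n)
  for (k in seq_len(m)) {
    ok <- outer(objs[, k], objs[, k], `<=`)
    le <- le & ok
    lt <- lt | outer(objs[, k], objs[, k], `<`)
  }
  dom <- le & lt                    # dom[i, j]: i dominates j
  n_dom <- colSums(dom)
  rank <- integer(n)
  current <- which(n_dom == 0)
  r <- 1L
  while (length(current)) {
    rank[current] <- r
    n_dom[current] <- -1L
    if (length(current) == 1) {
      n_dom <- n_dom - dom[current, ]
    } else {
      n_dom <- n_dom - colSums(dom[current, , drop = FALSE])
    }
    current <- which(n_dom == 0 & rank == 0L)
    r <- r + 1L
  }
  rank
}

# Crowding distance within one front.
.crowding <- function(objs) {
  n <- nrow(objs)
  if (n <= 2) return(rep(Inf, n))
  cd <- numeric(n)
  for (k in seq_len(ncol(objs))) {
    o <- order(objs[, k])
    rng <- objs[o[n], k] - objs[o[1], k]
    cd[o[c(1, n)]] <- Inf
    if (rng > 0) {
      cd[o[2:(n - 1)]] <- cd[o[2:(n - 1)]] +
        (objs[o[3:n], k] - objs[o[1:(n - 2)], k]) / rng
    }
  }
  cd
}

# 2-D hypervolume of a nondominated set w.r.t. reference point (minimization).
.hv2d <- function(objs, ref) {
  keep <- objs[, 1] < ref[1] & objs[, 2] < ref[2]
  if (!any(keep)) return(0)
  o <- objs[keep, , drop = FALSE]
  o <- o[order(o[, 1]), , drop = FALSE]
  hv <- 0
  prev_f2 <- ref[2]
  for (i in seq_len(nrow(o))) {
    if (o[i, 2] < prev_f2) {
      hv <- hv + (ref[1] - o[i, 1]) * (prev_f2 - o[i, 2])
      prev_f2 <- o[i, 2]
    }
  }
  hv
}

#' Evolve a Pareto front by elitist non-dominated sorting
#'
#' A generational loop of binary tournament selection (rank then crowding),
#' simulated binary crossover and polynomial mutation, with elitist
#' survival by fast non-dominated sorting and crowding-distance truncation.
#' Alongside the population, a cumulative archive of all non-dominated
#' solutions encountered is maintained (crowding-pruned above
#' `archive_cap`); the returned front is the archive, whose hypervolume is
#' tracked per generation against a reference point fixed at the
#' componentwise maximum of the initial population's objectives.
#'
#' @param fn vector-valued objective (length-2 return), minimized
#'   componentwise; must return finite values.
#' @param lower,upper bound vectors.
#' @param config an [mo_config()].
#' @return An object of class `pareto_front`: `members` (list with matrix
#'   `pars` and matrix `objs`, one row per non-dominated member),
#'   `ideal_point`, `compromise_index`, `compromise` (list `par`, `obj`),
#'   `hv_trace`, `single_point` warning flag.
#' @examples
#' f <- function(x) c(x[1]^2, (x[1] - 2)^2)
#' pf <- nsga2_evolve(f, -5, 5, mo_config(n_generations = 50, pop_size = 40))
#' @export
nsga2_evolve <- function(fn, lower, upper, config = mo_config()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  np <- config$pop_size
  withr::with_seed(config$seed, {
    pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                               rep(upper, each = np)), np, d)
    objs <- t(apply(pop, 1, fn))
    m <- ncol(objs)
    ref <- apply(objs, 2, max)
    arch_p <- pop[.nondominated(objs), , drop = FALSE]
    arch_o <- objs[.nondominated(objs), , drop = FALSE]
    hv_trace <- .hv2d(arch_o, ref)
    rank <- .nds_ranks(objs)
    cd <- numeric(np)
    for (r in unique(rank)) cd[rank == r] <- .crowding(objs[rank == r, ,
                                                            drop = FALSE])
    pm <- 1 / d
    for (gen in seq_len(config$n_generations)) {
      # binary tournaments
      pick <- function() {
        ij <- sample.int(np, 2)
        i <- ij[1]; j <- ij[2]
        if (rank[i] < rank[j]) i
        else if (rank[j] < rank[i]) j
        else if (cd[i] >= cd[j]) i else j
      }
      children <- matrix(0, np, d)
      for (c2 in seq_len(np / 2)) {
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (stats::runif(1) < config$p_c) {
          u <- stats::runif(d)
          beta <- ifelse(u <= 0.5, (2 * u)^(1 / (config$eta_c + 1)),
                         (1 / (2 * (1 - u)))^(1 / (config$eta_c + 1)))
          c_a <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
          c_b <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
        } else {
          c_a <- p1; c_b <- p2
        }
        children[2 * c2 - 1, ] <- c_a
        children[2 * c2, ] <- c_b
      }
      # polynomial mutation
      mut <- matrix(stats::runif(np * d) < pm, np, d)
      if (any(mut)) {
        u <- stats::runif(sum(mut))
        delta <- ifelse(u < 0.5, (2 * u)^(1 / (config$eta_m + 1)) - 1,
                        1 - (2 * (1 - u))^(1 / (config$eta_m + 1)))
        span <- rep(upper - lower, each = np)[mut]
        children[mut] <- children[mut] + delta * span
      }
      # reflect into bounds
      for (k in seq_len(d)) {
        col <- children[, k]
        for (it in 1:6) {
          lo <- col < lower[k]; col[lo] <- 2 * lower[k] - col[lo]
          hi <- col > upper[k]; col[hi] <- 2 * upper[k] - col[hi]
          if (!any(col < lower[k] | col > upper[k])) break
        }
        children[, k] <- pmin(pmax(col, lower[k]), upper[k])
      }
      cobjs <- t(apply(children, 1, fn))
      # elitist survival
      allp <- rbind(pop, children)
      allo <- rbind(objs, cobjs)
      arank <- .nds_ranks(allo)
      sel <- integer(0)
      r <- 1L
      while (length(sel) < np) {
        idx <- which(arank == r)
        if (length(sel) + length(idx) <= np) {
          sel <- c(sel, idx)
        } else {
          cdr <- .crowding(allo[idx, , drop = FALSE])
          sel <- c(sel, idx[order(cdr, decreasing = TRUE)][
            seq_len(np - length(sel))])
        }
        r <- r + 1L
      }
      pop <- allp[sel, , drop = FALSE]
      objs <- allo[sel, , drop = FALSE]
      rank <- .nds_ranks(objs)
      cd <- numeric(np)
      for (rr in unique(rank)) cd[rank == rr] <-
          .crowding(objs[rank == rr, , drop = FALSE])
      # merge generation's rank-0 set into the archive
      first <- which(rank == 1L)
      arch_p <- rbind(arch_p, pop[first, , drop = FALSE])
      arch_o <- rbind(arch_o, objs[first, , drop = FALSE])
      dup <- duplicated(round(arch_o, 12))
      arch_p <- arch_p[!dup, , drop = FALSE]
      arch_o <- arch_o[!dup, , drop = FALSE]
      keep <- .nondominated(arch_o)
      arch_p <- arch_p[keep, , drop = FALSE]
      arch_o <- arch_o[keep, , drop = FALSE]
      if (nrow(arch_o) > config$archive_cap) {
        acd <- .crowding(arch_o)
        keep <- order(acd, decreasing = TRUE)[seq_len(config$archive_cap)]
        arch_p <- arch_p[keep, , drop = FALSE]
        arch_o <- arch_o[keep, , drop = FALSE]
      }
      hv_trace <- c(hv_trace, .hv2d(arch_o, ref))
    }
    pareto_front(arch_p, arch_o, hv_trace = hv_trace)
  })
}

#' Pareto front container
#'
#' @param pars matrix of decision vectors (one row per member).
#' @param objs matrix of objective vectors (same row order, minimization).
#' @param hv_trace optional hypervolume trace.
#' @return An object of class `pareto_front` with strictly non-dominated
#'   members, the componentwise `ideal_point`, and the selected compromise
#'   member (see [select_compromise()]).
#' @export
pareto_front <- function(pars, objs, hv_trace = NULL) {
  pars <- as.matrix(pars); objs <- as.matrix(objs)
  stopifnot(nrow(pars) == nrow(objs), nrow(objs) >= 1)
  keep <- .nondominated(objs)
  pars <- pars[keep, , drop = FALSE]
  objs <- objs[keep, , drop = FALSE]
  front <- structure(
    list(members = list(pars = pars, objs = objs),
         ideal_point = apply(objs, 2, min),
         compromise_index = NA_integer_,
         compromise = NULL,
         hv_trace = hv_trace,
         single_point = nrow(objs) == 1),
    class = "pareto_front"
  )
  ci <- select_compromise(front, index_only = TRUE)
  front$compromise_index <- ci
  front$compromise <- list(par = pars[ci, ], obj = objs[ci, ])
  if (front$single_point)
    warning("degenerate Pareto front: single non-dominated point",
            call. = FALSE)
  front
}

#' @export
print.pareto_front <- function(x, ...) {
  cat("<pareto_front: ", nrow(x$members$objs), " members; ideal = (",
      paste(signif(x$ideal_point, 4), collapse = ", "), ")>\n", sep = "")
  cat("  compromise member ", x$compromise_index, ": objectives (",
      paste(signif(x$compromise$obj, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Select the best compromise member of a Pareto front
#'
#' Objectives are min-max normalized to \eqn{[0,1]} over the front and the
#' member minimizing the Euclidean distance to the normalized ideal point
#' (the origin) is returned -- the knee of the compromise curve under
#' standard compromise programming.  Ties break lexicographically on the
#' objective vector.  A size-one front returns its only member.
#'
#' @param front a [pareto_front()], or a matrix of objective vectors.
#' @param index_only return just the selected row index.
#' @return List with `par` (NULL when a bare objective matrix was given),
#'   `obj`, and `index`; or the index alone.
#' @examples
#' objs <- rbind(c(0, 1), c(1, 0), c(0.3, 0.3))
#' select_compromise(objs)$obj   # c(0.3, 0.3)
#' @export
select_compromise <- function(front, index_only = FALSE) {
  if (inherits(front, "pareto_front")) {
    objs <- front$members$objs
    pars <- front$members$pars
  } else {
    objs <- as.matrix(front)
    keep <- .nondominated(objs)
    if (!all(keep)) objs <- objs[keep, , drop = FALSE]
    pars <- NULL
  }
  n <- nrow(objs)
  if (n == 0) stop("empty front", call. = FALSE)
  lo <- apply(objs, 2, min); hi <- apply(objs, 2, max)
  rng <- pmax(hi - lo, .Machine$double.eps)
  norm <- sweep(sweep(objs, 2, lo), 2, rng, `/`)
  dist <- sqrt(rowSums(norm^2))
  cand <- which(dist == min(dist))
  if (length(cand) > 1) {        # lexicographic tie-break
    o <- do.call(order, as.data.frame(objs[cand, , drop = FALSE]))
    cand <- cand[o[1]]
  }
  if (index_only) return(cand)
  list(par = if (is.null(pars)) NULL else pars[cand, ],
       obj = objs[cand, ], index = cand)
}

#' Cross-check the multi-objective compromise against the single-objective one
#'
#' Step 2 is verified against step 1: the total objective of the
#' multi-objective compromise should match the single-objective compromise
#' total, since two independent search frameworks converging to the same
#' region is evidence the compromise solution space has truly been found.
#'
#' @param compromise_vec objective vector `c(ssr_subs, ssr_cells)` of the
#'   multi-objective compromise.
#' @param so_compromise the single-objective compromise [objective_value()]
#'   (or its total as a scalar).
#' @param rel_tol relative gap tolerance.
#' @return List `gap` (relative), `pass`, `total_mo`, `total_so`,
#'   `rel_tol`, of class `so_mo_verification`.
#' @export
verify_against_so <- function(compromise_vec, so_compromise, rel_tol = 0.05) {
  total_mo <- sum(compromise_vec)
  total_so <- if (inherits(so_compromise, "objective_value"))
    so_compromise$total else as.numeric(so_compromise)
  gap <- abs(total_mo - total_so) / max(total_so, 1e-12)
  structure(list(gap = gap, pass = gap <= rel_tol,
                 total_mo = total_mo, total_so = total_so,
                 rel_tol = rel_tol),
            class = "so_mo_verification")
}

#' @export
print.so_mo_verification <- function(x, ...) {
  cat(sprintf("<so/mo verification> totals %.6g (MO) vs %.6g (SO); relative gap %.3g -> %s\n",
              x$total_mo, x$total_so, x$gap,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Fit a kinetic model by global multi-objective search
#'
#' Evolves the Pareto front of the per-variable error sums
#' `(ssr_subs, ssr_cells)` over log10-scaled parameters and selects the
#' best compromise member.
#'
#' @inheritParams fit_so
#' @param config an [mo_config()].
#' @param fixed named list of parameters held fixed (restricted fits).
#' @return A [pareto_front()] whose `members$pars` are natural-scale
#'   parameters (columns named), with `compromise_params` attached as a
#'   [kinetic_params()] object and `compromise_objective` as an
#'   [objective_value()].
#' @export
fit_mo <- function(spec, dataset, bounds = default_bounds(spec),
                   config = mo_config(), fixed = list()) {
  spec <- kin_model(spec)
  obj <- .kin_objective(spec, dataset, bounds, component = "vector",
                        fixed = fixed)
  front <- nsga2_evolve(obj$fn, obj$lower, obj$upper, config)
  pars_nat <- 10^front$members$pars
  colnames(pars_nat) <- obj$param_names
  front$members$pars <- pars_nat
  front$compromise$par <- pars_nat[front$compromise_index, ]
  front$compromise_params <- obj$to_params(
    log10(pars_nat[front$compromise_index, ]))
  front$fixed <- fixed
  front$free_params <- obj$param_names
  front$compromise_objective <- objective_value(front$compromise$obj[1],
                                                front$compromise$obj[2])
  front$model <- spec$name
  front
}
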