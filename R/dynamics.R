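#' Model parameters for the island dynamics
#'
#' Bundles a fitness landscape with the migration regime and genetic map.
#' The island receives one-way migration at backward rate `m` per individual
#' and generation from a monomorphic continent fixed for `continental_hap`.
#' The dynamics of the haplotype-frequency vector `x` follow, per haplotype
#' `X`, `dx/dt = (w_X - wbar - m) x + f_R(x) + m_C`, with `m_C = m` for the
#' continental haplotype and 0 otherwise; diploids use marginal
#' (random-mating) genotype fitnesses in place of `w_X`.
#'
#' @inheritParams hap_index
#' @param m migration rate (>= 0), same Malthusian scale as the fitnesses.
#' @param continental_hap haplotype fixed on the continent.
#' @param recomb vector of recombination rates between consecutive loci
#'   (length `n_loci - 1`); ignored in the `tight` and `loose` modes.  For
#'   the `discrete` mode each rate must lie in `[0, 0.5]`.
#' @param mode `"ode"` (full continuous-time system at the given `recomb`),
#'   `"tight"` (r = 0: the 2^n-allele single-locus reduction), `"loose"`
#'   (linkage-equilibrium limit r -> infinity; state reduces to the `n`
#'   allele frequencies), or `"discrete"` (discrete-time generations with
#'   multiplicative viabilities `1 + w`).
#' @return an object of class `model_params`.
#' @export
model_params <- function(landscape, m, continental_hap,
                         recomb = NULL,
                         mode = c("ode", "tight", "loose", "discrete")) {
  mode <- match.arg(mode)
  if (m < 0) stop("migration rate m must be >= 0")
  n <- landscape$n_loci
  if (mode %in% c("tight", "loose")) {
    recomb <- rep(0, max(n - 1L, 0L))
  } else {
    if (is.null(recomb)) stop("mode \"", mode, "\" needs recombination rates")
    recomb <- rep_len(as.numeric(recomb), max(n - 1L, 0L))
    if (any(recomb < 0)) stop("recombination rates must be >= 0")
    if (mode == "discrete" && any(recomb > 0.5))
      stop("discrete-time recombination rates must lie in [0, 0.5]")
  }
  landscape <- with_genotype_cache(landscape)
  p <- structure(
    list(landscape = landscape, m = m,
         continental = hap_index(landscape, continental_hap),
         recomb = recomb, mode = mode),
    class = "model_params")
  p$cache <- build_dynamics_cache(p)
  p
}

# precomputed aggregation matrices for the recombination operators: for a
# segment grouping g, E[i, j] = 1 iff haplotypes i and j agree on the
# segment, so (E %*% x)[i] is the marginal frequency of i's segment alleles
build_dynamics_cache <- function(params) {
  n <- params$landscape$n_loci
  H <- 2L^n
  idx <- 0:(H - 1L)
  agg <- function(mask) {
    g <- bitwAnd(idx, mask)
    outer(g, g, `==`) + 0
  }
  # continuous time: one bipartition per adjacent-gap crossover
  cont <- list()
  if (n >= 2L) for (k in seq_len(n - 1L)) {
    maskS <- 2L^k - 1L                       # loci 1..k
    cont[[k]] <- list(ES = agg(maskS), ET = agg(bitwNot(maskS) %% H))
  }
  # discrete time: all transmission masks with product-rule probabilities
  masks <- list()
  r <- params$recomb
  if (n >= 2L) {
    for (M in idx) {
      memb <- bitwAnd(M, 2L^(seq_len(n) - 1L)) > 0L
      change <- memb[-1L] != memb[-n]
      tM <- 0.5 * prod(ifelse(change, r, 1 - r))
      if (tM > 0)
        masks[[length(masks) + 1L]] <-
          list(tM = tM, EM = agg(M), EMc = agg(bitwNot(M) %% H))
    }
  }
  # locus membership matrix (n x H) for allele-frequency marginals
  list(cont = cont, masks = masks, memb = t(hap_bit_matrix(n)), H = H)
}

#' Mean fitness of a population state
#'
#' Haploid: `sum(w_i x_i)`.  Diploid: the random-mating expectation of the
#' ploidy-scaled genotype fitness, `sum_ij w_ij x_i x_j`.
#'
#' @param x haplotype frequency vector on the simplex (length `2^n`).
#' @inheritParams hap_index
#' @export
mean_fitness <- function(x, landscape) {
  if (landscape$ploidy == 1) sum(landscape$w * x)
  else drop(x %*% genotype_fitness_matrix(landscape) %*% x)
}

#' Allele frequencies of a haplotype-frequency state
#'
#' @inheritParams mean_fitness
#' @return derived-allele frequency at each locus.
#' @export
allele_frequencies <- function(x, landscape) {
  memb <- t(hap_bit_matrix(landscape$n_loci))
  freqs <- drop(memb %*% x)
  names(freqs) <- landscape$locus_names
  freqs
}

#' Continuous-time recombination flux
#'
#' Change in haplotype frequencies due to recombination, `f_R(x)`.  In
#' continuous time rare single crossovers dominate: each adjacent-gap
#' crossover `k` moves the state toward the random union of the two induced
#' segment marginals at rate `r_k` (multi-crossover bipartitions are
#' `O(r^2)` and ignored).  The flux sums to zero, conserves all single-locus
#' allele frequencies, and vanishes exactly at linkage equilibrium.
#'
#' @inheritParams mean_fitness
#' @param params a [model_params()].
#' @return flux vector of length `2^n`.
#' @export
recombination_flux <- function(x, params) {
  out <- numeric(length(x))
  cont <- params$cache$cont
  r <- params$recomb
  if (length(cont)) for (k in seq_along(cont)) {
    if (r[k] == 0) next
    pS <- drop(cont[[k]]$ES %*% x)  # marginal freq of the left segment
    pT <- drop(cont[[k]]$ET %*% x)
    out <- out + r[k] * (pS * pT - x)
  }
  out
}

# discrete-time recombination: full product rule over transmission masks,
# applied to a (viability-weighted) random-mating gamete pool
recombine_discrete <- function(x, params) {
  n <- params$landscape$n_loci
  if (n == 1L) return(x)
  out <- numeric(length(x))
  for (mk in params$cache$masks)
    out <- out + mk$tM * drop(mk$EM %*% x) * drop(mk$EMc %*% x)
  out
}

# per-haplotype selection coefficient: w_X (haploid) or marginal fitness
# 2 * sum_Y w_geno(X, Y) x_Y (diploid), minus nothing; mean handled by caller
selection_margin <- function(x, params) {
  ls <- params$landscape
  if (ls$ploidy == 1) ls$w else drop(2 * (ls$G %*% x))
}

#' Right-hand side of the island haplotype dynamics
#'
#' Evaluates `dx/dt` for the continuous-time system: selection relative to
#' the population mean, loss of every haplotype at the migration rate `m`,
#' gain of the continental haplotype at `m`, plus the recombination flux.
#' The sum of the entries is 0 whenever `x` is on the simplex.
#'
#' @inheritParams recombination_flux
#' @export
ode_rhs <- function(x, params) {
  marg <- selection_margin(x, params)
  # for diploids sum(marg * x) = 2 * wbar_geno, on the same scale as marg
  wbar <- sum(marg * x)
  dx <- (marg - wbar - params$m) * x + recombination_flux(x, params)
  dx[params$continental] <- dx[params$continental] + params$m
  dx
}

#' Linkage-equilibrium (loose-linkage) allele-frequency dynamics
#'
#' The r -> infinity limit: the state collapses to the `n` derived-allele
#' frequencies; the dynamics are obtained by evaluating [ode_rhs()] at the
#' linkage-equilibrium haplotype state and marginalizing per locus.
#'
#' @param p vector of derived-allele frequencies (length `n_loci`).
#' @inheritParams recombination_flux
#' @return `dp/dt`, length `n_loci`.
#' @export
loose_linkage_rhs <- function(p, params) {
  x <- le_state(p, params$landscape$n_loci)
  drop(params$cache$memb %*% ode_rhs(x, params))
}

#' Linkage-equilibrium haplotype state from allele frequencies
#'
#' @param p derived-allele frequencies.
#' @param n_loci number of loci.
#' @export
le_state <- function(p, n_loci = length(p)) {
  bits <- hap_bit_matrix(n_loci)
  x <- rep(1, 2L^n_loci)
  for (j in seq_len(n_loci))
    x <- x * ifelse(bits[, j] == 1L, p[j], 1 - p[j])
  x
}

#' One generation of the discrete-time model
#'
#' Life cycle: migration (a fraction `m` of the island is replaced by the
#' continental haplotype), then random mating with recombination by the full
#' crossover product rule, then viability selection with multiplicative
#' fitnesses `1 + w` (haploid) or `1 + w_geno` acting on the marginal
#' viability of each gamete (diploid).  `w = -1` encodes an inviable type;
#' viabilities below 0 are an error.
#'
#' @inheritParams recombination_flux
#' @return next-generation haplotype frequency vector.
#' @export
discrete_time_step <- function(x, params) {
  ls <- params$landscape
  m <- params$m
  if (m > 1) stop("discrete-time migration rate must be a fraction <= 1")
  x1 <- (1 - m) * x
  x1[params$continental] <- x1[params$continental] + m
  x2 <- recombine_discrete(x1, params)
  if (ls$ploidy == 1) {
    v <- 1 + ls$w
  } else {
    v <- 1 + drop(2 * (ls$G %*% x2))  # 1 + marginal genotype fitness
  }
  if (any(v < -1e-12))
    stop("negative viability: 1 + w < 0 for some genotype; ",
         "use w >= -1 in the discrete-time model")
  v[v < 0] <- 0
  x3 <- x2 * v
  if (sum(x3) <= 0) stop("population is entirely inviable")
  x3 / sum(x3)
}

#' Integrate the island dynamics to equilibrium
#'
#' Runs the dynamics of the chosen mode from `init` until the largest rate
#' of change falls below `tol` or the horizon `t_max` is exceeded (the
#' integration horizon doubles between checks).  Continuous-time modes use
#' a stiff-capable adaptive integrator (`deSolve::lsoda`), which tolerates
#' the very large epistasis values used in lethal-haplotype limits.
#'
#' @param init initial state: haplotype frequencies (length `2^n`) or, in
#'   `loose` mode, derived-allele frequencies (length `n`).
#' @inheritParams recombination_flux
#' @param tol convergence threshold on `max(abs(dx/dt))` (per-generation
#'   change in discrete mode).
#' @param t_max maximum integration time (generations in discrete mode).
#' @param keep_trajectory if `TRUE`, also return the sampled trajectory.
#' @param stop_fn optional predicate on the state; integration stops early
#'   (with `converged = FALSE` and `stopped = TRUE`) as soon as it returns
#'   `TRUE` at a checkpoint.  Used to abandon trajectories whose outcome is
#'   already decided, e.g. an allele irreversibly lost.
#' @return list with `state` (final state), `converged` flag, `time`
#'   reached, and optionally `trajectory` (a data frame).
#' @export
integrate_to_equilibrium <- function(init, params, tol = 1e-10,
                                     t_max = 1e6, keep_trajectory = FALSE,
                                     stop_fn = NULL) {
  loose <- params$mode == "loose"
  rhs <- if (loose) function(p) loose_linkage_rhs(p, params)
         else function(x) ode_rhs(x, params)

  if (params$mode == "discrete") {
    x <- init / sum(init)
    t <- 0; traj <- if (keep_trajectory) list(c(time = 0, x)) else NULL
    converged <- FALSE
    stopped <- FALSE
    while (t < t_max) {
      xn <- discrete_time_step(x, params)
      t <- t + 1
      if (keep_trajectory && (t %% max(1, floor(t_max / 1000)) == 0))
        traj[[length(traj) + 1L]] <- c(time = t, xn)
      if (max(abs(xn - x)) < tol) { x <- xn; converged <- TRUE; break }
      x <- xn
      if (!is.null(stop_fn) && t %% 100 == 0 && isTRUE(stop_fn(x))) {
        stopped <- TRUE; break
      }
    }
    return(finish_equilibrium(x, converged, t, traj, params,
                              stopped = stopped))
  }

  state <- if (loose) pmin(pmax(init, 0), 1) else init / sum(init)
  # the rhs is polynomial, hence smooth slightly outside the simplex; no
  # clamping inside the integrator (a clamped rhs is non-smooth at the
  # boundary and stalls the step-size control there).  Haplotype modes
  # evaluate the rhs on the normalized state so that integrator drift in
  # the total mass is neutral rather than amplified by recombination
  derivs <- if (loose) function(t, y, parms) list(rhs(y))
            else function(t, y, parms) list(rhs(y / sum(y)))
  t_now <- 0; chunk <- 50; converged <- FALSE; stopped <- FALSE
  traj <- if (keep_trajectory) list(c(time = 0, state)) else NULL
  while (t_now < t_max) {
    chunk <- min(chunk, t_max - t_now)
    sol <- suppressWarnings(
      deSolve::lsoda(y = state, times = c(0, chunk), func = derivs,
                     parms = NULL, rtol = 1e-8, atol = 1e-12,
                     maxsteps = 50000))
    finite_rows <- which(apply(is.finite(sol), 1L, all))
    if (!length(finite_rows))
      stop("non-finite state during integration")
    got <- as.numeric(sol[max(finite_rows), -1L])
    reached <- sol[max(finite_rows), 1L]
    if (reached <= 0)
      stop("integrator made no progress (t = ", t_now, ")")
    state <- pmin(pmax(got, 0), 1)
    if (!loose) state <- state / sum(state)
    t_now <- t_now + reached
    if (keep_trajectory) traj[[length(traj) + 1L]] <- c(time = t_now, state)
    if (max(abs(rhs(state))) < tol) { converged <- TRUE; break }
    if (!is.null(stop_fn) && isTRUE(stop_fn(state))) { stopped <- TRUE; break }
    if (reached >= chunk - 1e-12) chunk <- chunk * 2
  }
  finish_equilibrium(state, converged, t_now, traj, params,
                     stopped = stopped)
}

finish_equilibrium <- function(state, converged, time, traj, params,
                               stopped = FALSE) {
  ls <- params$landscape
  if (params$mode == "loose") {
    names(state) <- ls$locus_names
  } else {
    names(state) <- names(ls$w)
  }
  out <- list(state = state, converged = converged, time = time,
              stopped = stopped)
  if (!is.null(traj)) {
    tr <- as.data.frame(do.call(rbind, traj))
    xcols <- tr[, -1L, drop = FALSE]
    tr$mean_fitness <- if (params$mode == "loose")
      apply(xcols, 1L, function(p) mean_fitness(le_state(p, ls$n_loci), ls))
    else apply(xcols, 1L, mean_fitness, landscape = ls)
    out$trajectory <- tr
  }
  out
}
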