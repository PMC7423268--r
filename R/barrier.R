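#' Specify a genetic barrier to be maintained on the island
#'
#' A barrier query names the island alleles whose polymorphism defines the
#' barrier, e.g. `"Ab"`: maintain the derived `A` and the ancestral `b` on
#' the island against immigration of the continental haplotype.  The island
#' allele at each barrier locus must differ from the continental one.  An
#' optional background pattern (e.g. `"C"`) lists alleles fixed in both
#' demes; the continental haplotype is assembled as the complement of the
#' barrier alleles plus the background.
#'
#' @inheritParams hap_index
#' @param barrier allele pattern string for the island alleles at the
#'   barrier loci (uppercase = derived, lowercase = ancestral).
#' @param background optional allele pattern fixed on both demes; loci not
#'   mentioned in either pattern are taken ancestral everywhere.
#' @param scope `"local"` (a stable equilibrium reached from the resident
#'   island state / by continuation) or `"global"` (reached from every
#'   member of a spanning set of initial conditions).
#' @param delta persistence threshold: an island allele counts as
#'   maintained when its equilibrium frequency exceeds `delta`.
#' @return object of class `barrier_query`.
#' @export
barrier_query <- function(landscape, barrier, background = NULL,
                          scope = c("local", "global"), delta = 1e-6) {
  scope <- match.arg(scope)
  n <- landscape$n_loci
  bar <- parse_allele_pattern(barrier, landscape$locus_names)
  bg <- if (is.null(background)) list(loci = integer(0), derived = logical(0))
        else parse_allele_pattern(background, landscape$locus_names)
  if (length(intersect(bar$loci, bg$loci)))
    stop("barrier loci and background loci must be disjoint")
  # continental haplotype: opposite of the island allele at barrier loci,
  # background as declared, ancestral elsewhere
  cont_bits <- integer(n)
  cont_bits[bar$loci] <- as.integer(!bar$derived)
  cont_bits[bg$loci] <- as.integer(bg$derived)
  isl_bits <- cont_bits
  isl_bits[bar$loci] <- as.integer(bar$derived)
  structure(list(landscape = landscape,
                 barrier_loci = bar$loci,
                 island_derived = bar$derived,
                 background_loci = bg$loci,
                 continental_hap = hap_from_bits(cont_bits),
                 island_hap = hap_from_bits(isl_bits),
                 scope = scope, delta = delta),
            class = "barrier_query")
}

# frequency of each queried island allele in a state (haplotype or allele
# frequency space)
island_allele_freqs <- function(state, query, params) {
  p <- if (params$mode == "loose") state
       else drop(params$cache$memb %*% state)
  ifelse(query$island_derived, p[query$barrier_loci],
         1 - p[query$barrier_loci])
}

# initial state: resident island haplotype perturbed by the invading
# continental haplotype at frequency eps
resident_init <- function(query, params, eps = 1e-6) {
  ls <- query$landscape
  if (params$mode == "loose") {
    bits <- hap_bit_matrix(ls$n_loci)
    p <- bits[query$island_hap, ] * (1 - eps) + bits[query$continental_hap, ] * eps
    p
  } else {
    x <- numeric(2L^ls$n_loci)
    x[query$island_hap] <- 1 - eps
    x[query$continental_hap] <- eps
    x
  }
}

# spanning initial-condition set for global-scope queries: every vertex
# perturbed toward the continental haplotype, plus a uniform interior point
global_init_set <- function(query, params, eps = 1e-6) {
  ls <- query$landscape
  n <- ls$n_loci
  H <- 2L^n
  inits <- list()
  if (params$mode == "loose") {
    bits <- hap_bit_matrix(n)
    cont <- bits[query$continental_hap, ]
    for (v in seq_len(H))
      inits[[v]] <- bits[v, ] * (1 - eps) + cont * eps
    inits[[H + 1L]] <- rep(0.5, n)
    # keep background loci fixed as declared in every start
    bgb <- bits[query$continental_hap, query$background_loci]
    inits <- lapply(inits, function(p) {
      p[query$background_loci] <- bgb; p })
  } else {
    for (v in seq_len(H)) {
      x <- numeric(H); x[v] <- 1 - eps
      x[query$continental_hap] <- x[query$continental_hap] + eps
      inits[[v]] <- x
    }
    inits[[H + 1L]] <- rep(1 / H, H)
  }
  inits
}

#' Locate equilibria of the island dynamics
#'
#' Integrates the dynamics from a spanning set of initial conditions (all
#' haplotype vertices perturbed toward the continental haplotype plus an
#' interior point, or a user-supplied list), deduplicates the endpoints and
#' classifies each by which derived alleles persist above `delta` and by
#' local stability (largest real part of the Jacobian eigenvalues).
#'
#' @param params a [model_params()].
#' @param inits optional list of initial states.
#' @param delta persistence threshold for the classification.
#' @param tol,t_max convergence control for [integrate_to_equilibrium()].
#' @return data frame with one row per distinct equilibrium: columns for the
#'   state, `stable`, `converged`, and a `classification` string listing the
#'   persisting derived alleles.
#' @export
find_equilibria <- function(params, inits = NULL, delta = 1e-6,
                            tol = 1e-10, t_max = 1e5) {
  ls <- params$landscape
  if (is.null(inits)) {
    dummy <- structure(list(landscape = ls,
                            barrier_loci = integer(0),
                            island_derived = logical(0),
                            background_loci = integer(0),
                            continental_hap = params$continental,
                            island_hap = params$continental),
                       class = "barrier_query")
    inits <- global_init_set(dummy, params)
  }
  ends <- list(); stability <- logical(0); convs <- logical(0)
  for (init in inits) {
    eq <- integrate_to_equilibrium(init, params, tol = tol, t_max = t_max)
    dup <- any(vapply(ends, function(e)
      max(abs(e - eq$state)) < 1e-6, logical(1)))
    if (!dup) {
      ends[[length(ends) + 1L]] <- eq$state
      stability <- c(stability, equilibrium_stable(eq$state, params))
      convs <- c(convs, eq$converged)
    }
  }
  cls <- vapply(ends, function(e) {
    p <- if (params$mode == "loose") e else drop(params$cache$memb %*% e)
    paste(ls$locus_names[p > delta & p < 1 - delta], collapse = "")
  }, character(1))
  persisting <- vapply(ends, function(e) {
    p <- if (params$mode == "loose") e else drop(params$cache$memb %*% e)
    paste(ifelse(p > 1 - delta, toupper(ls$locus_names),
                 ifelse(p < delta, tolower(ls$locus_names), "*")),
          collapse = "")
  }, character(1))
  df <- as.data.frame(do.call(rbind, ends))
  names(df) <- if (params$mode == "loose") ls$locus_names else names(ls$w)
  df$stable <- stability
  df$converged <- convs
  df$polymorphic_loci <- cls
  df$pattern <- persisting
  df
}

# local stability via finite-difference Jacobian of the rhs.  In haplotype
# space only biologically accessible perturbations count: haplotypes in the
# support, their single-mutation neighbours, and recombinants of the
# support (double mutants that nothing generates cannot destabilize an
# equilibrium in a mutation-free model)
equilibrium_stable <- function(state, params, h = 1e-7, delta = 1e-8) {
  rhs <- if (params$mode == "loose")
    function(p) loose_linkage_rhs(p, params)
  else if (params$mode == "discrete")
    function(x) discrete_time_step(x, params) - x
  else function(x) ode_rhs(x, params)
  k <- length(state)
  dirs <- seq_len(k)
  if (params$mode != "loose") {
    ls <- params$landscape
    bits <- hap_bit_matrix(ls$n_loci)
    support <- unique(c(which(state > delta), params$continental))
    reach <- recombinant_closure(ls, support)
    for (s in support) {
      hd <- rowSums(bits != matrix(bits[s, ], k, ls$n_loci, byrow = TRUE))
      reach <- union(reach, which(hd == 1L))
    }
    dirs <- sort(reach)
  }
  f0 <- rhs(state)
  if (params$mode == "loose") {
    J <- matrix(0, length(dirs), length(dirs))
    for (jj in seq_along(dirs)) {
      s <- state; s[dirs[jj]] <- s[dirs[jj]] + h
      J[, jj] <- (rhs(s) - f0)[dirs] / h
    }
  } else {
    # perturb within the simplex (mass moved from the dominant haplotype),
    # so the off-simplex mass direction cannot masquerade as instability
    ref <- dirs[which.max(state[dirs])]
    dd <- setdiff(dirs, ref)
    if (!length(dd)) return(TRUE)
    J <- matrix(0, length(dd), length(dd))
    for (jj in seq_along(dd)) {
      s <- state; s[dd[jj]] <- s[dd[jj]] + h; s[ref] <- s[ref] - h
      J[, jj] <- (rhs(s) - f0)[dd] / h
    }
  }
  ev <- Re(eigen(J, only.values = TRUE)$values)
  all(ev < 1e-5)
}

# does a state maintained at migration rate m keep all queried island
# alleles above delta?
barrier_indicator <- function(m, query, params, init, tol, t_max) {
  params$m <- m
  # once an island allele has fallen far below the persistence threshold
  # the outcome is decided; abandoning the trajectory avoids resolving the
  # stiff final approach to the swamped vertex
  lost <- function(state)
    any(island_allele_freqs(state, query, params) < 1e-3 * query$delta)
  eq <- integrate_to_equilibrium(init, params, tol = tol, t_max = t_max,
                                 stop_fn = lost)
  ok <- !eq$stopped &&
    all(island_allele_freqs(eq$state, query, params) > query$delta)
  list(ok = ok, state = eq$state, converged = eq$converged)
}

#' Strength of a genetic barrier: the critical migration rate m_max
#'
#' Computes the maximum migration rate under which a stable equilibrium
#' retaining all queried island alleles (each above `delta`) persists, by
#' bisection on `m` of that indicator.  Under the `"local"` scope the
#' indicator is evaluated by numerical continuation: the equilibrium found
#' at the last sustainable (smaller) `m` seeds the next integration, with
#' the resident island haplotype (perturbed by the invader at frequency
#' `1e-6`) seeding the first.  Under the `"global"` scope the island
#' alleles must be retained from every member of a spanning set of initial
#' conditions.  The initial bracket is found on a logarithmic grid of
#' `m / alpha` (default `10^-3 .. 10^2`, with `alpha` the first direct
#' effect); if the barrier fails already at the smallest grid point the
#' barrier strength is 0.
#'
#' @param query a [barrier_query()].
#' @param params a [model_params()] for the same landscape (its `m` slot is
#'   ignored).
#' @param tol_m width of the final bisection bracket.
#' @param m_grid migration grid used to seed the bracket.
#' @param eq_tol,t_max convergence control of the inner integrations.
#' @return list of class `barrier_result`: `m_max`, `bracket`, `scope`,
#'   `mode`, and the last sustaining equilibrium `state`.
#' @examples
#' ls <- fitness_landscape(1)
#' q <- barrier_query(ls, "A")
#' pp <- model_params(ls, m = 0, continental_hap = "a", mode = "loose")
#' compute_mmax(q, pp, tol_m = 1e-3)$m_max  # ~ alpha
#' @export
compute_mmax <- function(query, params, tol_m = 1e-4,
                         m_grid = NULL, eq_tol = 1e-9, t_max = 1e5) {
  alpha <- abs(query$landscape$direct_effects[1L])
  if (alpha == 0) alpha <- 1
  if (is.null(m_grid)) m_grid <- alpha * 10^seq(-3, 2, by = 0.5)
  if (params$mode == "discrete") {
    # migration is a per-generation fraction in discrete time
    m_grid <- unique(c(m_grid[m_grid < 1], 1))
  }
  m_grid <- sort(m_grid)

  if (query$scope == "global") {
    init_set <- global_init_set(query, params)
    indicator <- function(m, warm) {
      res <- TRUE
      for (init in init_set) {
        r <- barrier_indicator(m, query, params, init, eq_tol, t_max)
        if (!r$ok) { res <- FALSE; break }
      }
      list(ok = res, state = NULL)
    }
  } else {
    indicator <- function(m, warm) {
      init <- if (is.null(warm)) resident_init(query, params) else warm
      barrier_indicator(m, query, params, init, eq_tol, t_max)
    }
  }

  warm <- NULL
  lo <- 0; hi <- NA; state_lo <- NULL
  for (m in m_grid) {
    r <- indicator(m, warm)
    if (r$ok) {
      lo <- m; warm <- r$state; state_lo <- r$state
    } else { hi <- m; break }
  }
  if (is.na(hi)) {
    # sustained on the whole grid: extend upward before giving up
    m <- max(m_grid)
    if (params$mode == "discrete") {
      warning("barrier sustained up to the maximal migration fraction 1")
      return(structure(list(m_max = 1, bracket = c(m, 1),
                            scope = query$scope, mode = params$mode,
                            state = state_lo),
                       class = "barrier_result"))
    }
    for (k in 1:3) {
      m <- m * 10
      r <- indicator(m, warm)
      if (!r$ok) { hi <- m; break }
      lo <- m; warm <- r$state; state_lo <- r$state
    }
    if (is.na(hi)) {
      warning("barrier sustained up to m = ", m, "; reporting that bound")
      return(structure(list(m_max = m, bracket = c(m, Inf),
                            scope = query$scope, mode = params$mode,
                            state = state_lo),
                       class = "barrier_result"))
    }
  }
  if (lo == 0) {
    # never sustained on the grid: the barrier has zero strength
    return(structure(list(m_max = 0, bracket = c(0, min(m_grid)),
                          scope = query$scope, mode = params$mode,
                          state = NULL),
                     class = "barrier_result"))
  }
  while (hi - lo > tol_m) {
    mid <- (lo + hi) / 2
    r <- indicator(mid, warm)
    if (r$ok) { lo <- mid; warm <- r$state; state_lo <- r$state }
    else hi <- mid
  }
  structure(list(m_max = (lo + hi) / 2, bracket = c(lo, hi),
                 scope = query$scope, mode = params$mode, state = state_lo),
            class = "barrier_result")
}

#' @export
print.barrier_result <- function(x, ...) {
  cat(sprintf("barrier strength m_max = %.6g (bracket [%.6g, %.6g], %s scope, %s mode)\n",
              x$m_max, x$bracket[1L], x$bracket[2L], x$scope, x$mode))
  invisible(x)
}

#' Scan the barrier strength over a model parameter
#'
#' Recomputes `m_max` on a grid of one scanned variable: a recombination
#' rate (`"r"`, applied to all adjacent gaps), an epistatic coefficient
#' (`"eps_AB"`, `"eps_abC"`) or the continental allele's direct effect
#' (`"beta"`) of the three-locus cryptic-epistasis scenario.  Scanning over
#' the migration rate itself is rejected (that is what `m_max` optimizes).
#'
#' @param scan_var one of `"r"`, `"eps_AB"`, `"eps_abC"`, `"beta"`.
#' @param grid numeric grid of scan values.
#' @param scenario for the epistasis/beta scans, a named list of baseline
#'   cryptic-scenario parameters
#'   (`alpha`, `beta`, `gamma_prime`, `eps_AB`, `eps_abC`, and optionally
#'   `ploidy`, `dominance`).
#' @param barrier,background,scope passed to [barrier_query()].
#' @param mode,recomb passed to [model_params()]; for the `"r"` scan the
#'   grid replaces `recomb` and the mode is `"ode"`.
#' @inheritParams compute_mmax
#' @return data frame with columns `value` (scan value), `m_max`, and `ok`
#'   (FALSE where the computation failed; errors are not propagated).
#' @export
parameter_scan <- function(scan_var, grid, scenario,
                           barrier = "Ab", background = "C",
                           scope = "local", mode = "loose", recomb = NULL,
                           tol_m = 1e-3, eq_tol = 1e-9, t_max = 1e5) {
  if (length(grid) == 0) stop("scan grid must be nonempty")
  scan_var <- as.character(scan_var)
  if (scan_var %in% c("m", "migration"))
    stop("the migration rate cannot be the scan variable; ",
         "m_max is itself the critical migration rate")
  if (!scan_var %in% c("r", "eps_AB", "eps_abC", "beta"))
    stop("unsupported scan variable \"", scan_var, "\"")
  build <- function(v) {
    sc <- scenario
    if (scan_var != "r") sc[[scan_var]] <- v
    ls <- scenario_landscape(sc$alpha, sc$beta, sc$gamma_prime,
                             sc$eps_AB, sc$eps_abC,
                             ploidy = if (is.null(sc$ploidy)) 1 else sc$ploidy,
                             dominance = sc$dominance)
    q <- barrier_query(ls, barrier, background, scope = scope)
    pp <- if (scan_var == "r")
      model_params(ls, 0, hap_string(ls, q$continental_hap),
                   recomb = v, mode = "ode")
    else model_params(ls, 0, hap_string(ls, q$continental_hap),
                      recomb = recomb, mode = mode)
    list(q = q, pp = pp)
  }
  rows <- lapply(grid, function(v) {
    out <- tryCatch({
      b <- build(v)
      res <- compute_mmax(b$q, b$pp, tol_m = tol_m,
                          eq_tol = eq_tol, t_max = t_max)
      data.frame(value = v, m_max = res$m_max, ok = TRUE)
    }, error = function(e) data.frame(value = v, m_max = NA_real_, ok = FALSE))
    out
  })
  do.call(rbind, rows)
}
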