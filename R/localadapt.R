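#' Declare an evolutionary scenario for local-adaptation analysis
#'
#' A scenario records, for each locus, where its derived allele originates:
#' `"island"` (appears and segregates on the island), `"continent"` (a
#' continental local adaptation, fixing instantaneously there) or `"both"`
#' (appears on the continent and subsequently fixes on both demes, becoming
#' a shared genetic background).  The admissible orders in which these
#' alleles can appear, together with the island states they generate,
#' determine the maximum amount of local adaptation `Lambda_max`.
#'
#' @inheritParams hap_index
#' @param origins character vector (length `n_loci`) over
#'   `c("island", "continent", "both")`.
#' @return object of class `history_scenario`.
#' @export
history_scenario <- function(landscape, origins) {
  origins <- match.arg(origins, c("island", "continent", "both"),
                       several.ok = TRUE)
  if (length(origins) != landscape$n_loci)
    stop("need one origin per locus")
  structure(list(landscape = landscape, origins = origins),
            class = "history_scenario")
}

# recombination closure of a haplotype set: every haplotype assembled from
# the alleles present at each locus
recombinant_closure <- function(landscape, hap_idx) {
  n <- landscape$n_loci
  bits <- hap_bit_matrix(n)
  keep <- rep(TRUE, 2L^n)
  for (j in seq_len(n)) {
    avail <- unique(bits[hap_idx, j])
    keep <- keep & (bits[, j] %in% avail)
  }
  which(keep)
}

new_history_state <- function(landscape, appeared, cont_idx, resident_idx,
                              label) {
  structure(list(appeared = appeared,
                 continental_hap = cont_idx,
                 island_resident = resident_idx,
                 island_present = recombinant_closure(
                   landscape, c(resident_idx, cont_idx)),
                 label = label),
            class = "history_state")
}

#' Current amount of local adaptation
#'
#' `Lambda`: the island-evaluated fitness advantage of the fittest
#' haplotype segregating on the island over a continental migrant.  At the
#' history-enumeration level the segregating set is the recombination
#' closure of the island resident and the continental haplotype (everything
#' migration plus recombination keeps regenerating).  Ploidy scaling makes
#' the diploid value identical to the haploid one.
#'
#' @param hist a `history_state` (from [enumerate_histories()]).
#' @inheritParams hap_index
#' @return the fitness difference `Lambda >= 0`.
#' @export
lambda_current <- function(hist, landscape) {
  max(landscape$w[hist$island_present]) - landscape$w[[hist$continental_hap]]
}

#' Enumerate admissible evolutionary histories
#'
#' Considers every order in which the scenario's derived alleles can
#' appear and filters by admissibility under the fitness landscape:
#' an island allele must have positive invasion fitness on the current
#' island resident (evaluated at migration -> 0); a continental allele is a
#' local adaptation to the continental environment and always admissible;
#' a both-fixing (background) allele appears on the continent only where
#' its marginal effect on the current continental haplotype is positive or
#' equals the best effect achievable on any continental background of the
#' scenario (the scenario asserts its global fixation; the assertion is
#' placed at the most favorable point, never on a strictly dominated
#' background), and it fixes on the island at the earliest later point at
#' which its effect on the island resident becomes positive, or failing
#' that at the end of the history.  With `exhaustive = TRUE` all filters
#' are disabled and background alleles fix immediately.
#'
#' @param scenario a [history_scenario()].
#' @param exhaustive disable the admissibility filter.
#' @return list of histories; each has `order` (locus appearance order) and
#'   `steps`, a list of `history_state`s (one per appearance or fixation
#'   event, including the transient state in which a background allele is
#'   fixed on the continent but not yet on the island).  An empty list
#'   (with a diagnostic attribute `reason`) means no admissible history.
#' @export
enumerate_histories <- function(scenario, exhaustive = FALSE) {
  ls <- scenario$landscape
  n <- ls$n_loci
  w_of <- function(bits) ls$w[[1L + sum(bits * 2L^(seq_len(n) - 1L))]]
  idx_of <- function(bits) 1L + sum(bits * 2L^(seq_len(n) - 1L))

  # best achievable continental marginal effect of each both-fixing allele
  best_cont_gain <- rep(NA_real_, n)
  cont_pool <- which(scenario$origins != "island")
  for (j in which(scenario$origins == "both")) {
    others <- setdiff(cont_pool, j)
    gains <- vapply(seq_len(2L^length(others)), function(si) {
      bg <- integer(n)
      if (length(others))
        bg[others] <- as.integer(bitwAnd(si - 1L,
                                         2L^(seq_along(others) - 1L)) > 0L)
      cand <- bg; cand[j] <- 1L
      w_of <- function(b) ls$w[[1L + sum(b * 2L^(seq_len(n) - 1L))]]
      w_of(cand) - w_of(bg)
    }, numeric(1))
    best_cont_gain[j] <- max(gains)
  }

  perms <- permutations(n)
  histories <- list()
  for (pi in seq_len(nrow(perms))) {
    ord <- perms[pi, ]
    cont <- integer(n); isl <- integer(n)
    pending <- integer(0)
    ok <- TRUE
    steps <- list()
    appeared <- character(0)
    push_step <- function(label) {
      steps[[length(steps) + 1L]] <<- new_history_state(
        ls, appeared, idx_of(cont), idx_of(isl), label)
    }
    settle_pending <- function() {
      repeat {
        fixed_one <- FALSE
        for (j in pending) {
          cand <- isl; cand[j] <- 1L
          if (exhaustive || w_of(cand) > w_of(isl)) {
            isl <<- cand
            pending <<- setdiff(pending, j)
            appeared <<- c(appeared, paste0(toupper(ls$locus_names[j]),
                                            ":fixes-island"))
            push_step(paste0(toupper(ls$locus_names[j]), " fixes on island"))
            fixed_one <- TRUE
          }
        }
        if (!fixed_one) break
      }
    }
    for (k in ord) {
      org <- scenario$origins[k]
      nm <- toupper(ls$locus_names[k])
      if (org == "island") {
        cand <- isl; cand[k] <- 1L
        if (!exhaustive && !(w_of(cand) > w_of(isl))) { ok <- FALSE; break }
        isl <- cand
        appeared <- c(appeared, paste0(nm, ":island"))
        push_step(paste0(nm, " appears on island"))
      } else if (org == "continent") {
        cont[k] <- 1L
        appeared <- c(appeared, paste0(nm, ":continent"))
        push_step(paste0(nm, " fixes on continent"))
      } else { # both
        candc <- cont; candc[k] <- 1L
        gain <- w_of(candc) - w_of(cont)
        if (!exhaustive && !(gain > 0 || gain >= best_cont_gain[k] - 1e-12)) {
          ok <- FALSE; break
        }
        cont <- candc
        appeared <- c(appeared, paste0(nm, ":continent"))
        push_step(paste0(nm, " fixes on continent"))
        pending <- c(pending, k)
      }
      settle_pending()
    }
    if (ok && length(pending)) {
      # the scenario asserts global fixation of background alleles; if the
      # island resident never makes the allele beneficial it is taken to
      # fix at the end of the history (the dynamical side of that
      # assumption is checked separately by check_background_fixation)
      for (j in pending) {
        isl[j] <- 1L
        appeared <- c(appeared, paste0(toupper(ls$locus_names[j]),
                                       ":fixes-island"))
        push_step(paste0(toupper(ls$locus_names[j]),
                         " fixes on island (asserted)"))
      }
      pending <- integer(0)
    }
    if (ok)
      histories[[length(histories) + 1L]] <-
        list(order = ls$locus_names[ord], steps = steps)
  }
  if (!length(histories))
    attr(histories, "reason") <-
      "no appearance order is admissible under the fitness landscape"
  histories
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Maximum amount of local adaptation
#'
#' `Lambda_max`: the largest current amount of local adaptation attained at
#' any step of any admissible evolutionary history of the scenario.  It is
#' a property of the fitness landscape (not of the current state) and upper
#' bounds the barrier strength for all simple-epistasis landscape classes.
#'
#' @inheritParams enumerate_histories
#' @param per_history if `TRUE`, also return the per-history, per-step
#'   `Lambda` values.
#' @return the value `Lambda_max`, or a list when `per_history = TRUE`.
#' @export
lambda_max <- function(scenario, exhaustive = FALSE, per_history = FALSE) {
  hh <- enumerate_histories(scenario, exhaustive = exhaustive)
  if (!length(hh))
    stop("Lambda_max undefined: ", attr(hh, "reason"))
  ls <- scenario$landscape
  per <- lapply(hh, function(h) {
    data.frame(step = vapply(h$steps, function(s) s$label, character(1)),
               lambda = vapply(h$steps, lambda_current, numeric(1),
                               landscape = ls))
  })
  lmax <- max(vapply(per, function(d) max(d$lambda), numeric(1)))
  if (per_history)
    list(lambda_max = lmax,
         histories = lapply(hh, `[[`, "order"),
         per_history = per)
  else lmax
}

#' Numerically check fixation of a background allele on the island
#'
#' For a scenario containing a both-fixing (background) allele: builds the
#' island equilibrium at the stated history point (the listed alleles
#' established, the focal allele absent), then fixes the focal allele on
#' the continent, introduces it on the island at frequency `1e-6`, and
#' integrates the dynamics.  Reports whether the allele reaches fixation
#' (frequency above `1 - delta`) on the island.
#'
#' @inheritParams enumerate_histories
#' @param params a [model_params()] whose landscape matches the scenario
#'   (its continental haplotype slot is overridden; its `m` is used).
#' @param after character vector of locus letters already established when
#'   the focal allele is introduced (island alleles on the island,
#'   continental ones on the continent).  Default: all non-focal loci.
#' @param delta fixation threshold.
#' @param t_max integration horizon.
#' @return list with `fixed` (logical), `freq` (final island frequency of
#'   the focal allele), `converged`, and the final `state`.
#' @export
check_background_fixation <- function(scenario, params, after = NULL,
                                      delta = 1e-6, t_max = 1e5) {
  ls <- scenario$landscape
  n <- ls$n_loci
  focal <- which(scenario$origins == "both")
  if (length(focal) != 1L)
    stop("scenario must contain exactly one both-fixing allele")
  if (is.null(after))
    after <- ls$locus_names[-focal]
  est <- match(toupper(after), toupper(ls$locus_names))
  cont <- integer(n); isl <- integer(n)
  for (k in est) {
    if (scenario$origins[k] == "island") isl[k] <- 1L else cont[k] <- 1L
  }
  cont_new <- cont; cont_new[focal] <- 1L

  # pre-introduction island equilibrium against the old continental hap
  p0 <- model_params(ls, params$m, hap_from_bits(cont),
                     recomb = params$recomb, mode = params$mode)
  if (params$mode == "loose") {
    init <- isl * (1 - 1e-6) + cont * 1e-6
  } else {
    init <- numeric(2L^n)
    init[1L + sum(isl * 2L^(seq_len(n) - 1L))] <- 1 - 1e-6
    init[1L + sum(cont * 2L^(seq_len(n) - 1L))] <- 1e-6
  }
  eq0 <- integrate_to_equilibrium(init, p0, tol = 1e-10, t_max = t_max)

  # focal allele fixes on the continent; introduce it on the island
  p1 <- model_params(ls, params$m, hap_from_bits(cont_new),
                     recomb = params$recomb, mode = params$mode)
  if (params$mode == "loose") {
    st <- eq0$state
    st[focal] <- max(st[focal], 1e-6)
  } else {
    st <- eq0$state
    bits <- hap_bit_matrix(n)
    donor <- which.max(st)
    carrier <- bits[donor, ]; carrier[focal] <- 1L
    ci <- 1L + sum(carrier * 2L^(seq_len(n) - 1L))
    st[ci] <- st[ci] + 1e-6
    st <- st / sum(st)
  }
  eq1 <- integrate_to_equilibrium(st, p1, tol = 1e-10, t_max = t_max)
  freq <- if (params$mode == "loose") eq1$state[focal]
          else drop(p1$cache$memb %*% eq1$state)[focal]
  list(fixed = is.finite(freq) && freq > 1 - delta,
       freq = unname(freq), converged = eq1$converged, state = eq1$state)
}
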