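#' Closed-form maximum of the two-locus barrier under negative epistasis
#'
#' Supremum over all negative epistasis strengths of the loose-linkage
#' haploid barrier `m_max^{Ab}` (island allele `A`, continental allele `B`),
#' as a piecewise function of the continental allele's direct effect:
#' `alpha` when `beta <= -alpha`; `(alpha - beta)^2 / (4 alpha)` when
#' `-alpha <= beta <= 0`; `alpha / 4` when `beta >= 0`.  In every regime the
#' value is strictly below the maximum amount of local adaptation, so a
#' two-locus DMI alone can never form a strong barrier.
#'
#' @param alpha direct advantage of the island allele (> 0).
#' @param beta direct effect of the continental allele on the island.
#' @return list with `value` and the `regime` label.
#' @export
max_two_locus_barrier <- function(alpha, beta) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta <= -alpha)
    list(value = alpha, regime = "beta <= -alpha")
  else if (beta <= 0)
    list(value = (alpha - beta)^2 / (4 * alpha),
         regime = "-alpha <= beta <= 0")
  else
    list(value = alpha / 4, regime = "beta >= 0")
}

#' Maximum two-locus barrier under positive epistasis
#'
#' With positive epistasis between `A` and `B` a barrier exists only if the
#' continental allele is deleterious on the island (`beta < 0`); its
#' supremum over epistasis strengths is `-beta`.  The bound
#' `m_max <= Lambda_max = alpha - beta` is attained only in the
#' compensatory limit `alpha = 0` (a neutral island allele that masks an
#' extremely deleterious `B`).
#'
#' @inheritParams max_two_locus_barrier
#' @return the supremum (0 when `beta >= 0`).
#' @export
positive_epistasis_max <- function(alpha, beta) {
  if (beta >= 0) 0 else -beta
}

#' Strong-barrier condition for the three-locus cryptic-epistasis scenario
#'
#' Decides, in closed form, whether the loose-linkage haploid barrier of
#' the cryptic-epistasis scenario exceeds the maximum amount of local
#' adaptation (`m_max^{Ab|C} > Lambda_max^{Ab|C}`).  Two strict-inequality
#' branches apply, for a locally deleterious (`beta < 0`) or beneficial
#' (`beta > 0`) continental allele; at the seam `beta = 0` both one-sided
#' conditions are evaluated and a disagreement is flagged.
#'
#' @inheritParams max_two_locus_barrier
#' @param eps_AB negative epistasis of the DMI.
#' @param eps_abC interaction of the background allele with the ancestral
#'   `ab` haplotype.
#' @return logical; for `beta = 0` with disagreeing one-sided limits, `NA`
#'   with a warning.
#' @export
strong_barrier_condition <- function(alpha, beta, eps_AB, eps_abC) {
  if (alpha <= 0) stop("alpha must be > 0")
  neg <- function(b)
    (eps_abC < (-eps_AB * (3 * alpha - 4 * b) + alpha * b) /
       (eps_AB + 4 * alpha - 3 * b)) && (eps_AB < -4 * alpha + 3 * b)
  pos <- function(b)
    (eps_abC < alpha * (b - 3 * eps_AB) / (4 * alpha + b + eps_AB)) &&
      (eps_AB < -(4 * alpha + b))
  if (beta < 0) neg(beta)
  else if (beta > 0) pos(beta)
  else {
    a <- neg(0); b <- pos(0)
    if (a != b) {
      warning("the two one-sided limits at beta = 0 disagree")
      NA
    } else a
  }
}

#' Analytic barrier strengths in limiting regimes
#'
#' `kind = "lethal_abC"`: with an inviable `abC` haplotype
#' (`eps_abC -> -Inf`, loose linkage, haploid) the barrier tends to
#' `-(eps_AB + beta) / 4` -- the limit is set by the hybrid fitness
#' deficit, not by local adaptation.  `kind = "recessive_tight"`: a diploid
#' barrier with recessive epistasis and tight linkage between `A` and `B`
#' never expresses the incompatibilities, so `m_max^{Ab|C} = alpha - beta`.
#'
#' @param kind `"lethal_abC"` or `"recessive_tight"`.
#' @param alpha,beta,eps_AB scenario parameters (only those the formula
#'   uses are required).
#' @return the analytic `m_max`.
#' @export
limit_formulas <- function(kind = c("lethal_abC", "recessive_tight"),
                           alpha = NULL, beta = NULL, eps_AB = NULL) {
  kind <- match.arg(kind)
  switch(kind,
         lethal_abC = -(eps_AB + beta) / 4,
         recessive_tight = alpha - beta)
}

#' Classify a landscape into the weak-barrier classes
#'
#' Tests the four structural conditions under which the maximum amount of
#' local adaptation provably bounds the barrier strength:
#' (1) some island allele takes part in no positive interaction, or some
#' continental allele in no negative interaction; (2) all derived alleles
#' originate on the same deme; (3) all epistatic interactions share one
#' sign; (4) continental and island derived alleles do not interact, or
#' interact only negatively.  Classes overlap (3 follows from 1 and 2, for
#' instance); the most structural match is reported first, in the order
#' 2, 3, 4, 1.  `"none"` means no condition holds -- for example the
#' cryptic-epistasis scenario, the prerequisite for a strong barrier.
#' Ancestral-pattern interactions are converted to their derived-allele
#' equivalent before testing, so both parameterizations classify
#' identically.
#'
#' @inheritParams hap_index
#' @param origins per-locus deme of origin (`"island"` / `"continent"`;
#'   `"both"`-fixing alleles count as continental, where they originate).
#' @return integer class 1-4, or `"none"`.
#' @export
weak_barrier_class_check <- function(landscape, origins) {
  n <- landscape$n_loci
  origins <- match.arg(origins, c("island", "continent", "both"),
                       several.ok = TRUE)
  if (length(origins) != n) stop("need one origin per locus")
  origins[origins == "both"] <- "continent"

  # derived-allele equivalent of every interaction term: an ancestral-
  # pattern term over loci S with ancestral subset Avec expands over the
  # derived superset by inclusion-exclusion; equivalently, collect the
  # nonzero interaction coefficients of the Taylor/Walsh expansion of w
  eps <- derived_interaction_coefficients(landscape)
  island <- which(origins == "island")
  continent <- which(origins == "continent")

  if (length(island) == 0L || length(continent) == 0L) return(2L)
  if (nrow(eps) && (all(eps$value > 0) || all(eps$value < 0))) return(3L)
  cross <- eps[vapply(eps$loci, function(s)
    any(s %in% island) && any(s %in% continent), logical(1)), , drop = FALSE]
  if (!nrow(cross) || all(cross$value < 0)) return(4L)
  involved <- function(locus) eps[vapply(eps$loci, function(s)
    locus %in% s, logical(1)), , drop = FALSE]
  cls1 <- any(vapply(island, function(l)
    all(involved(l)$value <= 0), logical(1))) ||
    any(vapply(continent, function(l)
      all(involved(l)$value >= 0), logical(1)))
  if (cls1) return(1L)
  "none"
}

# expand all interaction terms (including ancestral patterns) into the
# derived-allele basis: w(h) = sum_i b_i alpha_i + sum_S eps_S prod_{i in S} b_i
derived_interaction_coefficients <- function(landscape) {
  n <- landscape$n_loci
  bits <- hap_bit_matrix(n)
  H <- 2L^n
  w <- landscape$w
  # Moebius inversion over the subset lattice gives the unique polynomial
  # coefficients of w in the derived-allele indicators
  coefs <- numeric(H)
  for (i in seq_len(H)) {
    S <- which(bits[i, ] == 1L)
    sub <- which(apply(bits, 1L, function(b) all(which(b == 1L) %in% S)))
    coefs[i] <- sum(w[sub] * (-1)^(length(S) - rowSums(bits[sub, , drop = FALSE])))
  }
  keep <- which(rowSums(bits) >= 2L & abs(coefs) > 1e-12)
  data.frame(loci = I(lapply(keep, function(i) which(bits[i, ] == 1L))),
             value = coefs[keep])
}

#' Numeric supremum of the two-locus barrier over an epistasis grid
#'
#' Maximizes the numerically computed loose-linkage haploid barrier
#' `m_max^{Ab}` over a logarithmic grid of epistasis strengths, as an
#' independent check of the closed-form suprema
#' ([max_two_locus_barrier()], [positive_epistasis_max()]).
#'
#' @inheritParams max_two_locus_barrier
#' @param eps_sign `-1` to scan negative epistasis (DMI), `+1` positive.
#' @param eps_range absolute magnitude range of the grid.
#' @param n_grid grid size (log-spaced).
#' @param tol_m bisection tolerance of each inner [compute_mmax()] call.
#' @return list with `value` (the supremum), `eps_at_max`, and the scanned
#'   `table` (epsilon, m_max).
#' @export
numeric_two_locus_supremum <- function(alpha, beta, eps_sign = -1,
                                       eps_range = c(1e-3, 1e4),
                                       n_grid = 25, tol_m = 1e-3) {
  stopifnot(eps_sign %in% c(-1, 1))
  eps_grid <- eps_sign * 10^seq(log10(eps_range[1L]), log10(eps_range[2L]),
                                length.out = n_grid)
  mm <- vapply(eps_grid, function(e) {
    l <- fitness_landscape(c(alpha, beta),
                           epistasis = list(list(loci = 1:2, value = e)))
    q <- barrier_query(l, "Ab")
    compute_mmax(q, model_params(l, 0, "aB", mode = "loose"),
                 tol_m = tol_m)$m_max
  }, numeric(1))
  best <- which.max(mm)
  list(value = mm[best], eps_at_max = eps_grid[best],
       table = data.frame(eps_AB = eps_grid, m_max = mm))
}
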