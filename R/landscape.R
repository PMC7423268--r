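#' Multilocus diallelic fitness landscapes
#'
#' A `fitness_landscape` describes relative Malthusian fitnesses for all
#' `2^n` haplotypes at `n` diallelic loci (2-4 supported).  Each locus `i`
#' carries an ancestral allele (printed lowercase, e.g. `a`) and a derived
#' allele (uppercase, `A`) with direct selective advantage
#' `direct_effects[i]`.  Epistasis is a sum of interaction terms, each
#' attached to a subset of loci: ordinary terms are expressed when all
#' involved derived alleles are carried; "ancestral-pattern" terms (such as
#' an interaction `eps_abC` between a derived `C` and the ancestral `ab`
#' background) are expressed when the listed loci match the required
#' ancestral/derived pattern.  The fitness of the all-ancestral haplotype is
#' 0 by construction, so all fitnesses are relative to it.
#'
#' For diploids (`ploidy = 2`) direct effects are always codominant; the
#' `dominance` scheme controls how epistatic terms are expressed in
#' heterozygotes, see [genotype_fitness()].
#'
#' @param direct_effects numeric vector of per-locus selective advantages of
#'   the derived allele (Malthusian rates, relative scale; conventionally
#'   scaled so that the first island adaptation has effect 1).
#' @param epistasis list of interaction terms, each a `list(loci =, value =)`
#'   with `loci` an integer vector (length >= 2) of involved loci, all
#'   required to carry the derived allele.
#' @param ancestral_epistasis list of interaction terms keyed by a mixed
#'   ancestral/derived pattern, each a `list(pattern =, value =)` where
#'   `pattern` is a haplotype-letter string such as `"abC"`: lowercase
#'   letters require the ancestral allele, uppercase the derived allele, at
#'   the locus given by the letter's position in the locus names.
#' @param ploidy 1 (haploid) or 2 (diploid).
#' @param dominance for diploids, `"codominant"` or `"recessive"` expression
#'   of epistatic terms; must be `NULL` for haploids.
#' @param locus_names single letters naming the loci; defaults to
#'   `LETTERS[1:n]` so haplotypes print as e.g. `"AbC"`.
#'
#' @return an object of class `fitness_landscape` with precomputed haplotype
#'   fitness vector (attribute accessible via [haplotype_fitnesses()]).
#' @examples
#' # classical two-locus DMI: island adaptation A, continental allele B,
#' # negative epistasis between the derived alleles
#' ls2 <- fitness_landscape(direct_effects = c(1, -0.2),
#'                          epistasis = list(list(loci = c(1, 2), value = -10)))
#' haplotype_fitness(ls2, c("ab", "Ab", "aB", "AB"))
#' @seealso [haplotype_fitness()], [genotype_fitness()],
#'   [scenario_landscape()], [fitness_graph_analysis()]
#' @export
fitness_landscape <- function(direct_effects,
                              epistasis = list(),
                              ancestral_epistasis = list(),
                              ploidy = 1,
                              dominance = NULL,
                              locus_names = NULL) {
  n <- length(direct_effects)
  if (n < 1L || n > 4L)
    stop("between 1 and 4 loci are supported, got ", n)
  if (!is.numeric(direct_effects) || any(!is.finite(direct_effects)))
    stop("direct_effects must be finite numeric")
  if (!ploidy %in% c(1, 2)) stop("ploidy must be 1 or 2")
  if (ploidy == 2) {
    if (is.null(dominance))
      stop("a diploid landscape requires a dominance scheme ",
           "(\"codominant\" or \"recessive\")")
    dominance <- match.arg(dominance, c("codominant", "recessive"))
  } else if (!is.null(dominance)) {
    stop("dominance is only meaningful for ploidy = 2")
  }
  if (is.null(locus_names)) locus_names <- LETTERS[seq_len(n)]
  if (length(locus_names) != n || any(nchar(locus_names) != 1L))
    stop("locus_names must be single letters, one per locus")

  seen <- character(0)
  terms <- list()
  for (e in epistasis) {
    loci <- as.integer(e$loci)
    if (length(loci) < 2L || anyDuplicated(loci) ||
        any(loci < 1L | loci > n))
      stop("epistasis keys must be subsets of 1..n_loci of size >= 2")
    key <- paste(sort(loci), collapse = ",")
    if (key %in% seen)
      stop("duplicate epistasis key for loci {", key, "}")
    seen <- c(seen, key)
    terms[[length(terms) + 1L]] <-
      list(loci = sort(loci), derived = rep(TRUE, length(loci)),
           value = as.numeric(e$value))
  }
  for (e in ancestral_epistasis) {
    pat <- parse_allele_pattern(e$pattern, locus_names)
    if (length(pat$loci) < 2L)
      stop("ancestral_epistasis patterns must involve >= 2 loci")
    terms[[length(terms) + 1L]] <-
      list(loci = pat$loci, derived = pat$derived,
           value = as.numeric(e$value), pattern = e$pattern)
  }

  obj <- structure(
    list(n_loci = n,
         direct_effects = as.numeric(direct_effects),
         epistasis = epistasis,
         ancestral_epistasis = ancestral_epistasis,
         terms = terms,
         ploidy = ploidy,
         dominance = dominance,
         locus_names = locus_names),
    class = "fitness_landscape")
  obj$w <- compute_hap_fitnesses(obj)
  stopifnot(obj$w[[1L]] == 0)  # all-ancestral reference point
  obj
}

# parse "abC" style pattern -> loci indices + required-derived flags
parse_allele_pattern <- function(pattern, locus_names) {
  ch <- strsplit(pattern, "")[[1L]]
  loci <- match(toupper(ch), toupper(locus_names))
  if (any(is.na(loci)) || anyDuplicated(loci))
    stop("invalid allele pattern \"", pattern, "\" for loci ",
         paste(locus_names, collapse = ""))
  ord <- order(loci)
  list(loci = loci[ord], derived = (ch == toupper(ch))[ord])
}

# unambiguous bits -> index conversion for internal use
hap_from_bits <- function(bits) {
  as.integer(1L + sum(as.integer(bits) * 2L^(seq_along(bits) - 1L)))
}

# bits of haplotype index i (1-based): row of 0/1, bit j = derived at locus j
hap_bit_matrix <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}

#' Convert between haplotype strings and indices
#'
#' Haplotypes are indexed 1..2^n with locus 1 as the fastest-varying bit, so
#' for three loci the order is `abc, Abc, aBc, ABc, abC, AbC, aBC, ABC`.
#'
#' @param landscape a [fitness_landscape()].
#' @param hap haplotype(s) as letter strings (e.g. `"AbC"`), a 0/1 allele
#'   vector of length `n_loci` (read as such only when `n_loci >= 2`), or
#'   indices.
#' @return `hap_index` returns integer indices; `hap_string` returns letter
#'   strings.
#' @export
hap_index <- function(landscape, hap) {
  n <- landscape$n_loci
  if (is.character(hap)) {
    vapply(hap, function(h) {
      ch <- strsplit(h, "")[[1L]]
      if (length(ch) != n)
        stop("haplotype \"", h, "\" has length ", length(ch),
             " but the landscape has ", n, " loci")
      loci <- match(toupper(ch), toupper(landscape$locus_names))
      if (any(is.na(loci)))
        stop("haplotype \"", h, "\" does not match loci ",
             paste(landscape$locus_names, collapse = ""))
      bits <- integer(n)
      bits[loci] <- as.integer(ch == toupper(ch))
      as.integer(1L + sum(bits * 2L^(seq_len(n) - 1L)))
    }, integer(1), USE.NAMES = FALSE)
  } else if (is.numeric(hap) && n >= 2L && length(hap) == n &&
             all(hap %in% c(0, 1))) {
    # a 0/1 vector of length n_loci (>= 2) is an allele vector; plain
    # numbers are haplotype indices
    hap_from_bits(hap)
  } else if (is.numeric(hap)) {
    i <- as.integer(hap)
    if (any(i < 1L | i > 2L^n)) stop("haplotype index out of range")
    i
  } else stop("cannot interpret haplotype specification")
}

#' @rdname hap_index
#' @export
hap_string <- function(landscape, hap) {
  n <- landscape$n_loci
  bits <- hap_bit_matrix(n)
  idx <- hap_index(landscape, hap)
  vapply(idx, function(i) {
    paste(ifelse(bits[i, ] == 1L, toupper(landscape$locus_names),
                 tolower(landscape$locus_names)), collapse = "")
  }, character(1))
}

compute_hap_fitnesses <- function(landscape) {
  n <- landscape$n_loci
  bits <- hap_bit_matrix(n)
  w <- drop(bits %*% landscape$direct_effects)
  for (term in landscape$terms) {
    need <- as.integer(term$derived)
    match_term <- apply(bits[, term$loci, drop = FALSE], 1L,
                        function(b) all(b == need))
    w <- w + ifelse(match_term, term$value, 0)
  }
  names(w) <- apply(bits, 1L, function(b)
    paste(ifelse(b == 1L, toupper(landscape$locus_names),
                 tolower(landscape$locus_names)), collapse = ""))
  w
}

#' Haplotype fitness
#'
#' Fitness of a haplotype: the sum of the direct effects of the derived
#' alleles it carries plus every epistatic term whose allele pattern it
#' matches.  The all-ancestral haplotype has fitness 0.
#'
#' @inheritParams hap_index
#' @return numeric vector of relative Malthusian fitnesses.
#' @examples
#' ls2 <- fitness_landscape(c(1, -0.2),
#'                          epistasis = list(list(loci = 1:2, value = -10)))
#' haplotype_fitness(ls2, "AB")  # 1 - 0.2 - 10
#' @export
haplotype_fitness <- function(landscape, hap) {
  unname(landscape$w[hap_index(landscape, hap)])
}

#' @return `haplotype_fitnesses` returns the named vector of all `2^n`
#'   haplotype fitnesses in index order.
#' @rdname haplotype_fitness
#' @export
haplotype_fitnesses <- function(landscape) landscape$w

#' Diploid genotype fitness (ploidy-scaled)
#'
#' Fitness of an unordered pair of haplotypes on a diploid landscape, on the
#' ploidy-scaled convention: fitness differences between genotypes are
#' divided by the ploidy, so that the difference between the two homozygotes
#' `h/h` and `anc/anc` equals the haploid fitness of `h`.  Direct effects
#' are codominant: locus `i` contributes `(dosage_i / 2) * alpha_i`.
#' Under the `"codominant"` scheme an epistatic term contributes its value
#' times the product over involved loci of (required-allele dosage / 2);
#' under the `"recessive"` scheme it contributes its full value only when
#' every involved locus is homozygous for the required allele, and nothing
#' otherwise (so incompatibilities are silent in double and triple
#' heterozygotes).
#'
#' @inheritParams hap_index
#' @param hap1,hap2 the two haplotypes of the genotype.
#' @return ploidy-scaled Malthusian fitness relative to the all-ancestral
#'   homozygote.
#' @examples
#' lsd <- fitness_landscape(c(1, -0.2),
#'                          epistasis = list(list(loci = 1:2, value = -10)),
#'                          ploidy = 2, dominance = "codominant")
#' genotype_fitness(lsd, "Ab", "aB")  # (1 - 0.2)/2 + (-10)/4
#' @export
genotype_fitness <- function(landscape, hap1, hap2) {
  if (landscape$ploidy != 2)
    stop("genotype_fitness requires a diploid landscape (ploidy = 2)")
  i <- hap_index(landscape, hap1)
  j <- hap_index(landscape, hap2)
  G <- genotype_fitness_matrix(landscape)
  G[cbind(i, j)]
}

# full 2^n x 2^n ploidy-scaled genotype fitness matrix; cached on first use
genotype_fitness_matrix <- function(landscape) {
  if (!is.null(landscape$G)) return(landscape$G)
  n <- landscape$n_loci
  bits <- hap_bit_matrix(n)
  H <- 2L^n
  G <- matrix(0, H, H)
  for (i in seq_len(H)) for (j in seq_len(i)) {
    dos <- bits[i, ] + bits[j, ]              # derived dosage per locus
    f <- sum(dos / 2 * landscape$direct_effects)
    for (term in landscape$terms) {
      req <- ifelse(term$derived, dos[term$loci], 2 - dos[term$loci])
      f <- f + switch(landscape$dominance,
        codominant = term$value * prod(req / 2),
        recessive  = if (all(req == 2)) term$value else 0)
    }
    G[i, j] <- G[j, i] <- f
  }
  dimnames(G) <- list(names(landscape$w), names(landscape$w))
  G
}

# attach the cached genotype matrix (used by dynamics for speed)
with_genotype_cache <- function(landscape) {
  if (landscape$ploidy == 2 && is.null(landscape$G))
    landscape$G <- genotype_fitness_matrix(landscape)
  landscape
}

#' Three-locus cryptic-epistasis scenario landscape
#'
#' Builds the minimal three-locus landscape in which a two-locus DMI
#' (island adaptation `A`, continental allele `B`, negative epistasis
#' `eps_AB`) interacts with a background allele `C` that fixes in both
#' demes.  The landscape is parameterized by `gamma_prime`, the effect of
#' the `C` mutation in the background of at least one other derived allele,
#' and `eps_abC`, the (typically strongly negative) interaction of `C` with
#' the all-ancestral `ab` background.  This is equivalent to the
#' derived-allele parameterization with `eps_AC = eps_BC = -eps_abC`,
#' `eps_ABC = eps_abC` and direct effect `gamma = gamma_prime + eps_abC`
#' at the `C` locus; [cryptic_to_derived()] performs the exact round trip.
#'
#' @param alpha direct advantage of the island allele `A` (must be nonzero;
#'   all rates are conventionally scaled by it).
#' @param beta direct effect of the continental allele `B` on the island.
#' @param gamma_prime effect of `C` next to at least one derived allele.
#' @param eps_AB pairwise epistasis between `A` and `B` (the DMI).
#' @param eps_abC interaction of `C` with the ancestral `ab` background.
#' @inheritParams fitness_landscape
#' @return a three-locus [fitness_landscape()].
#' @examples
#' ls <- scenario_landscape(1, -0.2, 0.1, -10, -20)
#' haplotype_fitness(ls, "AbC") - haplotype_fitness(ls, "aBC")  # alpha - beta
#' @export
scenario_landscape <- function(alpha, beta, gamma_prime, eps_AB, eps_abC,
                               ploidy = 1, dominance = NULL) {
  if (alpha == 0)
    stop("alpha must be nonzero (it sets the scale of the model)")
  fitness_landscape(
    direct_effects = c(alpha, beta, gamma_prime),
    epistasis = list(list(loci = c(1, 2), value = eps_AB)),
    ancestral_epistasis = list(list(pattern = "abC", value = eps_abC)),
    ploidy = ploidy, dominance = dominance)
}

#' Convert between the cryptic and derived-allele parameterizations
#'
#' The `(gamma_prime, eps_abC)` description of the three-locus scenario and
#' the derived-allele description `(gamma, eps_AC, eps_BC, eps_ABC)` with
#' `eps_AC = eps_BC = -eps_ABC` generate identical haplotype fitnesses.
#'
#' @param gamma_prime,eps_abC cryptic parameterization.
#' @param gamma,eps_AC derived-allele parameterization.
#' @return named list with the parameters of the other parameterization.
#' @export
cryptic_to_derived <- function(gamma_prime, eps_abC) {
  eps_AC <- -eps_abC
  list(gamma = gamma_prime - eps_AC,
       eps_AC = eps_AC, eps_BC = eps_AC, eps_ABC = -eps_AC)
}

#' @rdname cryptic_to_derived
#' @export
derived_to_cryptic <- function(gamma, eps_AC) {
  list(gamma_prime = gamma + eps_AC, eps_abC = -eps_AC)
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("fitness_landscape: %d loci (%s), ploidy %d%s\n",
              x$n_loci, paste(x$locus_names, collapse = ""), x$ploidy,
              if (is.null(x$dominance)) ""
              else paste0(", ", x$dominance, " epistasis")))
  cat("haplotype fitnesses:\n")
  print(round(x$w, 6))
  invisible(x)
}
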