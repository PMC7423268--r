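# shared builders for the scenarios used across the suite

# classical two-locus DMI: island A, continental B, epistasis eps
dmi2 <- function(alpha = 1, beta = -0.2, eps = -10, ...) {
  fitness_landscape(c(alpha, beta),
                    epistasis = list(list(loci = 1:2, value = eps)), ...)
}

# three-locus cryptic-epistasis scenario with the background allele C
cryptic <- function(alpha = 1, beta = -0.2, gamma_prime = 0.1,
                    eps_AB = -10, eps_abC = -20, ...) {
  scenario_landscape(alpha, beta, gamma_prime, eps_AB, eps_abC, ...)
}

cryptic_origins <- c("island", "continent", "both")

# m_max for the standard "maintain A and b" query of a landscape
mmax_of <- function(landscape, barrier = "Ab", background = NULL,
                    mode = "loose", recomb = NULL, scope = "local",
                    tol_m = 1e-3, ...) {
  q <- barrier_query(landscape, barrier, background, scope = scope)
  pp <- model_params(landscape, 0, hap_string(landscape, q$continental_hap),
                     recomb = recomb, mode = mode)
  compute_mmax(q, pp, tol_m = tol_m, ...)$m_max
}

# a random simplex point
rsimplex <- function(k) { x <- stats::rexp(k); x / sum(x) }

# internal helpers reached through the namespace
hap_bit_matrix_of <- function(ls) barrierflow:::hap_bit_matrix(ls$n_loci)
recombine_discrete_of <- function(x, pp) barrierflow:::recombine_discrete(x, pp)
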