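#' Random landscapes from the weak-barrier classes
#'
#' Samples a fitness landscape (with per-locus deme-of-origin annotation)
#' that provably belongs to one of the four structural classes for which
#' the maximum amount of local adaptation bounds the barrier strength:
#' 1. some island allele takes part in no positive interaction, or some
#'    continental allele in no negative interaction;
#' 2. all derived alleles originate on one deme;
#' 3. all epistatic interactions share a single sign;
#' 4. continental and island alleles do not interact, or only negatively.
#'
#' Island-origin alleles draw direct effects from `U(0.3, 1)` (they must be
#' able to establish), continental ones from `U(-0.8, 0.8)` (a continental
#' adaptation may be deleterious, neutral or beneficial on the island);
#' pairwise (and for three loci, three-way) interactions are present with
#' probability 0.7 and draw magnitudes from `U(0.2, 3)`, with signs
#' constrained by the requested class.  Draws without any admissible
#' evolutionary history are rejected and redrawn, so `Lambda_max` is always
#' defined for the returned landscape.  Deterministic under `seed`.
#'
#' @param class_id integer 1-4.
#' @param n_loci number of loci (2-4; classes 1, 3 and 4 need mixed demes,
#'   hence at least 2 loci).
#' @param seed RNG seed.
#' @return a [fitness_landscape()] with attributes `origins` (per-locus
#'   deme of origin) and `class_id`.
#' @export
random_landscape <- function(class_id, n_loci = 3L, seed = 1L) {
  if (!class_id %in% 1:4) stop("class_id must be 1, 2, 3 or 4")
  if (n_loci < 2L || n_loci > 4L)
    stop("weak-barrier classes are defined for 2-4 loci")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  for (attempt in 1:200) {
    if (class_id == 2L) {
      deme <- sample(c("island", "continent"), 1L)
      origins <- rep(deme, n_loci)
    } else {
      repeat {
        origins <- sample(c("island", "continent"), n_loci, replace = TRUE)
        if (length(unique(origins)) == 2L) break
      }
    }
    direct <- ifelse(origins == "island",
                     stats::runif(n_loci, 0.3, 1),
                     stats::runif(n_loci, -0.8, 0.8))
    subsets <- all_subsets(n_loci)
    eps <- list()
    sign_all <- sample(c(-1, 1), 1L)             # class 3 common sign
    anchor <- NULL
    if (class_id == 1L) {
      clause <- sample(c("island", "continent"), 1L)
      anchor <- sample(which(origins == clause), 1L)
      anchor_sign <- if (clause == "island") -1 else 1
    }
    for (s in subsets) {
      if (stats::runif(1) > 0.7) next
      mag <- stats::runif(1, 0.2, 3)
      sgn <- switch(class_id,
        `1` = if (!is.null(anchor) && anchor %in% s) anchor_sign
              else sample(c(-1, 1), 1L),
        `2` = sample(c(-1, 1), 1L),
        `3` = sign_all,
        `4` = if (any(origins[s] == "island") &&
                  any(origins[s] == "continent")) -1
              else sample(c(-1, 1), 1L))
      eps[[length(eps) + 1L]] <- list(loci = s, value = sgn * mag)
    }
    ls <- fitness_landscape(direct, epistasis = eps)
    scn <- history_scenario(ls, origins)
    hh <- enumerate_histories(scn)
    if (!length(hh)) next
    attr(ls, "origins") <- origins
    attr(ls, "class_id") <- class_id
    return(ls)
  }
  stop("could not satisfy class ", class_id, " constraints for ",
       n_loci, " loci after 200 attempts")
}

all_subsets <- function(n) {
  out <- list()
  for (size in 2:n) {
    cmb <- utils::combn(n, size)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, j]
  }
  out
}
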