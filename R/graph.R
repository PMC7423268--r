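#' Fitness graph analysis of a haploid landscape
#'
#' Builds the hypercube fitness graph (vertices = haplotypes, edges =
#' single-mutation neighbours, annotated by the sign of the fitness change)
#' and reports its local peaks.  For a designated pair of haplotypes
#' (typically the fittest island haplotype and the continental haplotype) it
#' checks whether the two are connected by a high-fitness ridge: a
#' single-mutation path whose every vertex has fitness at least
#' `min(w(island), w(continental)) - tol`.  If such a path exists within the
#' recombination closure of the pair (all haplotypes constructible by
#' recombining the two), the ridge is flagged as recombination-closed,
#' meaning migration plus recombination alone regenerate every step of the
#' ridge.  Absence of a ridge means the pair sits on two peaks separated by
#' a fitness valley.
#'
#' @inheritParams hap_index
#' @param island_hap,continental_hap the haplotype pair to connect; default
#'   is the globally fittest haplotype versus the all-ancestral one.
#' @param background optional allele pattern string (e.g. `"C"`) restricting
#'   the analysis to the sub-cube where the listed loci are fixed for the
#'   indicated alleles.
#' @param tol fitness slack when thresholding ridge membership.
#' @return a list of class `fitness_graph_report` with elements `graph`
#'   (an igraph object), `peaks` (haplotype names of local fitness maxima),
#'   `ridge_exists`, `ridge_recomb_closed`, `valley` (no ridge at all) and
#'   `ridge_path` (one qualifying path, if any).
#' @examples
#' ls <- scenario_landscape(1, -0.2, 0.1, -10, -20)
#' fitness_graph_analysis(ls, "AbC", "aBC", background = "C")
#' @export
fitness_graph_analysis <- function(landscape, island_hap = NULL,
                                   continental_hap = NULL,
                                   background = NULL, tol = 1e-9) {
  n <- landscape$n_loci
  H <- 2L^n
  bits <- hap_bit_matrix(n)
  w <- landscape$w

  keep <- rep(TRUE, H)
  if (!is.null(background)) {
    pat <- parse_allele_pattern(background, landscape$locus_names)
    for (k in seq_along(pat$loci))
      keep <- keep & (bits[, pat$loci[k]] == as.integer(pat$derived[k]))
  }
  verts <- which(keep)

  # single-mutation edges within the retained sub-cube
  edges <- integer(0)
  for (a in verts) for (b in verts) if (a < b) {
    if (sum(bits[a, ] != bits[b, ]) == 1L) edges <- c(edges, a, b)
  }
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  igraph::V(g)$name <- names(w)[verts]
  igraph::V(g)$fitness <- w[verts]
  if (length(edges)) {
    emap <- match(edges, verts)
    g <- igraph::add_edges(g, emap)
    ea <- matrix(edges, ncol = 2L, byrow = TRUE)
    igraph::E(g)$dw <- w[ea[, 2L]] - w[ea[, 1L]]
    igraph::E(g)$sign <- sign(igraph::E(g)$dw)
  }

  # local peaks: fitter than every single-mutation neighbour in the sub-cube
  peaks <- vapply(seq_along(verts), function(k) {
    nb <- igraph::neighbors(g, k)
    length(nb) == 0L || all(w[verts[k]] > igraph::V(g)$fitness[nb])
  }, logical(1))

  if (is.null(island_hap)) island_hap <- verts[which.max(w[verts])]
  if (is.null(continental_hap)) continental_hap <- verts[1L]
  i_isl <- hap_index(landscape, island_hap)
  i_con <- hap_index(landscape, continental_hap)
  if (!all(c(i_isl, i_con) %in% verts))
    stop("island/continental haplotype outside the designated background")

  thresh <- min(w[i_isl], w[i_con]) - tol
  # recombination closure of the pair: per-locus allele sets
  closure <- rep(TRUE, H)
  for (j in seq_len(n)) {
    avail <- unique(c(bits[i_isl, j], bits[i_con, j]))
    closure <- closure & (bits[, j] %in% avail)
  }

  ridge_path <- function(allowed) {
    ok <- verts %in% which(allowed) & (w[verts] >= thresh)
    ok[match(c(i_isl, i_con), verts)] <- TRUE
    sub <- igraph::induced_subgraph(g, which(ok))
    from <- match(names(w)[i_isl], igraph::V(sub)$name)
    to <- match(names(w)[i_con], igraph::V(sub)$name)
    sp <- suppressWarnings(igraph::shortest_paths(sub, from, to)$vpath[[1L]])
    if (length(sp) == 0L) NULL else igraph::V(sub)$name[as.integer(sp)]
  }

  path_any <- ridge_path(rep(TRUE, H))
  path_closed <- ridge_path(closure)

  structure(list(graph = g,
                 peaks = igraph::V(g)$name[peaks],
                 island_hap = names(w)[i_isl],
                 continental_hap = names(w)[i_con],
                 ridge_exists = !is.null(path_any),
                 ridge_recomb_closed = !is.null(path_closed),
                 valley = is.null(path_any),
                 ridge_path = if (!is.null(path_closed)) path_closed
                              else path_any),
            class = "fitness_graph_report")
}

#' @export
print.fitness_graph_report <- function(x, ...) {
  cat("fitness graph:", igraph::vcount(x$graph), "haplotypes,",
      igraph::ecount(x$graph), "single-mutation edges\n")
  cat("local peaks:", paste(x$peaks, collapse = ", "), "\n")
  cat(sprintf("pair %s (island) vs %s (continent): %s\n",
              x$island_hap, x$continental_hap,
              if (x$valley) "separated by a fitness valley"
              else if (x$ridge_recomb_closed)
                "connected by a recombination-closed fitness ridge"
              else "connected by a fitness ridge (not recombination-closed)"))
  if (!is.null(x$ridge_path))
    cat("ridge path:", paste(x$ridge_path, collapse = " -> "), "\n")
  invisible(x)
}
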