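#' Read and write fitness landscapes
#'
#' Landscapes serialize to YAML or JSON (chosen by file extension) with
#' keys `n_loci`, `direct_effects`, `epistasis` (list of `{loci, value}`),
#' `ancestral_epistasis` (list of `{pattern, value}`), `ploidy` and
#' `dominance`.
#'
#' @inheritParams hap_index
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_landscape` returns a [fitness_landscape()];
#'   `write_landscape` returns `path` invisibly.
#' @export
write_landscape <- function(landscape, path) {
  obj <- list(n_loci = landscape$n_loci,
              direct_effects = landscape$direct_effects,
              epistasis = lapply(landscape$epistasis, function(e)
                list(loci = as.integer(e$loci), value = e$value)),
              ancestral_epistasis = lapply(landscape$ancestral_epistasis,
                                           function(e)
                list(pattern = e$pattern, value = e$value)),
              ploidy = landscape$ploidy,
              dominance = landscape$dominance)
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  landscape_from_list(obj)
}

landscape_from_list <- function(obj) {
  known <- c("n_loci", "direct_effects", "epistasis", "ancestral_epistasis",
             "ploidy", "dominance")
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown landscape keys: ", paste(unknown, collapse = ", "))
  de <- as.numeric(unlist(obj$direct_effects))
  if (!is.null(obj$n_loci) && length(de) != obj$n_loci)
    stop("direct_effects has length ", length(de),
         " but n_loci is ", obj$n_loci)
  fitness_landscape(
    direct_effects = de,
    epistasis = lapply(obj$epistasis, function(e)
      list(loci = as.integer(unlist(e$loci)), value = as.numeric(e$value))),
    ancestral_epistasis = lapply(obj$ancestral_epistasis, function(e)
      list(pattern = as.character(e$pattern), value = as.numeric(e$value))),
    ploidy = if (is.null(obj$ploidy)) 1 else obj$ploidy,
    dominance = obj$dominance)
}

#' Scenario presets
#'
#' Named parameter sets for the models analysed in depth:
#' * `dmi2` -- the classical two-locus DMI (island `A`, continental `B`,
#'   strong negative epistasis).
#' * `cryptic_deleteriousB` -- the three-locus cryptic-epistasis scenario
#'   with a continental allele deleterious on the island
#'   (`beta/alpha = -0.2`, `eps_AB/alpha = -10`, `eps_abC/alpha = -20`);
#'   its barrier is strong once recombination is appreciable.
#' * `cryptic_beneficialB` -- the same with a continental allele that is
#'   beneficial on the island (`beta/alpha = 1.2`); its tight-linkage
#'   barrier strength is 0.
#' * `cryptic_diploid_codominant`, `cryptic_diploid_recessive` -- diploid
#'   variants of `cryptic_deleteriousB` under the two dominance schemes.
#'
#' The background effect `gamma_prime/alpha = 0.1` (beneficial next to a
#' derived partner) is a convention; a fixed background shifts all island
#' fitnesses equally, so barrier strengths do not depend on it.
#'
#' @param name preset name.
#' @return named list of scenario parameters (`alpha`, `beta`,
#'   `gamma_prime`, `eps_AB`, `eps_abC`, `ploidy`, `dominance`, plus
#'   `barrier`/`background` query strings).
#' @export
preset_scenario <- function(name = c("dmi2", "cryptic_deleteriousB",
                                     "cryptic_beneficialB",
                                     "cryptic_diploid_codominant",
                                     "cryptic_diploid_recessive")) {
  name <- match.arg(name)
  base <- list(alpha = 1, beta = -0.2, gamma_prime = 0.1,
               eps_AB = -10, eps_abC = -20, ploidy = 1, dominance = NULL,
               barrier = "Ab", background = "C")
  switch(name,
    dmi2 = list(alpha = 1, beta = -0.2, gamma_prime = NULL, eps_AB = -10,
                eps_abC = NULL, ploidy = 1, dominance = NULL,
                barrier = "Ab", background = NULL),
    cryptic_deleteriousB = base,
    cryptic_beneficialB = utils::modifyList(base, list(beta = 1.2)),
    cryptic_diploid_codominant =
      utils::modifyList(base, list(ploidy = 2, dominance = "codominant")),
    cryptic_diploid_recessive =
      utils::modifyList(base, list(ploidy = 2, dominance = "recessive")))
}

scenario_to_landscape <- function(sc) {
  if (is.null(sc$gamma_prime)) {
    fitness_landscape(c(sc$alpha, sc$beta),
                      epistasis = list(list(loci = c(1, 2),
                                            value = sc$eps_AB)),
                      ploidy = sc$ploidy, dominance = sc$dominance)
  } else {
    scenario_landscape(sc$alpha, sc$beta, sc$gamma_prime, sc$eps_AB,
                       sc$eps_abC, ploidy = sc$ploidy,
                       dominance = sc$dominance)
  }
}

#' Parse a scenario configuration file
#'
#' Reads a YAML or JSON configuration with blocks `landscape` (or a
#' top-level `preset` name), `dynamics` (`m`, `recomb`, `mode`), `query`
#' (`barrier`, `background`, `scope`, `delta`), optional `scan`
#' (`var`, `min`, `max`, `steps`, `log`), an `action` (one of `"mmax"`,
#' `"scan"`, `"lambda-max"`, `"simulate"`), and optional `rng_seed` /
#' `output`.  Missing entries receive the package defaults (loose-linkage
#' mode, `delta = 1e-6`, `m = 0`, local scope).  Unknown keys anywhere are
#' an error naming the offending keys.
#'
#' @param path configuration file.
#' @return validated configuration of class `scenario_config` with the
#'   landscape already constructed.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  known <- c("preset", "landscape", "dynamics", "query", "scan", "action",
             "rng_seed", "output")
  unknown <- setdiff(names(obj), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))

  if (!is.null(obj$preset)) {
    sc <- preset_scenario(obj$preset)
    landscape <- scenario_to_landscape(sc)
    if (is.null(obj$query))
      obj$query <- list(barrier = sc$barrier, background = sc$background)
  } else if (!is.null(obj$landscape)) {
    landscape <- landscape_from_list(obj$landscape)
  } else stop("config needs either a \"landscape\" block or a \"preset\"")

  dyn <- obj$dynamics
  dyn_known <- c("m", "recomb", "mode")
  if (length(setdiff(names(dyn), dyn_known)))
    stop("unknown dynamics keys: ",
         paste(setdiff(names(dyn), dyn_known), collapse = ", "))
  if (is.null(dyn$m)) dyn$m <- 0
  if (is.null(dyn$mode)) dyn$mode <- "loose"
  dyn$recomb <- if (is.null(dyn$recomb)) NULL else as.numeric(unlist(dyn$recomb))

  qry <- obj$query
  qry_known <- c("barrier", "background", "scope", "delta")
  if (length(setdiff(names(qry), qry_known)))
    stop("unknown query keys: ",
         paste(setdiff(names(qry), qry_known), collapse = ", "))
  if (is.null(qry$scope)) qry$scope <- "local"
  if (is.null(qry$delta)) qry$delta <- 1e-6
  query <- if (is.null(qry$barrier)) NULL else
    barrier_query(landscape, qry$barrier, qry$background,
                  scope = qry$scope, delta = qry$delta)

  scan <- obj$scan
  if (!is.null(scan)) {
    scan_known <- c("var", "min", "max", "steps", "log")
    if (length(setdiff(names(scan), scan_known)))
      stop("unknown scan keys: ",
           paste(setdiff(names(scan), scan_known), collapse = ", "))
  }

  structure(list(landscape = landscape, dynamics = dyn, query = query,
                 query_spec = qry, scan = scan,
                 action = if (is.null(obj$action)) "mmax" else obj$action,
                 rng_seed = obj$rng_seed, output = obj$output,
                 preset = obj$preset),
            class = "scenario_config")
}

#' Run a preset analysis and write its tables
#'
#' For the haploid cryptic presets, scans the barrier strength
#' `m_max^{Ab|C}` (and the pre-background `m_max^{Ab|c}`) over a grid of
#' recombination rates, writing a TSV plus a JSON run manifest (parameters,
#' seed, package version, wall time).  For the diploid presets, computes
#' the strong-barrier boundary (the critical `eps_abC` below which
#' `m_max > Lambda_max`) over a grid of `eps_AB` values.
#'
#' @inheritParams preset_scenario
#' @param out_dir directory for the TSV/JSON outputs.
#' @param grid scan grid: recombination rates (haploid presets) or `eps_AB`
#'   values (diploid presets); small defaults keep runs quick.
#' @param tol_m bisection tolerance passed down to [compute_mmax()].
#' @param seed recorded in the manifest (the computation is deterministic).
#' @return data frame of results, invisibly; files are written as a side
#'   effect.
#' @export
run_preset <- function(name, out_dir = ".", grid = NULL,
                       tol_m = 1e-3, seed = 1L) {
  t0 <- Sys.time()
  sc <- preset_scenario(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ls <- scenario_to_landscape(sc)

  if (identical(sc$ploidy, 2)) {
    if (is.null(grid)) grid <- c(-12, -9, -6)
    rows <- lapply(grid, function(e) {
      thr <- tryCatch(numeric_strong_barrier_boundary(
        sc$alpha, sc$beta, e, sc$gamma_prime,
        ploidy = 2, dominance = sc$dominance, tol = 0.1),
        error = function(err) NA_real_)
      data.frame(eps_AB = e, eps_abC_threshold = thr)
    })
    tab <- do.call(rbind, rows)
    tsv <- file.path(out_dir, paste0(name, "_boundary.tsv"))
  } else if (!is.null(sc$gamma_prime)) {
    if (is.null(grid)) grid <- c(0, 0.5, 2, 10, 50)
    rows <- lapply(grid, function(r) {
      q <- barrier_query(ls, sc$barrier, sc$background)
      pp <- if (r == 0)
        model_params(ls, 0, hap_string(ls, q$continental_hap), mode = "tight")
      else model_params(ls, 0, hap_string(ls, q$continental_hap),
                        recomb = r, mode = "ode")
      res <- compute_mmax(q, pp, tol_m = tol_m)
      data.frame(r = r, m_max_AbC = res$m_max)
    })
    tab <- do.call(rbind, rows)
    scn <- history_scenario(ls, c("island", "continent", "both"))
    tab$lambda_max <- lambda_max(scn)
    tsv <- file.path(out_dir, paste0(name, "_scan.tsv"))
  } else {
    if (is.null(grid)) grid <- c(0, 0.5, 2, 10, 50)
    rows <- lapply(grid, function(r) {
      q <- barrier_query(ls, sc$barrier)
      pp <- if (r == 0)
        model_params(ls, 0, hap_string(ls, q$continental_hap), mode = "tight")
      else model_params(ls, 0, hap_string(ls, q$continental_hap),
                        recomb = r, mode = "ode")
      res <- compute_mmax(q, pp, tol_m = tol_m)
      data.frame(r = r, m_max_Ab = res$m_max)
    })
    tab <- do.call(rbind, rows)
    tsv <- file.path(out_dir, paste0(name, "_scan.tsv"))
  }
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(preset = name, parameters = sc[!vapply(sc, is.null,
                                                          logical(1))],
                   grid = grid, tol_m = tol_m, seed = seed,
                   package_version = as.character(utils::packageVersion(
                     "barrierflow")),
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir,
                                           paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tab)
}

#' Generate labelled random-landscape fixtures
#'
#' Writes `n_per_class` random landscapes for each weak-barrier class 1-4
#' plus cryptic-epistasis instances sampled inside and outside the
#' strong-barrier region, together with a JSON manifest recording the
#' property each fixture must satisfy (`m_max <= Lambda_max` for the weak
#' classes; the sign of `m_max - Lambda_max` for the cryptic instances).
#' Byte-identical output under a fixed seed.
#'
#' @param seed RNG seed.
#' @param n_per_class landscapes per weak-barrier class (>= 1).
#' @param dir output directory.
#' @return the manifest, invisibly.
#' @export
generate_fixtures <- function(seed, n_per_class = 1L, dir = ".") {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (cls in 1:4) for (k in seq_len(n_per_class)) {
    ls <- random_landscape(cls, n_loci = 3L,
                           seed = seed + 1000L * cls + k)
    f <- sprintf("class%d_%02d.yaml", cls, k)
    write_landscape(ls, file.path(dir, f))
    entries[[length(entries) + 1L]] <-
      list(file = f, class = cls,
           origins = attr(ls, "origins"),
           property = "m_max <= Lambda_max")
  }
  # cryptic instances straddling the strong-barrier region
  set.seed(seed)
  for (k in seq_len(max(2L, n_per_class))) {
    eAB <- stats::runif(1, -12, -6)
    bnd <- strong_barrier_boundary(1, -0.2, eAB)
    inside <- k %% 2L == 1L
    eabC <- if (inside) bnd - stats::runif(1, 2, 6)
            else bnd + stats::runif(1, 2, 6)
    ls <- scenario_landscape(1, -0.2, 0.1, eAB, eabC)
    f <- sprintf("cryptic_%s_%02d.yaml", if (inside) "inside" else "outside",
                 k)
    write_landscape(ls, file.path(dir, f))
    entries[[length(entries) + 1L]] <-
      list(file = f, class = "cryptic",
           origins = c("island", "continent", "both"),
           property = if (inside) "m_max > Lambda_max"
                      else "m_max <= Lambda_max")
  }
  manifest <- list(seed = seed, n_per_class = n_per_class,
                   fixtures = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analytic strong-barrier boundary in the cryptic-epistasis scenario
#'
#' The critical `eps_abC` below which the loose-linkage haploid barrier is
#' strong, from the closed-form condition of
#' [strong_barrier_condition()]; `NA` where no amount of background
#' epistasis suffices (`eps_AB` too weak).
#'
#' @inheritParams strong_barrier_condition
#' @return threshold value of `eps_abC`.
#' @export
strong_barrier_boundary <- function(alpha, beta, eps_AB) {
  if (beta < 0) {
    if (!(eps_AB < -4 * alpha + 3 * beta)) return(NA_real_)
    (-eps_AB * (3 * alpha - 4 * beta) + alpha * beta) /
      (eps_AB + 4 * alpha - 3 * beta)
  } else {
    if (!(eps_AB < -(4 * alpha + beta))) return(NA_real_)
    alpha * (beta - 3 * eps_AB) / (4 * alpha + beta + eps_AB)
  }
}

#' Numeric strong-barrier boundary
#'
#' Locates, by bisection on `eps_abC`, the point at which the numerically
#' computed barrier strength `m_max^{Ab|C}` crosses `Lambda_max^{Ab|C}`,
#' for haploid or diploid (codominant / recessive) loose-linkage dynamics.
#'
#' @inheritParams strong_barrier_condition
#' @param gamma_prime background-allele effect next to a derived partner.
#' @param ploidy,dominance passed to [scenario_landscape()].
#' @param mode linkage regime of the dynamics, `"loose"` or `"tight"`.
#' @param lower,upper bisection bracket for `eps_abC`.
#' @param tol bracket width at which to stop.
#' @inheritParams compute_mmax
#' @return the boundary `eps_abC`, or `NA` if `m_max - Lambda_max` has the
#'   same sign across the bracket.
#' @export
numeric_strong_barrier_boundary <- function(alpha, beta, eps_AB,
                                            gamma_prime = 0.1,
                                            ploidy = 1, dominance = NULL,
                                            mode = "loose",
                                            lower = -60, upper = -0.5,
                                            tol = 0.05, tol_m = 1e-3) {
  margin <- function(eabC) {
    ls <- scenario_landscape(alpha, beta, gamma_prime, eps_AB, eabC,
                             ploidy = ploidy, dominance = dominance)
    q <- barrier_query(ls, "Ab", "C")
    pp <- model_params(ls, 0, hap_string(ls, q$continental_hap),
                       mode = mode)
    lmax <- lambda_max(history_scenario(ls,
                                        c("island", "continent", "both")))
    compute_mmax(q, pp, tol_m = tol_m)$m_max - lmax
  }
  flo <- margin(lower); fup <- margin(upper)
  if (sign(flo) == sign(fup)) return(NA_real_)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    if (sign(margin(mid)) == sign(flo)) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}
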