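# Continuous-space Wright-Fisher simulation of dispersal and its effect on
# spatial FST: R-facing configuration, initialization from standing
# variation, generation stepping (C++ core), FST-trajectory tracking,
# dispersal calibration against a target maximum-distance FST, and the
# long-range-dispersal scenario study.

#' Gaussian interaction kernel parameters
#'
#' Kernel value is `max_strength * exp(-d^2 / (2 sigma^2))` for
#' `d <= max_distance`, else 0.
#'
#' @param max_distance,max_strength,sigma kernel parameters, all > 0.
#' @return list of class `kernel_params`.
#' @export
kernel_params <- function(max_distance, max_strength, sigma) {
  stopifnot(max_distance > 0, max_strength > 0, sigma > 0)
  structure(list(max_distance = max_distance, max_strength = max_strength,
                 sigma = sigma), class = "kernel_params")
}

#' Kernel strength at a distance
#' @param d distances (vectorized).
#' @param kernel a [kernel_params()].
#' @return kernel values (0 beyond `max_distance`).
#' @export
kernel_strength <- function(d, kernel) {
  ifelse(d <= kernel$max_distance,
         kernel$max_strength * exp(-d^2 / (2 * kernel$sigma^2)), 0)
}

#' Simulation configuration
#'
#' Defaults are the desk-scale stated world: N = 2000 on the unit square,
#' 20k sites on a 2e7-bp chromosome with mutation and recombination rates of
#' 2.5e-7 (1e-8 scaled x25), mate-choice kernel (0.1, 1.0, 0.02) and
#' competition kernel (0.3, 3.0, 0.1), base dispersal SD `sigma_disp`,
#' long-range SD `sigma_lr` = 0.20, 2000 burn-in generations and 120
#' long-range-dispersal generations.  The long-range exclusion radius is the
#' radial 99% quantile of the 2-D base kernel,
#' `r99 = sigma_disp * sqrt(2 ln 100)`.
#'
#' @param N population size.
#' @param sigma_disp base dispersal SD (habitat units).
#' @param p_lr long-range dispersal fraction during the LRD phase.
#' @param sigma_lr long-range dispersal SD (> sigma_disp).
#' @param n_sites number of simulated biallelic sites.
#' @param genome_length_bp chromosome length.
#' @param mu_per_site per-site per-gamete mutation (flip) probability.
#' @param r_per_bp per-bp recombination rate.
#' @param mate_kernel,comp_kernel [kernel_params()].
#' @param burnin_gens burn-in generations (p_lr forced to 0).
#' @param lrd_gens long-range-dispersal generations (default 120).
#' @param maf_min MAF filter applied to exported genotypes.
#' @param record_every trajectory recording interval (generations).
#' @param min_cell_n minimum individuals for a habitat grid cell.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(N = 2000, sigma_disp = 0.02, p_lr = 0,
                       sigma_lr = 0.20, n_sites = 20000,
                       genome_length_bp = 2e7, mu_per_site = 2.5e-7,
                       r_per_bp = 2.5e-7,
                       mate_kernel = kernel_params(0.1, 1.0, 0.02),
                       comp_kernel = kernel_params(0.3, 3.0, 0.1),
                       burnin_gens = 2000, lrd_gens = 120, maf_min = 0.01,
                       record_every = 10, min_cell_n = 2) {
  stopifnot(p_lr >= 0, p_lr <= 1, sigma_lr > sigma_disp,
            burnin_gens + lrd_gens > 0, N >= 2, n_sites >= 1)
  structure(list(
    N = N, sigma_disp = sigma_disp, p_lr = p_lr, sigma_lr = sigma_lr,
    r99 = sigma_disp * sqrt(2 * log(100)),
    n_sites = n_sites, genome_length_bp = genome_length_bp,
    mu_per_site = mu_per_site, r_per_bp = r_per_bp,
    mate_kernel = mate_kernel, comp_kernel = comp_kernel,
    burnin_gens = burnin_gens, lrd_gens = lrd_gens, maf_min = maf_min,
    record_every = record_every, min_cell_n = min_cell_n),
    class = "sim_config")
}

.sim_params_list <- function(config, p_lr) {
  list(mate_maxd = config$mate_kernel$max_distance,
       mate_sigma = config$mate_kernel$sigma,
       comp_maxd = config$comp_kernel$max_distance,
       comp_maxs = config$comp_kernel$max_strength,
       comp_sigma = config$comp_kernel$sigma,
       sigma_disp = config$sigma_disp, p_lr = p_lr,
       sigma_lr = config$sigma_lr, r99 = config$r99,
       genome_length_bp = config$genome_length_bp,
       mu_per_site = config$mu_per_site, r_per_bp = config$r_per_bp,
       site_bp = attr(config, "site_bp") %||%
         as.integer(round(seq_len(config$n_sites) *
                            (config$genome_length_bp /
                               (config$n_sites + 1)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert simulated generations to calendar years
#'
#' The 120 long-range-dispersal generations approximate the ~3000 years of
#' the historical period at a generation time of 25 years.
#'
#' @param generations number of generations.
#' @param generation_time_years years per generation (default 25).
#' @return years.
#' @export
generations_to_years <- function(generations, generation_time_years = 25) {
  generations * generation_time_years
}

#' Initialize a population from standing variation
#'
#' Positions are uniform on the unit square.  Per-site ancestral frequencies
#' are drawn from the neutral site-frequency spectrum (density proportional
#' to 1/x on [1/(2N), 1 - 1/(2N)]) and alleles are assigned independently
#' per haplotype, so generation 0 has no spatial structure; the burn-in then
#' establishes isolation by distance.  This standing-variation start plus
#' burn-in replaces a coalescent completion of deep history.
#'
#' @param config a [sim_config()].
#' @return list of class `population_state`: `generation`, `positions`
#'   (N x 2), `genomes` (raw, haplotype-major), `config`.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$N
  positions <- cbind(runif(N), runif(N))
  a <- 1 / (2 * N)
  u <- runif(config$n_sites)
  freqs <- a * ((1 - a) / a)^u          # inverse CDF of 1/x on [a, 1-a]
  genomes <- cpp_init_genomes(freqs, 2L * N)
  structure(list(generation = 0L, positions = positions, genomes = genomes,
                 config = config), class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("population_state: N = ", nrow(x$positions), ", ",
      x$config$n_sites, " sites, generation ", x$generation, "\n", sep = "")
  invisible(x)
}

#' Competition-scaled fitness
#'
#' `competition_i` is the kernel-weighted neighbour sum (self excluded);
#' fitness is `1.1 - competition / N`, floored at zero.  Mothers are sampled
#' proportionally to this fitness during reproduction.
#'
#' @param positions N x 2 coordinate matrix.
#' @param comp_kernel a [kernel_params()].
#' @param N population size used in the fitness scaling (default nrow).
#' @return numeric vector of fitness values.
#' @export
competition_fitness <- function(positions, comp_kernel,
                                N = nrow(positions)) {
  comp <- cpp_competition(positions, comp_kernel$max_distance,
                          comp_kernel$max_strength, comp_kernel$sigma)
  fit <- 1.1 - comp / N
  if (all(fit <= 0)) stop("all fitness zero: pathological configuration")
  pmax(fit, 0)
}

#' Sample a father by mate-choice kernel
#'
#' Candidates within `max_distance` of the mother (self excluded) are
#' sampled with probability proportional to the kernel strength at their
#' distance; returns NA when no candidate is in range (the mating attempt
#' fails and the caller redraws a mother).
#'
#' @param mother index of the mother in `positions`.
#' @param positions N x 2 coordinate matrix.
#' @param mate_kernel a [kernel_params()].
#' @return father index, or NA.
#' @export
mate_choice <- function(mother, positions, mate_kernel) {
  d <- sqrt((positions[, 1] - positions[mother, 1])^2 +
              (positions[, 2] - positions[mother, 2])^2)
  w <- kernel_strength(d, mate_kernel)
  w[mother] <- 0
  if (sum(w) == 0) return(NA_integer_)
  sample.int(nrow(positions), 1, prob = w)
}

#' Offspring dispersal
#'
#' With probability `1 - p_lr` an isotropic Gaussian displacement with SD
#' `sigma_disp`; with probability `p_lr` a Gaussian with SD `sigma_lr`,
#' rejection-sampled until the displacement exceeds `r99` so that long-range
#' dispersers genuinely leave the base kernel's 99% radius.  Positions are
#' reflected at the habitat boundaries.
#'
#' @param mother_pos matrix (n x 2) of maternal positions.
#' @param config a [sim_config()].
#' @param p_lr long-range fraction (default the config's).
#' @return n x 2 matrix of offspring positions.
#' @export
disperse <- function(mother_pos, config, p_lr = config$p_lr) {
  if (is.null(dim(mother_pos))) mother_pos <- matrix(mother_pos, ncol = 2)
  cpp_disperse(mother_pos, config$sigma_disp, p_lr, config$sigma_lr,
               config$r99)
}

#' Advance a population by one or more generations
#'
#' Non-overlapping Wright-Fisher step: N offspring are created with mothers
#' sampled by competition-scaled fitness and fathers by the mate-choice
#' kernel; haplotypes recombine with Poisson crossovers
#' (`r_per_bp * genome_length_bp` expected per meiosis, uniform positions)
#' and mutate by per-site flips; offspring are placed by [disperse()].
#'
#' @param state a `population_state`.
#' @param config a [sim_config()] (defaults to the state's).
#' @param n_gens number of generations (default 1).
#' @param p_lr long-range fraction for these generations.
#' @return updated `population_state`.
#' @export
step_generation <- function(state, config = state$config, n_gens = 1,
                            p_lr = config$p_lr) {
  res <- cpp_step_generations(state$positions, state$genomes,
                              config$n_sites,
                              .sim_params_list(config, p_lr), n_gens)
  state$positions <- res$positions
  state$genomes <- res$genomes
  state$generation <- state$generation + n_gens
  state
}

#' Spatial FST table on the habitat grid
#'
#' Splits the unit square into an `n_grid` x `n_grid` grid and computes
#' Hudson FST (with unequal sample-size correction, complete-data fast path)
#' and mean euclidean inter-individual distance between all pairs of
#' populated cells.
#'
#' @param state a `population_state`.
#' @param n_grid grid dimension (default 10).
#' @param min_cell_n minimum cell occupancy.
#' @param max_per_cell cap on individuals used for the mean-distance
#'   computation (distance only; FST uses everyone).
#' @return data.frame cellA, cellB, nA, nB, fst, dist.
#' @export
sim_grid_fst <- function(state, n_grid = 10,
                         min_cell_n = state$config$min_cell_n,
                         max_per_cell = 20) {
  pos <- state$positions
  cx <- pmin(floor(pos[, 1] * n_grid), n_grid - 1)
  cy <- pmin(floor(pos[, 2] * n_grid), n_grid - 1)
  cell <- cx * n_grid + cy + 1
  counts <- tabulate(cell, n_grid^2)
  pop <- which(counts >= min_cell_n)
  if (length(pop) < 2) stop("fewer than 2 populated habitat cells")
  cellmap <- match(cell, pop)          # NA for unpopulated cells
  keep <- !is.na(cellmap)
  L <- state$config$n_sites
  genomes <- state$genomes
  if (any(!keep)) {
    hap_keep <- rep(keep, each = 2 * L)
    genomes <- genomes[hap_keep]
  }
  der <- cpp_cell_counts(genomes, L, cellmap[keep], length(pop))
  freq <- sweep(der, 2, 2 * counts[pop], "/")
  hm <- .hudson_fst_matrix(freq, 2 * counts[pop])
  # per-cell member coordinates (subsampled for the distance average)
  members <- split(which(keep), cellmap[keep])
  xs <- lapply(members, function(ix) pos[ix[seq_len(min(length(ix),
                                                        max_per_cell))], 1])
  ys <- lapply(members, function(ix) pos[ix[seq_len(min(length(ix),
                                                        max_per_cell))], 2])
  np <- length(pop)
  ii <- rep(seq_len(np), times = seq_len(np) - 1)        # i > j pairs
  jj <- unlist(lapply(seq_len(np), function(i) seq_len(i - 1)),
               use.names = FALSE)
  dd <- vapply(seq_along(ii), function(k)
    .mean_cross_distance(xs[[ii[k]]], ys[[ii[k]]], xs[[jj[k]]],
                         ys[[jj[k]]], mode = "euclidean"), numeric(1))
  data.frame(cellA = pop[ii], cellB = pop[jj],
             nA = counts[pop[ii]], nB = counts[pop[jj]],
             fst = hm$fst[cbind(ii, jj)], dist = dd)
}

#' Maximum-distance FST summary
#'
#' The mean FST over cell pairs whose mean inter-individual distance is at
#' least `frac_of_max` of the largest observed pair distance — the
#' "FST at maximum distance" tracked by the calibration and the long-range
#' dispersal scenarios.
#'
#' @param fst_table output of [sim_grid_fst()].
#' @param frac_of_max distance threshold as a fraction of the maximum
#'   (default 0.8).
#' @return scalar FST.
#' @export
fst_max_distance <- function(fst_table, frac_of_max = 0.8) {
  thr <- frac_of_max * max(fst_table$dist)
  mean(fst_table$fst[fst_table$dist >= thr])
}

#' Run a full simulation: burn-in, long-range phase, trajectory, export
#'
#' Burn-in runs with `p_lr = 0`; the final `lrd_gens` generations use the
#' configured `p_lr`.  Every `record_every` generations (within the LRD
#' phase, plus sparser checkpoints during burn-in) the 10x10-grid FST table
#' is summarized into the trajectory.  Final genotypes are MAF-filtered and
#' exported as a [geno_matrix] with euclidean coordinates as metadata.
#'
#' @param config a [sim_config()].
#' @param state optionally, a pre-burned-in `population_state` to continue
#'   from (the burn-in is then skipped).
#' @param burnin_record_every recording interval during burn-in (default
#'   10 x `record_every`).
#' @return list of class `sim_result`: `trajectory` (data.frame generation,
#'   phase, fst_max, n_pairs), `geno` ([geno_matrix]), `meta` (data.frame
#'   id, x, y), `state` (final `population_state`).
#' @export
run_simulation <- function(config, state = NULL,
                           burnin_record_every = 10 * config$record_every) {
  if (is.null(state)) {
    state <- init_population(config)
    state <- .run_phase(state, config, config$burnin_gens, p_lr = 0,
                        record_every = burnin_record_every,
                        phase = "burnin")
  } else {
    state$config <- config
    attr(state, "trajectory") <- attr(state, "trajectory")
  }
  state <- .run_phase(state, config, config$lrd_gens, p_lr = config$p_lr,
                      record_every = config$record_every, phase = "lrd")
  traj <- attr(state, "trajectory")
  exported <- export_genotypes(state)
  structure(list(trajectory = traj, geno = exported$geno,
                 meta = exported$meta, state = state),
            class = "sim_result")
}

.run_phase <- function(state, config, n_gens, p_lr, record_every, phase) {
  traj <- attr(state, "trajectory")
  if (is.null(traj)) traj <- list()
  if (is.data.frame(traj)) traj <- list(traj)   # continuing a prior phase
  record <- function(st) {
    tab <- sim_grid_fst(st)
    traj[[length(traj) + 1]] <<- data.frame(
      generation = st$generation, phase = phase,
      fst_max = fst_max_distance(tab), mean_fst = mean(tab$fst),
      n_pairs = nrow(tab))
  }
  if (n_gens > 0) record(state)   # phase-start record (matched scenarios)
  done <- 0
  while (done < n_gens) {
    chunk <- min(record_every, n_gens - done)
    state <- step_generation(state, config, n_gens = chunk, p_lr = p_lr)
    done <- done + chunk
    record(state)
  }
  attr(state, "trajectory") <- do.call(rbind, traj)
  state
}

#' Export simulated genotypes as a genotype matrix
#'
#' @param state a `population_state`.
#' @param maf_min MAF filter (default from config).
#' @return list with `geno` ([geno_matrix], diploid) and `meta` (id, x, y
#'   euclidean coordinates, pseudo lon/lat for grid tooling).
#' @export
export_genotypes <- function(state, maf_min = state$config$maf_min) {
  cfg <- state$config
  dos <- cpp_dosages(state$genomes, cfg$n_sites)
  site_bp <- .sim_params_list(cfg, 0)$site_bp
  ids <- paste0("ind", seq_len(cfg$N))
  variants <- data.frame(id = paste0("s", seq_len(cfg$n_sites)),
                         chrom = "1", genpos = site_bp * 1e-8,
                         physpos = site_bp, ref = "A", alt = "C",
                         stringsAsFactors = FALSE)
  gm <- geno_matrix(dos, variants, ids, "diploid")
  gm <- apply_site_filters(gm, site_filter_spec(min_maf = maf_min))
  meta <- data.frame(id = ids, x = state$positions[, 1],
                     y = state$positions[, 2],
                     lon = state$positions[, 1], lat = state$positions[, 2],
                     region = "habitat", period = "Present-day",
                     stringsAsFactors = FALSE)
  list(geno = gm, meta = meta)
}

#' Calibrate dispersal against a target maximum-distance FST
#'
#' Grid search over population size N and base dispersal SD: each grid point
#' is burned in and its post-burn-in maximum-distance FST measured; the
#' returned configuration is the point closest to `target_fst_max`.
#'
#' @param target_fst_max target (default 0.03).
#' @param N_grid,sigma_grid search grids.
#' @param config template [sim_config()] supplying all other parameters
#'   (including the burn-in length and site count used for screening).
#' @param n_records post-burn-in records averaged into the achieved FST.
#' @return list of class `calibration`: `config` (calibrated, with the
#'   selected N and sigma_disp), `achieved`, `grid` (full table), `state`
#'   (the selected point's burned-in population, reusable for scenarios).
#' @export
calibrate_dispersal <- function(target_fst_max = 0.03,
                                N_grid = c(2000, 4000),
                                sigma_grid = c(0.03, 0.05, 0.08),
                                config = sim_config(burnin_gens = 500,
                                                    n_sites = 2000),
                                n_records = 3) {
  rows <- list(); states <- list()
  for (N in N_grid) for (sg in sigma_grid) {
    cfg <- config
    cfg$N <- N
    cfg$sigma_disp <- sg
    cfg$r99 <- sg * sqrt(2 * log(100))
    state <- init_population(cfg)
    state <- step_generation(state, cfg, n_gens = cfg$burnin_gens, p_lr = 0)
    vals <- numeric(n_records)
    for (r in seq_len(n_records)) {
      if (r > 1) state <- step_generation(state, cfg, n_gens = 10, p_lr = 0)
      vals[r] <- fst_max_distance(sim_grid_fst(state))
    }
    key <- paste(N, sg)
    states[[key]] <- state
    rows[[key]] <- data.frame(N = N, sigma_disp = sg,
                              fst_max = mean(vals))
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  err <- abs(grid$fst_max - target_fst_max)
  best <- which.min(err)
  if (err[best] > 0.5 * target_fst_max)
    stop("no grid point within 50% of target FST ", target_fst_max,
         " (closest achieved ", signif(grid$fst_max[best], 3),
         "); widen the N / sigma_disp grid")
  cfg <- config
  cfg$N <- grid$N[best]
  cfg$sigma_disp <- grid$sigma_disp[best]
  cfg$r99 <- cfg$sigma_disp * sqrt(2 * log(100))
  structure(list(config = cfg, achieved = grid$fst_max[best], grid = grid,
                 state = states[[paste(grid$N[best],
                                       grid$sigma_disp[best])]]),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("dispersal calibration: N = ", x$config$N, ", sigma_disp = ",
      x$config$sigma_disp, ", achieved max-distance FST = ",
      signif(x$achieved, 3), "\n", sep = "")
  invisible(x)
}

#' Long-range dispersal scenarios
#'
#' From a calibrated base configuration, runs the final `lrd_gens`
#' generations under each long-range fraction in `p_lr` (sharing the
#' burned-in starting state within a seed, so scenarios are matched), tracks
#' the maximum-distance FST trajectory, and reports its relative change plus
#' a Mann-Kendall trend test.  Optionally runs PCA on the final generation.
#'
#' @param config calibrated [sim_config()].
#' @param p_lr long-range fractions (default 0, 0.04, 0.08).
#' @param seeds integer seeds; one burn-in per seed.
#' @param state optional pre-burned-in state (single-seed use).
#' @param run_pca also compute [pca_simulated()] scores on each final
#'   generation (default FALSE; used for the structure-collapse figure).
#' @return list of class `lrd_scenarios`: `summary` (data.frame seed, p_lr,
#'   fst_start, fst_end, rel_change, mk_tau, mk_p), `trajectories`, and
#'   `pca` (when requested).
#' @export
run_lrd_scenarios <- function(config, p_lr = c(0, 0.04, 0.08),
                              seeds = 1:5, state = NULL, run_pca = FALSE) {
  rows <- list(); trajs <- list(); pcas <- list()
  for (sd_i in seq_along(seeds)) {
    seed <- seeds[sd_i]
    if (is.null(state)) {
      set.seed(seed)
      st0 <- init_population(config)
      st0 <- step_generation(st0, config, n_gens = config$burnin_gens,
                             p_lr = 0)
    } else st0 <- state
    for (pl in p_lr) {
      set.seed(seed * 1000L + round(pl * 100))
      cfg <- config
      cfg$p_lr <- pl
      st <- st0
      attr(st, "trajectory") <- NULL
      st <- .run_phase(st, cfg, cfg$lrd_gens, p_lr = pl,
                       record_every = cfg$record_every, phase = "lrd")
      traj <- attr(st, "trajectory")
      mk <- suppressWarnings(
        cor.test(traj$generation, traj$fst_max, method = "kendall"))
      key <- paste0("seed", seed, "_plr", pl)
      trajs[[key]] <- traj
      rows[[key]] <- data.frame(
        seed = seed, p_lr = pl,
        fst_start = traj$fst_max[1],
        fst_end = traj$fst_max[nrow(traj)],
        rel_change = traj$fst_max[nrow(traj)] / traj$fst_max[1] - 1,
        mk_tau = unname(mk$estimate), mk_p = mk$p.value)
      if (run_pca) {
        ex <- export_genotypes(st)
        pcas[[key]] <- list(scores = pca_simulated(ex$geno)$scores,
                            meta = ex$meta)
      }
    }
  }
  out <- list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
              trajectories = trajs)
  if (run_pca) out$pca <- pcas
  structure(out, class = "lrd_scenarios")
}
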