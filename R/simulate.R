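#' Configuration for the breeding-program simulator
#'
#' Defines a multi-cycle outcrossing breeding program descended from common
#' founders: heterozygous genets, truncation selection each generation,
#' Mendelian gamete sampling at unlinked biallelic markers, site-specific
#' genetic effects (G x E as a between-site genetic correlation on breeding
#' values), spatially autocorrelated plot error on a row/column grid, and
#' depth-dependent genotype degradation. Two named presets capture the
#' contrasting architectures of interest: `"domestication"` (few large QTL,
#' high cross-site genetic correlation) and `"agronomic"` (many small QTL,
#' low cross-site correlation).
#'
#' @param preset `"custom"`, `"domestication"` (10 QTL, `ge_correlation`
#'   0.9, `h2_target` 0.7) or `"agronomic"` (500 QTL, `ge_correlation` 0.3,
#'   `h2_target` 0.4). Explicit arguments override preset values.
#' @param n_founders founder genets, default 48.
#' @param n_markers biallelic SNP markers, default 2000.
#' @param n_qtl markers with causal effects (must be `<= n_markers`).
#' @param qtl_effect_dist `"few_large"` or `"many_small"`; sets `n_qtl`
#'   when that is not given (10 resp. 500).
#' @param h2_target single-site narrow-sense heritability the phenotype
#'   noise is scaled to.
#' @param n_cycles breeding cycles to advance, default 3.
#' @param genets_per_cycle evaluated genets per cycle, default 600.
#' @param selection_fraction fraction of a cycle selected as parents of the
#'   next, default 0.2.
#' @param mating `"random_intermating"` or `"open_pollination_halfsib"`.
#' @param ge_correlation genetic correlation of breeding values between
#'   sites, in (0, 1].
#' @param rho_row,rho_col spatial autocorrelations of the plot-error field.
#' @param spatial_variance_fraction share of the non-genetic variance that
#'   is spatially structured, default 0.2.
#' @param depth_mean mean GBS read depth (Poisson); 0 makes every call
#'   missing in [degrade_genotypes()].
#' @param missing_rate extra completely-at-random missing-call rate.
#' @param split_programs breed two divergent programs from cycle 2 onward.
#' @param trait_name trait label used in phenotype records.
#' @param seed integer seed; mandatory, every simulator draw derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(preset = c("custom", "domestication", "agronomic"),
                       n_founders = 48L, n_markers = 2000L, n_qtl = NULL,
                       qtl_effect_dist = NULL, h2_target = NULL,
                       n_cycles = 3L, genets_per_cycle = 600L,
                       selection_fraction = 0.2,
                       mating = c("random_intermating",
                                  "open_pollination_halfsib"),
                       ge_correlation = NULL, rho_row = 0.4, rho_col = 0.4,
                       spatial_variance_fraction = 0.2, depth_mean = 8,
                       missing_rate = 0, split_programs = FALSE,
                       trait_name = "sim_trait", seed) {
  preset <- match.arg(preset)
  mating <- match.arg(mating)
  if (missing(seed)) stop("`seed` is mandatory")
  defaults <- switch(preset,
    domestication = list(qtl_effect_dist = "few_large", n_qtl = 10L,
                         ge_correlation = 0.9, h2_target = 0.7),
    agronomic = list(qtl_effect_dist = "many_small", n_qtl = 500L,
                     ge_correlation = 0.3, h2_target = 0.4),
    custom = list(qtl_effect_dist = "many_small", n_qtl = 200L,
                  ge_correlation = 0.9, h2_target = 0.6))
  if (is.null(qtl_effect_dist)) qtl_effect_dist <- defaults$qtl_effect_dist
  qtl_effect_dist <- match.arg(qtl_effect_dist, c("few_large", "many_small"))
  if (is.null(n_qtl))
    n_qtl <- if (qtl_effect_dist == "few_large") 10L else
      min(defaults$n_qtl, n_markers %/% 2L)
  if (is.null(h2_target)) h2_target <- defaults$h2_target
  if (is.null(ge_correlation)) ge_correlation <- defaults$ge_correlation
  if (n_qtl > n_markers) stop("n_qtl must not exceed n_markers")
  for (fr in list(h2_target = h2_target, selection_fraction = selection_fraction,
                  ge_correlation = ge_correlation))
    if (fr <= 0 || fr > 1) stop("fractions must lie in (0, 1]")
  if (spatial_variance_fraction < 0 || spatial_variance_fraction > 1)
    stop("spatial_variance_fraction must lie in [0, 1]")
  if (abs(rho_row) >= 1 || abs(rho_col) >= 1) stop("|rho| must be < 1")
  structure(list(preset = preset, n_founders = as.integer(n_founders),
                 n_markers = as.integer(n_markers), n_qtl = as.integer(n_qtl),
                 qtl_effect_dist = qtl_effect_dist, h2_target = h2_target,
                 n_cycles = as.integer(n_cycles),
                 genets_per_cycle = as.integer(genets_per_cycle),
                 selection_fraction = selection_fraction, mating = mating,
                 ge_correlation = ge_correlation, rho_row = rho_row,
                 rho_col = rho_col,
                 spatial_variance_fraction = spatial_variance_fraction,
                 depth_mean = depth_mean, missing_rate = missing_rate,
                 split_programs = isTRUE(split_programs),
                 trait_name = trait_name, seed = as.integer(seed)),
            class = "sim_config")
}

sim_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

#' Simulate founder genets
#'
#' Founder haplotypes are drawn at Hardy-Weinberg equilibrium with
#' per-marker allele frequencies ~ Uniform(0.05, 0.95); markers are
#' unlinked.
#'
#' @param cfg a [sim_config()].
#' @return list with haplotype matrices `h1`, `h2` (genets x markers, 0/1),
#'   `ids`, and the founder allele frequencies `p`.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 0L))
  n <- cfg$n_founders; m <- cfg$n_markers
  p <- stats::runif(m, 0.05, 0.95)
  ids <- sprintf("F%04d", seq_len(n))
  mk <- sprintf("M%05d", seq_len(m))
  h1 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m,
               dimnames = list(ids, mk))
  h2 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m,
               dimnames = list(ids, mk))
  list(h1 = h1, h2 = h2, ids = ids, p = p)
}

## one gamete per parent row: free recombination across unlinked markers
sample_gametes <- function(h1, h2, rows) {
  m <- ncol(h1)
  pick <- matrix(stats::runif(length(rows) * m) < 0.5, length(rows), m)
  g <- h2[rows, , drop = FALSE]
  g[pick] <- h1[rows, , drop = FALSE][pick]
  g
}

#' Advance a breeding program over cycles
#'
#' Draws the trait architecture (QTL positions, common and site-specific
#' additive effects with the configured between-site genetic correlation),
#' then per cycle: phenotype-based truncation selection of the top
#' `selection_fraction`, mating per the configured scheme (each progeny
#' from two distinct selected parents via Mendelian gamete sampling;
#' half-sib mode fixes one maternal parent per family), producing
#' `genets_per_cycle` offspring. With `split_programs` the selected parents
#' of cycle 1 are divided into two programs that then breed independently.
#'
#' @param founders a [simulate_founders()] result.
#' @param cfg the same [sim_config()].
#' @return list of class `sim_population`: per-cycle haplotypes and ids,
#'   `effects` (markers x sites), `qtl_idx`, acyclic `pedigree`, and `meta`
#'   (genet, cycle, program).
#' @export
advance_cycles <- function(founders, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 1L))
  m <- cfg$n_markers
  n_sites <- cfg$n_cycles
  qtl_idx <- sort(sample.int(m, cfg$n_qtl))
  b0 <- stats::rnorm(cfg$n_qtl)
  rg <- cfg$ge_correlation
  beta <- matrix(0, m, n_sites,
                 dimnames = list(colnames(founders$h1),
                                 paste0("S", seq_len(n_sites))))
  for (s in seq_len(n_sites))
    beta[qtl_idx, s] <- sqrt(rg) * b0 + sqrt(1 - rg) * stats::rnorm(cfg$n_qtl)
  sel_eff <- numeric(m)
  sel_eff[qtl_idx] <- b0
  cycles <- vector("list", cfg$n_cycles)
  pedigree <- data.frame(genet_id = character(0), parent1 = character(0),
                         parent2 = character(0), cycle = character(0),
                         stringsAsFactors = FALSE)
  ## parents start as founders (one pool); programs may split after cycle 1
  pools <- list(P1 = founders)
  for (cyc in seq_len(cfg$n_cycles)) {
    offs <- lapply(names(pools), function(pn) {
      par <- pools[[pn]]
      n_par <- nrow(par$h1)
      n_off <- cfg$genets_per_cycle %/% length(pools)
      ids <- sprintf("C%d%s_%04d", cyc,
                     if (length(pools) > 1) paste0(pn) else "",
                     seq_len(n_off))
      if (cfg$mating == "random_intermating") {
        pr <- t(vapply(seq_len(n_off),
                       function(i) sample.int(n_par, 2L), integer(2)))
      } else {
        n_fam <- max(2L, ceiling(n_par / 2))
        dams <- rep_len(sample.int(n_par, n_fam), n_off)
        sires <- vapply(dams, function(d)
          sample(setdiff(seq_len(n_par), d), 1L), integer(1))
        pr <- cbind(dams, sires)
      }
      h1 <- sample_gametes(par$h1, par$h2, pr[, 1])
      h2 <- sample_gametes(par$h1, par$h2, pr[, 2])
      dimnames(h1) <- dimnames(h2) <- list(ids, colnames(par$h1))
      list(program = pn, ids = ids, h1 = h1, h2 = h2,
           ped = data.frame(genet_id = ids,
                            parent1 = par$ids[pr[, 1]],
                            parent2 = par$ids[pr[, 2]],
                            cycle = paste0("C", cyc),
                            stringsAsFactors = FALSE))
    })
    h1 <- do.call(rbind, lapply(offs, `[[`, "h1"))
    h2 <- do.call(rbind, lapply(offs, `[[`, "h2"))
    ids <- unlist(lapply(offs, `[[`, "ids"))
    program <- unlist(lapply(offs, function(o) rep(o$program, length(o$ids))))
    pedigree <- rbind(pedigree, do.call(rbind, lapply(offs, `[[`, "ped")))
    cycles[[cyc]] <- list(cycle = paste0("C", cyc), ids = ids, h1 = h1,
                          h2 = h2, program = program)
    ## select parents of the next cycle from this one
    if (cyc < cfg$n_cycles) {
      dos <- h1 + h2
      bv <- drop(dos %*% sel_eff)
      vb <- stats::var(bv)
      noise_sd <- if (vb > 0) sqrt(vb * (1 - cfg$h2_target) / cfg$h2_target)
                  else 1
      psel <- bv + stats::rnorm(length(bv), sd = noise_sd)
      by_prog <- split(seq_along(ids), program)
      sel_pools <- lapply(by_prog, function(idx) {
        n_sel <- max(2L, round(cfg$selection_fraction * length(idx)))
        keep <- idx[order(psel[idx], decreasing = TRUE)[seq_len(n_sel)]]
        list(h1 = h1[keep, , drop = FALSE], h2 = h2[keep, , drop = FALSE],
             ids = ids[keep])
      })
      if (cfg$split_programs && cyc == 1L) {
        sel <- sel_pools[[1]]
        n_sel <- length(sel$ids)
        if (n_sel < 4) stop("too few selected genets to split programs")
        half <- sample.int(n_sel, n_sel %/% 2)
        pools <- list(
          P1 = list(h1 = sel$h1[half, , drop = FALSE],
                    h2 = sel$h2[half, , drop = FALSE], ids = sel$ids[half]),
          P2 = list(h1 = sel$h1[-half, , drop = FALSE],
                    h2 = sel$h2[-half, , drop = FALSE], ids = sel$ids[-half]))
      } else {
        pools <- sel_pools
      }
      if (any(vapply(pools, function(p) length(p$ids), integer(1)) < 2))
        stop("selection_fraction leaves fewer than 2 parents")
    }
  }
  meta <- do.call(rbind, lapply(cycles, function(cc)
    data.frame(genet_id = cc$ids, cycle = cc$cycle, program = cc$program,
               stringsAsFactors = FALSE)))
  structure(list(cycles = cycles, effects = beta, qtl_idx = qtl_idx,
                 sel_effects = sel_eff, pedigree = pedigree, meta = meta,
                 founders = founders),
            class = "sim_population")
}

#' Simulate phenotypes on spatial field grids
#'
#' Each cycle is evaluated at its own site on a near-square row/column
#' grid. A genet's genetic value at site \eqn{s} is its dosage times the
#' site-\eqn{s} effect vector (cross-site genetic correlation
#' `ge_correlation`). Plot error is an AR1 x AR1 random field (variance
#' share `spatial_variance_fraction`) plus independent noise, scaled so the
#' realized single-site heritability matches `h2_target`.
#'
#' @param pop a [advance_cycles()] population.
#' @param cfg the same [sim_config()].
#' @return list: `records` (phenotype data.frame with `genet_id`, `cycle`,
#'   `program`, `site`, `year`, `row`, `col`, `trait`, `value`) and `truth`
#'   (class `sim_truth`: true breeding values per genet and site, QTL
#'   effects, realized per-cycle heritabilities and the spatial parameters
#'   used, plus the pedigree).
#' @export
simulate_phenotypes <- function(pop, cfg) {
  stopifnot(inherits(pop, "sim_population"), inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 2L))
  sites <- colnames(pop$effects)
  all_ids <- unlist(lapply(pop$cycles, `[[`, "ids"))
  dos_all <- do.call(rbind, lapply(pop$cycles, function(cc) cc$h1 + cc$h2))
  bv_all <- dos_all %*% pop$effects          # genets x sites
  rownames(bv_all) <- all_ids
  phi <- cfg$spatial_variance_fraction
  recs <- vector("list", length(pop$cycles))
  realized_h2 <- numeric(length(pop$cycles))
  for (ci in seq_along(pop$cycles)) {
    cc <- pop$cycles[[ci]]
    n <- length(cc$ids)
    site <- sites[ci]
    bv <- bv_all[cc$ids, ci]
    nr <- max(2L, floor(sqrt(n)))
    nc <- ceiling(n / nr)
    if (nr * nc < n) stop("grid smaller than the population")
    cells <- sample.int(nr * nc, n)          # random plot assignment
    prow <- ((cells - 1L) %% nr) + 1L
    pcol <- ((cells - 1L) %/% nr) + 1L
    vb <- stats::var(bv)
    s2e <- if (vb > 0) vb * (1 - cfg$h2_target) / cfg$h2_target else 1
    lr <- t(chol(build_ar1(nr, cfg$rho_row)))
    lc <- t(chol(build_ar1(nc, cfg$rho_col)))
    field <- lr %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% t(lc)
    err <- sqrt(phi * s2e) * field[cbind(prow, pcol)] +
      sqrt((1 - phi) * s2e) * stats::rnorm(n)
    y <- bv + err
    realized_h2[ci] <- vb / stats::var(y)
    recs[[ci]] <- data.frame(genet_id = cc$ids, cycle = cc$cycle,
                             program = cc$program, site = site, year = 1L,
                             row = prow, col = pcol, trait = cfg$trait_name,
                             value = y, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  truth <- structure(
    list(bv = bv_all, qtl_idx = pop$qtl_idx, effects = pop$effects,
         realized_h2 = stats::setNames(realized_h2,
                                       vapply(pop$cycles, `[[`,
                                              character(1), "cycle")),
         rho_row = cfg$rho_row, rho_col = cfg$rho_col,
         spatial_variance_fraction = phi, pedigree = pop$pedigree),
    class = "sim_truth")
  list(records = records, truth = truth)
}

#' True-dosage marker matrix of all cycle genets
#'
#' @param pop a [advance_cycles()] population.
#' @return an imputed-state [marker_matrix] of exact dosages.
#' @export
population_dosage <- function(pop) {
  stopifnot(inherits(pop, "sim_population"))
  dos <- do.call(rbind, lapply(pop$cycles, function(cc) cc$h1 + cc$h2))
  storage.mode(dos) <- "double"
  new_marker_matrix(dos, imputed = TRUE, meta = pop$meta)
}

#' Degrade clean genotypes into depth-limited GBS-like calls
#'
#' Per call, total read depth is Poisson(`depth_mean`) and reads sample the
#' genet's two alleles (alternate-allele reads ~ Binomial(depth,
#' dosage/2)). Calls with zero depth are missing; a heterozygote whose
#' reads happen to all come from one allele is miscalled homozygous —
#' exactly the error mode the depth-based call filters exist to catch.
#'
#' @param m a [marker_matrix] of true dosages (0/1/2, no missing).
#' @param cfg a [sim_config()] (uses `depth_mean`, `missing_rate`, `seed`).
#' @return a [genotype_calls()] object with `depth`, `ad_ref`, `ad_alt`.
#' @export
degrade_genotypes <- function(m, cfg) {
  stopifnot(inherits(m, "marker_matrix"), inherits(cfg, "sim_config"))
  set.seed(sim_seed(cfg, 3L))
  d <- m$dosage
  if (anyNA(d)) stop("true dosages must be complete")
  n <- nrow(d); mm <- ncol(d)
  depth <- matrix(stats::rpois(n * mm, cfg$depth_mean), n, mm,
                  dimnames = dimnames(d))
  alt <- matrix(stats::rbinom(n * mm, as.vector(depth), as.vector(d) / 2),
                n, mm, dimnames = dimnames(d))
  calls <- matrix(1L, n, mm, dimnames = dimnames(d))
  calls[alt == 0L] <- 0L
  calls[alt == depth] <- 2L
  calls[depth == 0L] <- NA_integer_
  if (cfg$missing_rate > 0) {
    drop_idx <- which(stats::runif(n * mm) < cfg$missing_rate)
    calls[drop_idx] <- NA_integer_
  }
  alleles <- data.frame(marker_id = colnames(d), ref = "A", alt = "C",
                        stringsAsFactors = FALSE)
  genotype_calls(calls, depth = depth, ad_ref = depth - alt, ad_alt = alt,
                 alleles = alleles, meta = m$meta)
}

#' Run the full simulator
#'
#' Founders, cycle advancement, phenotypes and (when `depth_mean > 0`)
#' degraded genotype calls, in one seeded call. Every number downstream of
#' a fixed config is bit-reproducible.
#'
#' @param cfg a [sim_config()].
#' @return list: `config`, `population`, `genotypes` (true-dosage
#'   [marker_matrix]), `calls` (degraded [genotype_calls()] or `NULL`),
#'   `phenotypes` (records data.frame), `truth` (`sim_truth`).
#' @export
simulate_breeding_program <- function(cfg) {
  founders <- simulate_founders(cfg)
  pop <- advance_cycles(founders, cfg)
  ph <- simulate_phenotypes(pop, cfg)
  geno <- population_dosage(pop)
  calls <- if (cfg$depth_mean > 0) degrade_genotypes(geno, cfg) else NULL
  list(config = cfg, population = pop, genotypes = geno, calls = calls,
       phenotypes = ph$records, truth = ph$truth)
}
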