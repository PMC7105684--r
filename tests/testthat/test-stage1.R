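test_that("AR1 matrix definition and closed-form inverse", {
  expect_equal(build_ar1(3, 0), diag(3))
  expect_equal(build_ar1(3, 0.5),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  expect_error(build_ar1(3, 1), "rho")
  expect_error(build_ar1(0, 0.5), "n")
  ## closed-form tridiagonal inverse at n = 50, rho = 0.9
  n <- 50; rho <- 0.9
  s <- build_ar1(n, rho)
  inv <- matrix(0, n, n)
  diag(inv) <- c(1, rep(1 + rho^2, n - 2), 1) / (1 - rho^2)
  inv[cbind(1:(n - 1), 2:n)] <- inv[cbind(2:n, 1:(n - 1))] <-
    -rho / (1 - rho^2)
  expect_lt(max(abs(solve(s) - inv)), 1e-8)
})

test_that("model assembly: design matrices, ordering, residual blocks", {
  k <- structure(diag(4), dimnames = list(paste0("g", 1:4), paste0("g", 1:4)),
                 class = c("grm", "matrix", "array"))
  ph <- data.frame(genet_id = paste0("g", 1:4), cycle = "C1", site = "S1",
                   year = 1L, row = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
                   trait = "t", value = rnorm(4))
  spec <- assemble_stage1(ph, k, "t", "C1")
  expect_equal(spec$X, matrix(1, 4, 1), ignore_attr = TRUE)
  expect_equal(dim(spec$Z), c(4L, 4L))
  expect_true(all(rowSums(spec$Z) == 1) && all(colSums(spec$Z) == 1))
  ## two sites -> fixed site effect and block-diagonal residual
  ph2 <- ph
  ph2$site <- c("S1", "S1", "S2", "S2")
  spec2 <- assemble_stage1(ph2, k, "t", "C1")
  expect_equal(ncol(spec2$X), 2L)
  expect_equal(length(spec2$site_blocks), 2L)
  ## Kronecker structure of one block vs a direct kron oracle
  ph3 <- expand.grid(row = 1:3, col = 1:2)
  ph3$genet_id <- paste0("g", 1:6)
  ph3$cycle <- "C1"; ph3$site <- "S1"; ph3$year <- 1L; ph3$trait <- "t"
  ph3$value <- rnorm(6)
  k6 <- structure(diag(6), dimnames = list(ph3$genet_id, ph3$genet_id),
                  class = c("grm", "matrix", "array"))
  spec3 <- assemble_stage1(ph3, k6, "t", "C1")
  b <- spec3$site_blocks[[1]]
  cs <- gsbreed:::site_ar1_corr(b, 0.5, 0)
  oracle <- kronecker(build_ar1(2, 0), build_ar1(3, 0.5))
  ## assembly orders plots column-major, matching the kron layout
  expect_equal(cs, oracle, ignore_attr = TRUE)
  ## validation errors
  ph_dup <- ph; ph_dup$row <- 1; ph_dup$col <- 1
  expect_error(assemble_stage1(ph_dup, k, "t", "C1"), "duplicate plot")
  ph_bad <- ph; ph_bad$genet_id[1] <- "unknown"
  expect_error(assemble_stage1(ph_bad, k, "t", "C1"), "missing from")
  ph_yr <- rbind(ph, transform(ph, year = 2L, row = row + 2))
  expect_error(assemble_stage1(ph_yr, k, "t", "C1"), "separate trait")
  ## replicated genets are carried by Z, not rejected
  ph_rep <- rbind(ph, transform(ph, row = row + 2))
  spec_rep <- assemble_stage1(ph_rep, k, "t", "C1")
  expect_equal(dim(spec_rep$Z), c(8L, 4L))
  expect_true(all(colSums(spec_rep$Z) == 2))
})

test_that("REML optimum matches a dense-grid search of the exact likelihood", {
  ## n = 25 toy, K = I, pure AR1 residual (no nugget)
  set.seed(5)
  n <- 25
  ph <- expand.grid(row = 1:5, col = 1:5)
  ph$genet_id <- sprintf("g%02d", 1:n)
  ph$cycle <- "C1"; ph$site <- "S1"; ph$year <- 1L; ph$trait <- "t"
  sp <- kronecker(t(chol(build_ar1(5, 0.6))), t(chol(build_ar1(5, 0.3))))
  ph$value <- rnorm(n, sd = 1.2) + drop(sp %*% rnorm(n))  # u + AR1 field
  k <- structure(diag(n), dimnames = list(ph$genet_id, ph$genet_id),
                 class = c("grm", "matrix", "array"))
  spec <- assemble_stage1(ph, k, "t", "C1")
  fit <- fit_reml(spec, stage1_control(nugget = FALSE))
  ## oracle: dense grid over (rho_r, rho_c, sigma2_a, sigma2_e)
  X <- matrix(1, n, 1)
  y <- spec$y
  zkz <- spec$Z %*% spec$K %*% t(spec$Z)
  b <- spec$site_blocks[[1]]
  best <- -Inf
  for (rr in seq(-0.8, 0.8, by = 0.1)) {
    for (rc in seq(-0.8, 0.8, by = 0.1)) {
      cs <- gsbreed:::site_ar1_corr(b, rr, rc)
      for (s2a in exp(seq(log(0.05), log(10), length.out = 25))) {
        for (s2e in exp(seq(log(0.05), log(10), length.out = 25))) {
          ll <- oracle_reml_ll(y, X, s2a * zkz + s2e * cs)
          if (ll > best) best <- ll
        }
      }
    }
  }
  ## exact likelihood at the fitted parameters
  cs_fit <- gsbreed:::site_ar1_corr(b, fit$sites$rho_row, fit$sites$rho_col)
  ll_fit <- oracle_reml_ll(y, X, fit$sigma2_a * zkz +
                             fit$sites$sigma2_e * cs_fit)
  expect_gte(ll_fit, best - 0.5)
  expect_equal(fit$loglik, ll_fit, tolerance = 1e-4)
})

test_that("null genetic variance is estimated near zero", {
  ## sigma2_A = 0: pure-noise phenotypes, two plots per genet so the
  ## genetic and residual components are identified; median ratio < 0.05
  set.seed(8)
  ratios <- replicate(5, {
    ph <- expand.grid(row = 1:10, col = 1:20)
    n <- nrow(ph)                              # 200 obs, 100 genets
    ph$genet_id <- sprintf("g%03d", rep(1:100, 2))
    ph$cycle <- "C1"; ph$site <- "S1"; ph$year <- 1L; ph$trait <- "t"
    ph$value <- rnorm(n)                       # pure iid noise, no signal
    ids <- sprintf("g%03d", 1:100)
    k <- structure(diag(100), dimnames = list(ids, ids),
                   class = c("grm", "matrix", "array"))
    fit <- fit_stage1(ph, k, "t", "C1",
                      control = stage1_control(nugget = FALSE))
    fit$sigma2_a / mean(fit$sites$sigma2_e)
  })
  expect_lt(median(ratios), 0.05)
})

test_that("with rho = 0 and K = I the fit matches an independent one-way REML", {
  set.seed(13)
  n_gen <- 40; reps <- 3
  ph <- data.frame(genet_id = rep(sprintf("g%02d", 1:n_gen), each = reps))
  ph$cycle <- "C1"; ph$site <- "S1"; ph$year <- 1L; ph$trait <- "t"
  ph$row <- rep(1:n_gen, each = reps)
  ph$col <- rep(1:reps, times = n_gen)
  u <- rnorm(n_gen, sd = sqrt(2))
  ph$value <- u[rep(1:n_gen, each = reps)] + rnorm(n_gen * reps)
  k <- structure(diag(n_gen),
                 dimnames = list(sprintf("g%02d", 1:n_gen),
                                 sprintf("g%02d", 1:n_gen)),
                 class = c("grm", "matrix", "array"))
  fit <- fit_stage1(ph, k, "t", "C1",
                    control = stage1_control(nugget = FALSE,
                                             fix_rho = c(0, 0)))
  lm4 <- lme4::lmer(value ~ 1 + (1 | genet_id), data = ph, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lm4))
  ratio_lme4 <- vc$vcov[1] / vc$vcov[2]
  ratio_fit <- fit$sigma2_a / fit$sites$sigma2_e
  expect_equal(ratio_fit, ratio_lme4, tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lm4)), tolerance = 1e-6)
})

test_that("estimates are invariant to observation order", {
  s <- small_sim(seed = 19, n = 64, m = 120)
  ph <- s$sim$phenotypes
  f1 <- fit_stage1(ph, s$k, "sim_trait", "C1")
  perm <- sample(nrow(ph))
  f2 <- fit_stage1(ph[perm, ], s$k, "sim_trait", "C1")
  expect_equal(f1$sigma2_a, f2$sigma2_a, tolerance = 1e-8)
  expect_equal(f1$sites$rho_row, f2$sites$rho_row, tolerance = 1e-8)
  expect_equal(f1$blups, f2$blups, tolerance = 1e-8)
})

test_that("BLUPs shrink toward zero as the variance ratio vanishes and sum to ~0", {
  set.seed(23)
  n <- 60
  ph <- data.frame(genet_id = sprintf("g%02d", 1:n), cycle = "C1",
                   site = "S1", year = 1L, row = rep(1:6, 10),
                   col = rep(1:10, each = 6), trait = "t",
                   value = rnorm(n))
  k <- structure(diag(n), dimnames = list(ph$genet_id, ph$genet_id),
                 class = c("grm", "matrix", "array"))
  fit <- fit_stage1(ph, k, "t", "C1",
                    control = stage1_control(nugget = FALSE,
                                             fix_rho = c(0, 0)))
  ## K = I, balanced single plot per genet: BLUPs centre on zero
  expect_lt(abs(sum(fit$blups)), 1e-6 * n * stats::sd(ph$value))
  ## shrinkage: scale of BLUPs bounded by the shrinkage factor
  lam <- fit$lambda
  expect_lt(max(abs(fit$blups)),
            (lam / (1 + lam)) * max(abs(ph$value - mean(ph$value))) + 1e-8)
})

test_that("the observation floor gates extraction, override lifts it", {
  s <- small_sim(seed = 29, n = 40, m = 80)
  fit <- fit_stage1(s$sim$phenotypes, s$k, "sim_trait", "C1")
  expect_warning(b0 <- extract_blups(fit), "ineligible")
  expect_equal(nrow(b0), 0L)
  expect_false(attr(b0, "eligible"))
  b1 <- extract_blups(fit, override = TRUE)
  expect_equal(nrow(b1), 40L)
  expect_setequal(names(b1)[5:7], c("blup", "value_adj", "value_raw"))
  ## unobserved genets are absent
  expect_setequal(b1$genet_id, unique(s$sim$phenotypes$genet_id))
})

test_that("spatial autocorrelation is recovered on a 20x20 grid", {
  ## one representative replicate per truth; the full 20-replicate sweep
  ## is exercised by the acceptance suite
  for (rho in c(0.2, 0.8)) {
    cfg <- sim_config(n_cycles = 1, genets_per_cycle = 400, n_markers = 400,
                      n_qtl = 150, h2_target = 0.3,
                      spatial_variance_fraction = 0.6,
                      rho_row = rho, rho_col = rho, depth_mean = 0,
                      seed = 1000 + round(100 * rho))
    sim <- simulate_breeding_program(cfg)
    k <- suppressMessages(compute_grm(sim$genotypes))
    fit <- fit_stage1(sim$phenotypes, k, "sim_trait", "C1")
    expect_lt(abs(fit$sites$rho_row - rho), 0.25)
    expect_lt(abs(fit$sites$rho_col - rho), 0.25)
  }
})
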