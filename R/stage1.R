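#' First-order autoregressive correlation matrix
#'
#' Entry \eqn{(i, j)} equals \eqn{\rho^{|i-j|}}: the separable building
#' block of the AR1 x AR1 spatial residual used for field grids. Symmetric,
#' unit diagonal and positive definite for \eqn{|\rho| < 1}.
#'
#' @param n dimension (number of rows or columns of the grid), `n >= 1`.
#' @param rho autocorrelation parameter, `|rho| < 1`.
#' @return an `n` x `n` correlation matrix.
#' @export
build_ar1 <- function(n, rho) {
  if (n < 1) stop("`n` must be >= 1")
  if (!is.finite(rho) || abs(rho) >= 1) stop("`rho` must lie in (-1, 1)")
  idx <- seq_len(n)
  rho^abs(outer(idx, idx, "-"))
}

## AR1 x AR1 correlation among the observed plots of one site, using the
## cached integer distance matrices of the block (gaps in the grid are
## handled by simply indexing the observed plots); rho^d goes through a
## power table instead of elementwise pow
site_ar1_corr <- function(b, rho_r, rho_c) {
  k <- length(b$idx)
  pr <- rho_r^(0:b$maxr)
  pc <- rho_c^(0:b$maxc)
  matrix(pr[b$dr + 1L], k, k) * matrix(pc[b$dc + 1L], k, k)
}

#' Stage-1 control parameters
#'
#' @param nugget include an independent (nugget) residual component next to
#'   the AR1 x AR1 spatial component, so the residual for site \eqn{s} is
#'   \eqn{\sigma^2_{e,s} [(1-\phi_s) I + \phi_s \Sigma_c(\rho_c) \otimes
#'   \Sigma_r(\rho_r)]} with spatial proportion \eqn{\phi_s}. With
#'   `nugget = FALSE` the residual is the pure separable AR1 x AR1 model
#'   (\eqn{\phi_s = 1}).
#' @param fix_rho optional length-2 numeric `c(rho_row, rho_col)` fixing the
#'   autocorrelations instead of estimating them (applies to every site).
#' @param fix_phi optional fixed spatial proportion in `[0, 1]`.
#' @param maxit maximum Nelder-Mead evaluations.
#' @param reltol relative convergence tolerance on the REML log-likelihood
#'   (Nelder-Mead `reltol`).
#' @param rho_max largest admissible `|rho|` during the search.
#' @return a list of class `stage1_control`.
#' @export
stage1_control <- function(nugget = TRUE, fix_rho = NULL, fix_phi = NULL,
                           maxit = 800L, reltol = 1e-8, rho_max = 0.98) {
  if (!is.null(fix_rho) && (length(fix_rho) != 2 || any(abs(fix_rho) >= 1)))
    stop("`fix_rho` must be c(rho_row, rho_col) with |rho| < 1")
  if (!is.null(fix_phi) && (fix_phi < 0 || fix_phi > 1))
    stop("`fix_phi` must lie in [0, 1]")
  structure(list(nugget = isTRUE(nugget), fix_rho = fix_rho,
                 fix_phi = fix_phi, maxit = as.integer(maxit),
                 reltol = reltol, rho_max = rho_max),
            class = "stage1_control")
}

#' Assemble the stage-1 mixed-model specification
#'
#' Builds \eqn{y = Xb + Zu + e} for one cycle and trait-year: `y` the
#' observed phenotypes, `X` an intercept plus a fixed site effect when the
#' cycle spans more than one site, `Z` the incidence of observations on
#' genets, and the per-site residual blocks ordered site-major and
#' column-major within site. `u ~ N(0, sigma2_A K)` uses the genomic
#' relationship matrix restricted to the observed genets.
#'
#' @param pheno data.frame with columns `genet_id`, `cycle`, `site`, `year`,
#'   `row`, `col`, `trait`, `value` (missing values allowed, dropped).
#' @param k a `grm` covering every observed genet.
#' @param trait,cycle labels selecting the records to fit.
#' @param year optional year; required when the cycle-trait has several.
#' @return a list of class `stage1_spec`.
#' @export
assemble_stage1 <- function(pheno, k, trait, cycle, year = NULL) {
  need <- c("genet_id", "cycle", "site", "year", "row", "col", "trait", "value")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) stop("phenotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  rec <- pheno[pheno$trait == trait & pheno$cycle == cycle & !is.na(pheno$value), ,
               drop = FALSE]
  if (!is.null(year)) rec <- rec[rec$year == year, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for trait '", trait, "', cycle '",
                           cycle, "'", if (!is.null(year)) paste0(", year ", year))
  yrs <- unique(rec$year)
  if (length(yrs) > 1)
    stop("multiple years present (", paste(yrs, collapse = ", "),
         "); each year is a separate trait - pass `year`")
  dup <- duplicated(rec[, c("site", "row", "col")])
  if (any(dup))
    stop("duplicate plot assignment at ",
         paste(utils::head(sprintf("%s(%d,%d)", rec$site[dup], rec$row[dup],
                                   rec$col[dup]), 3), collapse = ", "))
  kid <- genet_ids(k)
  absent <- setdiff(unique(rec$genet_id), kid)
  if (length(absent))
    stop("genets missing from the relationship matrix: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) ", ...")
  ## canonical observation order: site-major, column-major within site
  rec <- rec[order(rec$site, rec$col, rec$row), , drop = FALSE]
  gobs <- sort(unique(rec$genet_id))
  z <- matrix(0, nrow(rec), length(gobs),
              dimnames = list(NULL, gobs))
  z[cbind(seq_len(nrow(rec)), match(rec$genet_id, gobs))] <- 1
  sites <- unique(rec$site)
  if (length(sites) > 1) {
    x <- stats::model.matrix(~ factor(site, levels = sites), data = rec)
  } else {
    x <- matrix(1, nrow(rec), 1)
  }
  colnames(x)[1] <- "(Intercept)"
  if (qr(x)$rank < ncol(x)) stop("singular fixed-effect design matrix")
  site_blocks <- lapply(sites, function(s) {
    idx <- which(rec$site == s)
    rw <- rec$row[idx]; cl <- rec$col[idx]
    ## integer plot-distance matrices cached for fast AR1 powers
    dr <- abs(outer(rw, rw, "-")); storage.mode(dr) <- "integer"
    dc <- abs(outer(cl, cl, "-")); storage.mode(dc) <- "integer"
    list(site = s, idx = idx, row = rw, col = cl, dr = dr, dc = dc,
         maxr = max(dr), maxc = max(dc))
  })
  ksub <- unclass(k)[gobs, gobs, drop = FALSE]
  structure(list(y = rec$value, X = x, Z = z, K = ksub,
                 genet_ids = gobs, site_blocks = site_blocks,
                 records = rec, trait = trait, cycle = cycle,
                 year = yrs),
            class = "stage1_spec")
}

## ---- REML engine -----------------------------------------------------------

## parameter vector layout (free parameters only):
##   per site: z_rho_r, z_rho_c (atanh scale)  [unless fix_rho]
##   per site: z_phi (logit scale)             [if nugget and no fix_phi]
##   per site s >= 2: log tau_s (residual scale relative to site 1)
##   global: log lambda (sigma2_A / sigma2_e1)
## the overall scale sigma2_e1 is profiled out in closed form.
stage1_theta_map <- function(spec, control) {
  ns <- length(spec$site_blocks)
  map <- list(ns = ns, rho_free = is.null(control$fix_rho),
              phi_free = control$nugget && is.null(control$fix_phi))
  len <- 0L
  if (map$rho_free) { map$i_rho <- len + seq_len(2 * ns); len <- len + 2L * ns }
  if (map$phi_free) { map$i_phi <- len + seq_len(ns); len <- len + ns }
  if (ns > 1) { map$i_tau <- len + seq_len(ns - 1L); len <- len + ns - 1L }
  map$i_lambda <- len + 1L
  map$len <- len + 1L
  map
}

stage1_unpack <- function(theta, spec, control, map) {
  ns <- map$ns
  if (map$rho_free) {
    zr <- theta[map$i_rho]
    rho_r <- tanh(zr[seq_len(ns)])
    rho_c <- tanh(zr[ns + seq_len(ns)])
  } else {
    rho_r <- rep(control$fix_rho[1], ns)
    rho_c <- rep(control$fix_rho[2], ns)
  }
  if (control$nugget) {
    phi <- if (map$phi_free) stats::plogis(theta[map$i_phi])
           else rep(control$fix_phi, ns)
  } else phi <- rep(1, ns)
  tau <- c(1, if (ns > 1) exp(theta[map$i_tau]))
  lambda <- exp(theta[map$i_lambda])
  list(rho_r = rho_r, rho_c = rho_c, phi = phi, tau = tau, lambda = lambda)
}

## negative profiled REML log-likelihood; also returns the pieces needed
## for BLUP extraction when `full = TRUE`
stage1_nll <- function(theta, spec, control, map, zkz, full = FALSE) {
  pars <- stage1_unpack(theta, spec, control, map)
  if (any(abs(c(pars$rho_r, pars$rho_c)) > control$rho_max) ||
      !all(is.finite(c(pars$tau, pars$lambda))) ||
      pars$lambda > 1e10 || any(pars$tau > 1e8))
    return(if (full) NULL else 1e10)
  n <- length(spec$y); p <- ncol(spec$X)
  v0 <- pars$lambda * zkz
  one_site <- length(spec$site_blocks) == 1L
  for (s in seq_along(spec$site_blocks)) {
    b <- spec$site_blocks[[s]]
    cs <- site_ar1_corr(b, pars$rho_r[s], pars$rho_c[s])
    if (one_site) {
      v0 <- v0 + (pars$tau[s] * pars$phi[s]) * cs
      diag(v0) <- diag(v0) + pars$tau[s] * (1 - pars$phi[s])
    } else {
      rs <- (pars$tau[s] * pars$phi[s]) * cs
      diag(rs) <- diag(rs) + pars$tau[s] * (1 - pars$phi[s])
      v0[b$idx, b$idx] <- v0[b$idx, b$idx] + rs
    }
  }
  u <- tryCatch(chol(v0), error = function(e) NULL)
  if (is.null(u)) return(if (full) NULL else 1e10)
  ldet_v <- 2 * sum(log(diag(u)))
  w <- backsolve(u, cbind(spec$y, spec$X), transpose = TRUE)
  wy <- w[, 1]
  wx <- w[, -1, drop = FALSE]
  xtvx <- crossprod(wx)
  xtvy <- crossprod(wx, wy)
  cxx <- tryCatch(chol(xtvx), error = function(e) NULL)
  if (is.null(cxx)) return(if (full) NULL else 1e10)
  beta <- backsolve(cxx, backsolve(cxx, xtvy, transpose = TRUE))
  qform <- sum(wy^2) - sum(xtvy * beta)
  if (qform <= 0) return(if (full) NULL else 1e10)
  s2 <- qform / (n - p)
  ldet_xvx <- 2 * sum(log(diag(cxx)))
  ll <- -0.5 * ((n - p) * (log(2 * pi * s2) + 1) + ldet_v + ldet_xvx)
  if (!full) return(-ll)
  ## pieces for prediction: V0^-1 residual
  resid <- spec$y - spec$X %*% beta
  v0inv_r <- backsolve(u, backsolve(u, resid, transpose = TRUE))
  list(pars = pars, beta = drop(beta), sigma2_e1 = s2, loglik = ll,
       v0inv_r = drop(v0inv_r), resid = drop(resid))
}

#' Fit the stage-1 spatial genomic mixed model by REML
#'
#' Maximises the restricted likelihood of \eqn{y = Xb + Zu + e}, with
#' \eqn{u \sim N(0, \sigma^2_A K)} and a separable AR1(row) x AR1(col)
#' residual per site (optionally with an independent nugget component, see
#' [stage1_control()]). Autocorrelations, the spatial proportion, per-site
#' residual scales and the genetic-to-residual variance ratio are searched
#' by Nelder-Mead on transformed scales, initialised from the lag-1
#' autocorrelations of ordinary least-squares residuals; the overall
#' residual scale is profiled out in closed form. BLUPs are
#' \eqn{\hat u = \sigma^2_A K Z' V^{-1} (y - X\hat b)}.
#'
#' @param spec a [assemble_stage1()] model specification.
#' @param control a [stage1_control()].
#' @return an object of class `stage1_fit` with elements `blups`,
#'   `value_adj` (spatially detrended phenotypes per genet), `sigma2_a`,
#'   per-site residual table `sites` (`sigma2_e`, `rho_row`, `rho_col`,
#'   `spatial_prop`), `fixed_effects`, `loglik`, `converged`.
#' @export
fit_reml <- function(spec, control = stage1_control()) {
  stopifnot(inherits(spec, "stage1_spec"), inherits(control, "stage1_control"))
  map <- stage1_theta_map(spec, control)
  zkz <- spec$Z %*% spec$K %*% t(spec$Z)
  ## initial values from OLS residual autocorrelations
  ols <- stats::lm.fit(spec$X, spec$y)
  init <- numeric(map$len)
  if (map$rho_free) {
    ac <- vapply(spec$site_blocks, function(b) {
      r <- ols$residuals[b$idx]
      c(grid_lag1(r, b$row, b$col, along = "row"),
        grid_lag1(r, b$row, b$col, along = "col"))
    }, numeric(2))
    ac[!is.finite(ac)] <- 0
    ac <- pmax(pmin(ac, 0.9), -0.9)
    init[map$i_rho] <- atanh(c(ac[1, ], ac[2, ]))
  }
  if (map$phi_free) init[map$i_phi] <- stats::qlogis(0.5)
  init[map$i_lambda] <- 0
  nll <- function(th) stage1_nll(th, spec, control, map, zkz)
  if (map$len == 1L) {
    opt <- stats::optimize(function(z) nll(z), interval = c(-15, 15),
                           tol = 1e-9)
    theta <- opt$minimum
    conv <- TRUE
  } else {
    opt <- stats::optim(init, nll, method = "Nelder-Mead",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    theta <- opt$par
    conv <- opt$convergence == 0
  }
  fin <- stage1_nll(theta, spec, control, map, zkz, full = TRUE)
  if (is.null(fin)) stop("stage-1 REML failed at the returned optimum")
  pars <- fin$pars
  s2e1 <- fin$sigma2_e1
  sigma2_a <- pars$lambda * s2e1
  ## genetic and spatial BLUPs
  kzt <- spec$K %*% t(spec$Z)
  ublup <- drop(pars$lambda * kzt %*% fin$v0inv_r) * 1
  names(ublup) <- spec$genet_ids
  s_hat <- numeric(length(spec$y))
  for (s in seq_along(spec$site_blocks)) {
    b <- spec$site_blocks[[s]]
    cs <- site_ar1_corr(b, pars$rho_r[s], pars$rho_c[s])
    s_hat[b$idx] <- pars$tau[s] * pars$phi[s] *
      drop(cs %*% fin$v0inv_r[b$idx])
  }
  adj_obs <- fin$resid - s_hat
  adj <- drop(crossprod(spec$Z, adj_obs) / colSums(spec$Z))
  names(adj) <- spec$genet_ids
  raw <- drop(crossprod(spec$Z, fin$resid) / colSums(spec$Z))
  names(raw) <- spec$genet_ids
  nobs_g <- colSums(spec$Z)
  sites <- data.frame(
    site = vapply(spec$site_blocks, `[[`, character(1), "site"),
    n_obs = vapply(spec$site_blocks, function(b) length(b$idx), integer(1)),
    sigma2_e = pars$tau * s2e1,
    rho_row = pars$rho_r, rho_col = pars$rho_c,
    spatial_prop = pars$phi,
    stringsAsFactors = FALSE)
  fe <- fin$beta
  names(fe) <- colnames(spec$X)
  structure(list(trait = spec$trait, cycle = spec$cycle, year = spec$year,
                 blups = ublup, value_adj = adj, value_raw = raw,
                 n_obs_genet = nobs_g,
                 sigma2_a = max(sigma2_a, 0), sites = sites,
                 fixed_effects = fe, loglik = fin$loglik,
                 converged = conv, n_obs = length(spec$y),
                 lambda = pars$lambda, control = control),
            class = "stage1_fit")
}

## lag-1 autocorrelation of grid residuals along one axis
grid_lag1 <- function(r, row, col, along = c("row", "col")) {
  along <- match.arg(along)
  key <- if (along == "row") paste(col, row) else paste(row, col)
  nb <- if (along == "row") paste(col, row + 1) else paste(row, col + 1)
  j <- match(nb, key)
  ok <- !is.na(j)
  if (sum(ok) < 3) return(0)
  stats::cor(r[ok], r[j[ok]])
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf("stage-1 fit: trait '%s', cycle '%s', year %s; n = %d obs, %d genets\n",
              x$trait, x$cycle, paste(x$year, collapse = "/"),
              x$n_obs, length(x$blups)))
  cat(sprintf("  sigma2_A = %.4g; REML loglik = %.3f; converged: %s\n",
              x$sigma2_a, x$loglik, x$converged))
  print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Convenience wrapper: assemble and fit one cycle/trait-year
#'
#' @inheritParams assemble_stage1
#' @param control a [stage1_control()].
#' @return a `stage1_fit`.
#' @export
fit_stage1 <- function(pheno, k, trait, cycle, year = NULL,
                       control = stage1_control()) {
  fit_reml(assemble_stage1(pheno, k, trait, cycle, year), control)
}

#' Extract per-genet adjusted values from a stage-1 fit
#'
#' Returns one row per observed genet with the genomic BLUP (`blup`), the
#' spatially detrended phenotype (`value_adj` = phenotype minus fixed
#' effects minus the fitted spatial field, averaged over a genet's plots)
#' and the fixed-effect-adjusted raw phenotype (`value_raw`); `value_adj`
#' is the stage-2 prediction response, while variance-component estimation
#' downstream should use `value_raw`, which is free of BLUP shrinkage (see
#' the vignette). Cycle-trait combinations with fewer observations than `min_obs` are
#' ineligible for genomic selection and yield an empty table with a warning
#' unless `override = TRUE`.
#'
#' @param fit a `stage1_fit`.
#' @param min_obs minimum observations per cycle-trait (default 350).
#' @param override disable the observation floor.
#' @return data.frame `genet_id`, `trait`, `cycle`, `year`, `blup`,
#'   `value_adj`, `n_obs`.
#' @export
extract_blups <- function(fit, min_obs = 350L, override = FALSE) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (fit$n_obs < min_obs && !override) {
    warning(sprintf("cycle '%s' trait '%s': %d observations < floor %d; ineligible",
                    fit$cycle, fit$trait, fit$n_obs, min_obs))
    out <- data.frame(genet_id = character(0), trait = character(0),
                      cycle = character(0), year = integer(0),
                      blup = numeric(0), value_adj = numeric(0),
                      value_raw = numeric(0),
                      n_obs = integer(0), stringsAsFactors = FALSE)
    attr(out, "eligible") <- FALSE
    return(out)
  }
  out <- data.frame(genet_id = names(fit$blups), trait = fit$trait,
                    cycle = fit$cycle, year = fit$year[1],
                    blup = unname(fit$blups),
                    value_adj = unname(fit$value_adj),
                    value_raw = unname(fit$value_raw),
                    n_obs = unname(fit$n_obs_genet),
                    stringsAsFactors = FALSE)
  attr(out, "eligible") <- TRUE
  out
}
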