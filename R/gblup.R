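#' Fit a kinship-based GBLUP model
#'
#' Stage-2 genomic prediction: \eqn{y = \mu + g + e} on per-genet adjusted
#' phenotypes with \eqn{g \sim N(0, K \sigma^2_g)}. The single variance
#' ratio \eqn{\lambda = \sigma^2_g / \sigma^2_e} is estimated by REML
#' through an eigen-decomposition of the (intercept-projected) training
#' submatrix of `K` — the profile restricted likelihood is maximised in one
#' dimension, which is exact and deterministic for this two-component model.
#' GEBVs for every genet in `K` (phenotyped or not) follow as
#' \eqn{\hat g = \lambda K_{\cdot,t} (\lambda K_{t,t} + I)^{-1}
#' (y_t - \hat\mu)}.
#'
#' @param blups per-genet table from [extract_blups()] (or any data.frame
#'   with `genet_id` and the response column), or a named numeric vector.
#' @param k a `grm` covering at least the training genets.
#' @param training_ids genets to train on; default all phenotyped genets
#'   present in `k`. At least 2 required.
#' @param response which column of `blups` to use: `"value_adj"` (default;
#'   spatially detrended phenotypes — the prediction response), `"blup"`
#'   (stage-1 genomic BLUPs), or `"value_raw"` (fixed-effect-adjusted raw
#'   phenotypes — the response to use when the variance components /
#'   heritability are the quantity of interest, since it is free of the
#'   upward bias that stage-1 BLUP shrinkage induces in a second-stage
#'   variance-ratio fit; see the package vignette).
#' @return an object of class `gblup_fit`: `sigma2_g`, `sigma2_e`, `h2`,
#'   `mu`, `gebv` (named, all genets of `k`), `loglik`, `converged`,
#'   `training_ids`.
#' @export
fit_gblup <- function(blups, k, training_ids = NULL,
                      response = c("value_adj", "blup", "value_raw")) {
  if (is.data.frame(blups)) {
    response <- match.arg(response)
    if (!response %in% names(blups))
      response <- intersect(c("value_adj", "blup", "value_raw", "value"), names(blups))[1]
    if (is.na(response)) stop("no usable response column in `blups`")
    y_all <- blups[[response]]
    names(y_all) <- blups$genet_id
  } else {
    y_all <- blups
    if (is.null(names(y_all))) stop("a numeric response must carry genet names")
  }
  if (anyDuplicated(names(y_all))) {
    message("averaging multiple records per genet")
    y_all <- tapply(y_all, names(y_all), mean)
    y_all <- stats::setNames(as.numeric(y_all), names(y_all))
  }
  kid <- genet_ids(k)
  if (is.null(training_ids)) training_ids <- intersect(names(y_all), kid)
  training_ids <- as.character(training_ids)
  bad <- setdiff(training_ids, names(y_all))
  if (length(bad)) stop("training genets without phenotype: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(training_ids, kid)
  if (length(bad)) stop("training genets missing from K: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  nt <- length(training_ids)
  if (nt < 2) stop("at least 2 training genets are required")
  kv <- unclass(k)
  ktt <- kv[training_ids, training_ids, drop = FALSE]
  y <- y_all[training_ids]
  ## restricted (intercept-projected) eigen problem
  ctr <- diag(nt) - matrix(1 / nt, nt, nt)
  skS <- ctr %*% ktt %*% ctr
  ev <- eigen((skS + t(skS)) / 2, symmetric = TRUE)
  keep <- seq_len(nt - 1L)          # centring removes one dimension
  xi <- pmax(ev$values[keep], 0)
  eta <- drop(crossprod(ev$vectors[, keep, drop = FALSE], y - mean(y)))
  nr <- nt - 1L
  ## restricted likelihood of the error contrasts; the -log|X'X|/2 term
  ## (here X = 1, so -log(n)/2) puts it on the usual REML scale
  rll <- function(loglam) {
    lam <- exp(loglam)
    d <- lam * xi + 1
    ss <- sum(eta^2 / d)
    -0.5 * (nr * (log(2 * pi * ss / nr) + 1) + sum(log(d)) + log(nt))
  }
  opt <- stats::optimize(function(z) -rll(z), interval = c(-14, 14),
                         tol = 1e-10)
  lambda <- exp(opt$minimum)
  ## treat ratios pinned at the search boundary as effectively 0 / infinite
  if (opt$minimum <= -13.9) lambda <- 0
  d <- lambda * xi + 1
  sigma2_e <- sum(eta^2 / d) / nr
  sigma2_g <- lambda * sigma2_e
  loglik <- rll(log(max(lambda, 1e-300)))
  ## GLS intercept under the fitted V
  vtt <- lambda * ktt + diag(nt)
  ut <- tryCatch(chol(vtt), error = function(e) chol(vtt + diag(1e-8, nt)))
  w1 <- backsolve(ut, rep(1, nt), transpose = TRUE)
  wy <- backsolve(ut, y, transpose = TRUE)
  mu <- sum(w1 * wy) / sum(w1^2)
  rhs <- backsolve(ut, backsolve(ut, y - mu, transpose = TRUE))
  gebv <- drop(lambda * kv[, training_ids, drop = FALSE] %*% rhs)
  names(gebv) <- kid
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 h2 = if (sigma2_g + sigma2_e > 0)
                   sigma2_g / (sigma2_g + sigma2_e) else NA_real_,
                 mu = mu, lambda = lambda, gebv = gebv, loglik = loglik,
                 converged = TRUE, training_ids = training_ids,
                 response = if (is.data.frame(blups)) response else "vector"),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("GBLUP fit: %d training genets, %d predicted\n",
              length(x$training_ids), length(x$gebv)))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f, REML loglik = %.3f\n",
              x$sigma2_g, x$sigma2_e, x$h2, x$loglik))
  invisible(x)
}

#' Genomic heritability
#'
#' \eqn{h^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_e)} from the stage-2
#' variance components.
#'
#' @param sigma2_g additive genotypic variance (\eqn{\ge 0}).
#' @param sigma2_e residual variance (\eqn{\ge 0}); not both zero.
#' @return heritability in `[0, 1]`.
#' @export
genomic_heritability <- function(sigma2_g, sigma2_e) {
  if (sigma2_g < 0 || sigma2_e < 0) stop("variances must be non-negative")
  if (sigma2_g + sigma2_e == 0) stop("heritability undefined: both variances zero")
  sigma2_g / (sigma2_g + sigma2_e)
}

#' Predict GEBVs for a set of genets
#'
#' @param object a [fit_gblup()] fit.
#' @param ids genet identifiers; must all be present in the relationship
#'   matrix the model was fitted with.
#' @param ... unused.
#' @return data.frame `genet_id`, `gebv`.
#' @export
predict.gblup_fit <- function(object, ids = names(object$gebv), ...) {
  ids <- as.character(ids)
  bad <- setdiff(ids, names(object$gebv))
  if (length(bad)) stop("unknown genet(s): ",
                        paste(utils::head(bad, 5), collapse = ", "))
  data.frame(genet_id = ids, gebv = unname(object$gebv[ids]),
             stringsAsFactors = FALSE)
}
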