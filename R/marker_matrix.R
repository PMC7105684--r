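#' Convert calls to a dosage marker matrix
#'
#' Codes biallelic calls as alternate-allele dosage (hom ref = 0, het = 1,
#' hom alt = 2, missing = `NA`) and computes per-marker alternate allele
#' frequencies and call rates from the non-missing calls.
#'
#' @param calls a [genotype_calls()] object containing only biallelic
#'   markers (run [filter_markers()] first, or construct accordingly).
#' @return an object of class `marker_matrix` with elements `dosage`
#'   (genets x markers numeric matrix), `allele_freq`, `call_rate`,
#'   `imputed` flag and genet metadata.
#' @export
to_dosage <- function(calls) {
  stopifnot(inherits(calls, "genotype_calls"))
  multi <- calls$n_alleles != 2L
  if (any(multi))
    stop("non-biallelic markers present: ",
         paste(utils::head(colnames(calls$calls)[multi], 5), collapse = ", "),
         if (sum(multi) > 5) ", ...")
  d <- calls$calls
  storage.mode(d) <- "double"
  new_marker_matrix(d, imputed = FALSE, meta = calls$meta)
}

new_marker_matrix <- function(dosage, imputed, meta = NULL) {
  n_obs <- colSums(!is.na(dosage))
  p <- colSums(dosage, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  p[n_obs == 0] <- NA_real_
  structure(list(dosage = dosage,
                 allele_freq = p,
                 call_rate = n_obs / nrow(dosage),
                 imputed = isTRUE(imputed),
                 meta = meta),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$dosage), "genets x", ncol(x$dosage), "markers;",
      if (x$imputed) "imputed" else sprintf("%.1f%% missing", 100 * mean(is.na(x$dosage))),
      "\n")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$dosage)

#' @export
as.matrix.marker_matrix <- function(x, ...) x$dosage

#' Naive imputation of missing dosages
#'
#' Replaces missing entries either with the marker mean dosage \eqn{2p_k}
#' (continuous dosages allowed after imputation) or with a random draw from
#' Binomial(2, \eqn{p_k}), i.e. Hardy-Weinberg sampling at the observed
#' alternate allele frequency. A stand-in for haplotype-based imputation
#' that is adequate for relationship-matrix construction, where common
#' variants dominate.
#'
#' @param m a [to_dosage()] marker matrix.
#' @param method `"marker_mean"` (default) or `"random_hwe"`.
#' @param seed integer seed, required for `"random_hwe"`.
#' @return the marker matrix with no missing entries (`imputed = TRUE`).
#' @export
impute_naive <- function(m, method = c("marker_mean", "random_hwe"),
                         seed = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  method <- match.arg(method)
  if (anyNA(m$allele_freq))
    stop("markers with all calls missing (cannot estimate allele frequency): ",
         paste(utils::head(colnames(m$dosage)[is.na(m$allele_freq)], 5),
               collapse = ", "))
  d <- m$dosage
  miss <- is.na(d)
  if (any(miss)) {
    jmiss <- which(colSums(miss) > 0)
    if (method == "marker_mean") {
      for (j in jmiss) d[miss[, j], j] <- 2 * m$allele_freq[j]
    } else {
      if (is.null(seed)) stop("`seed` is required for random_hwe imputation")
      set.seed(as.integer(seed))
      for (j in jmiss) {
        k <- sum(miss[, j])
        d[miss[, j], j] <- stats::rbinom(k, 2L, m$allele_freq[j])
      }
    }
  }
  out <- new_marker_matrix(d, imputed = TRUE, meta = m$meta)
  attr(out, "impute_method") <- method
  out
}

#' Principal component analysis of the marker matrix
#'
#' PCA of the column-centred (optionally standardised) dosage matrix, on a
#' marker subset restricted by MAF and pre-imputation call rate — the usual
#' population-structure subset (defaults: MAF > 0.05, call rate > 0.50,
#' both strict).
#'
#' @param m an imputed [marker_matrix].
#' @param n_components number of components to return.
#' @param maf_subset minimum MAF (exclusive) for markers entering the PCA.
#' @param call_rate_subset minimum pre-imputation call rate (exclusive).
#' @param standardize divide centred columns by their standard deviation.
#' @return an object of class `gs_pca` with `scores` (genets x components),
#'   `var_explained` and `loadings`.
#' @export
pca_markers <- function(m, n_components = 10L, maf_subset = 0.05,
                        call_rate_subset = 0.5, standardize = FALSE) {
  stopifnot(inherits(m, "marker_matrix"))
  if (!m$imputed) stop("impute the marker matrix before PCA")
  maf <- pmin(m$allele_freq, 1 - m$allele_freq)
  keep <- maf > maf_subset & m$call_rate > call_rate_subset
  if (!any(keep)) stop("no markers pass the PCA subset thresholds")
  x <- m$dosage[, keep, drop = FALSE]
  x <- scale(x, center = TRUE, scale = standardize)
  x[is.nan(x)] <- 0
  rk <- min(dim(x)) - 1L  # centering removes one dimension
  if (n_components > rk) {
    warning("n_components exceeds matrix rank; truncated to ", rk)
    n_components <- rk
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  k <- seq_len(n_components)
  structure(list(scores = pc$x[, k, drop = FALSE],
                 var_explained = pc$sdev[k]^2 / tot,
                 loadings = pc$rotation[, k, drop = FALSE],
                 n_markers = sum(keep)),
            class = "gs_pca")
}

#' @export
print.gs_pca <- function(x, ...) {
  cat("marker PCA:", nrow(x$scores), "genets,", x$n_markers, "markers,",
      ncol(x$scores), "components\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$var_explained, 5)),
            collapse = ", "),
      if (length(x$var_explained) > 5) "..." else "", "\n")
  invisible(x)
}
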