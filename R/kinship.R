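#' Realized additive genomic relationship matrix
#'
#' VanRaden GRM: dosage columns are centred by twice the alternate allele
#' frequency, and \eqn{K = M_c M_c' / (2 \sum_k p_k (1 - p_k))}. The
#' proportionality constant \eqn{\theta = 1 / (2 \sum_k p_k(1-p_k))} is the
#' standard normalisation that puts the matrix on the unit-diagonal scale
#' (mean diagonal near \eqn{1 + f} for inbreeding coefficient \eqn{f}).
#' Allele frequencies are estimated from the current (filtered, imputed)
#' data set. Monomorphic markers carry no relationship information and are
#' excluded from both the cross-product and the normalising sum.
#'
#' @param m an imputed [marker_matrix] (no missing entries).
#' @return a `grm` object: a symmetric genet x genet numeric matrix with
#'   attributes `theta`, `n_markers_used`, `bend_applied`.
#' @export
compute_grm <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  d <- m$dosage
  if (anyNA(d)) stop("marker matrix contains missing entries; impute first")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; cannot compute a GRM")
  if (any(!poly))
    message(sum(!poly), " monomorphic marker(s) excluded from the GRM")
  dp <- d[, poly, drop = FALSE]
  pp <- p[poly]
  mc <- sweep(dp, 2L, 2 * pp, "-")
  denom <- 2 * sum(pp * (1 - pp))
  k <- tcrossprod(mc) / denom
  k <- (k + t(k)) / 2
  structure(k, theta = 1 / denom, n_markers_used = sum(poly),
            bend_applied = FALSE, bend = 0,
            class = c("grm", "matrix", "array"))
}

#' @export
print.grm <- function(x, ...) {
  v <- unclass(x)
  cat("grm:", nrow(v), "genets;", attr(x, "n_markers_used"), "markers;",
      sprintf("mean diag %.3f; mean offdiag %.3f", mean(diag(v)),
              mean(v[row(v) != col(v)])), "\n")
  if (isTRUE(attr(x, "bend_applied")))
    cat("  bent to PSD (", attr(x, "bend_strategy"), ", magnitude ",
        format(attr(x, "bend")), ")\n", sep = "")
  invisible(x)
}

#' Bend a relationship matrix to positive semi-definiteness
#'
#' REML machinery needs an (at least numerically) PSD covariance. If the
#' smallest eigenvalue is below `eps`, either a ridge
#' \eqn{(\epsilon - \lambda_{min}) I} is added (default) or eigenvalues are
#' floored at `eps` and the matrix reconstructed. Matrices already PSD
#' (smallest eigenvalue \eqn{\ge} `eps`) are returned unchanged.
#'
#' @param k a `grm` or plain symmetric matrix.
#' @param eps eigenvalue floor, default `1e-6`.
#' @param method `"ridge"` (default) or `"eigenfloor"`.
#' @return the (possibly bent) matrix, with attributes `bend_applied`,
#'   `bend` (magnitude) and `bend_strategy` recording what was done.
#' @export
bend_to_psd <- function(k, eps = 1e-6, method = c("ridge", "eigenfloor")) {
  method <- match.arg(method)
  v <- unclass(k)
  ev <- eigen(v, symmetric = TRUE)
  lmin <- min(ev$values)
  if (lmin >= eps) {
    attr(k, "bend_applied") <- FALSE
    attr(k, "bend") <- 0
    return(k)
  }
  if (method == "ridge") {
    mag <- eps - lmin
    out <- v + diag(mag, nrow(v))
  } else {
    vals <- pmax(ev$values, eps)
    out <- ev$vectors %*% (vals * t(ev$vectors))
    out <- (out + t(out)) / 2
    mag <- eps - lmin
  }
  dimnames(out) <- dimnames(v)
  for (a in c("theta", "n_markers_used"))
    attr(out, a) <- attr(k, a)
  structure(out, bend_applied = TRUE, bend = mag, bend_strategy = method,
            class = class(k))
}

#' Serialize / read back a relationship matrix
#'
#' Dense CSV with genet IDs as the first column and as the header, readable
#' back losslessly at full double precision.
#'
#' @param k a `grm` (or symmetric matrix with dimnames).
#' @param path output CSV path.
#' @return `path` invisibly (`write_grm`); a `grm` object (`read_grm`).
#' @export
write_grm <- function(k, path) {
  v <- unclass(k)
  df <- data.frame(genet_id = rownames(v),
                   format(v, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  colnames(v) <- colnames(df)[-1]
  structure(v, theta = NA_real_, n_markers_used = NA_integer_,
            bend_applied = FALSE, bend = 0,
            class = c("grm", "matrix", "array"))
}
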