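#' Genotype filtering thresholds
#'
#' Bundle of the call-level and marker/genet-level filtering thresholds used
#' by GBS SNP curation. Boundary semantics follow the rule phrasing they
#' implement: MAF must be strictly greater than `min_maf`, a genet is dropped
#' when its missingness strictly exceeds `max_genet_missing`, while the
#' marker call-rate threshold is inclusive (call rate \eqn{\ge}
#' `min_marker_call_rate` is retained).
#'
#' @param min_maf minimum minor allele frequency (exclusive), default 0.01.
#' @param min_marker_call_rate minimum fraction of genets with a non-missing
#'   call (inclusive), default 0.30.
#' @param biallelic_only drop markers with more than two alleles, default TRUE.
#' @param min_hom_depth minimum read depth to accept a homozygous call,
#'   default 4.
#' @param min_het_contrasting minimum reads of *each* allele to accept a
#'   heterozygous call, default 2.
#' @param max_genet_missing maximum fraction of missing calls a genet may
#'   have (exclusive), default 0.95.
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(min_maf = 0.01, min_marker_call_rate = 0.30,
                        biallelic_only = TRUE, min_hom_depth = 4L,
                        min_het_contrasting = 2L, max_genet_missing = 0.95) {
  for (fr in list(min_maf = min_maf, min_marker_call_rate = min_marker_call_rate,
                  max_genet_missing = max_genet_missing)) {
    if (!is.numeric(fr) || fr < 0 || fr > 1)
      stop("filter fractions must lie in [0, 1]")
  }
  if (min_hom_depth < 1 || min_het_contrasting < 1)
    stop("depth thresholds must be >= 1")
  structure(list(min_maf = min_maf,
                 min_marker_call_rate = min_marker_call_rate,
                 biallelic_only = isTRUE(biallelic_only),
                 min_hom_depth = as.integer(min_hom_depth),
                 min_het_contrasting = as.integer(min_het_contrasting),
                 max_genet_missing = max_genet_missing),
            class = "filter_spec")
}

#' Apply read-depth call rules
#'
#' Sets to missing (a) homozygous calls supported by fewer than
#' `spec$min_hom_depth` reads and (b) heterozygous calls with fewer than
#' `spec$min_het_contrasting` reads of either allele. All other calls are
#' unchanged.
#'
#' @param calls a [genotype_calls()] object with depth information.
#' @param spec a [filter_spec()].
#' @return the call set with low-evidence calls set to missing.
#' @export
apply_depth_rules <- function(calls, spec = filter_spec()) {
  stopifnot(inherits(calls, "genotype_calls"), inherits(spec, "filter_spec"))
  if (is.null(calls$depth) && is.null(calls$ad_ref))
    stop("read depth unavailable: skip the depth-rule stage for this input")
  cm <- calls$calls
  n_hom <- n_het <- 0L
  if (!is.null(calls$depth)) {
    hom <- !is.na(cm) & cm != 1L & !is.na(calls$depth) &
      calls$depth < spec$min_hom_depth
    n_hom <- sum(hom)
    cm[hom] <- NA_integer_
  }
  if (!is.null(calls$ad_ref) && !is.null(calls$ad_alt)) {
    het <- !is.na(cm) & cm == 1L & !is.na(calls$ad_ref) & !is.na(calls$ad_alt) &
      (calls$ad_ref < spec$min_het_contrasting |
         calls$ad_alt < spec$min_het_contrasting)
    n_het <- sum(het)
    cm[het] <- NA_integer_
  } else {
    warning("per-allele depths unavailable; heterozygote contrasting-tag rule skipped")
  }
  out <- calls
  out$calls <- cm
  attr(out, "depth_rule_report") <- list(hom_set_missing = n_hom,
                                         het_set_missing = n_het)
  out
}

marker_stats <- function(calls) {
  cm <- calls$calls
  n_obs <- colSums(!is.na(cm))
  call_rate <- n_obs / nrow(cm)
  p <- colSums(cm, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  p[n_obs == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  data.frame(marker_id = colnames(cm), call_rate = call_rate,
             alt_freq = p, maf = maf, n_alleles = calls$n_alleles,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter markers by allele count, MAF and call rate
#'
#' Retains biallelic markers with minor allele frequency strictly above
#' `spec$min_maf` (computed from non-missing calls) and call rate at least
#' `spec$min_marker_call_rate`. A retention report (counts failing each
#' criterion) is attached as attribute `"filter_report"`.
#'
#' @param calls a [genotype_calls()] object.
#' @param spec a [filter_spec()].
#' @return the filtered call set.
#' @export
filter_markers <- function(calls, spec = filter_spec()) {
  stopifnot(inherits(calls, "genotype_calls"), inherits(spec, "filter_spec"))
  st <- marker_stats(calls)
  ok_bi <- if (spec$biallelic_only) st$n_alleles == 2L else rep(TRUE, nrow(st))
  ok_maf <- !is.na(st$maf) & st$maf > spec$min_maf
  ok_cr <- st$call_rate >= spec$min_marker_call_rate
  keep <- ok_bi & ok_maf & ok_cr
  if (!any(keep))
    warning("all markers removed by filtering")
  out <- subset_calls(calls, markers = which(keep))
  attr(out, "filter_report") <- list(
    n_in = nrow(st), n_kept = sum(keep),
    fail_biallelic = sum(!ok_bi), fail_maf = sum(!ok_maf),
    fail_call_rate = sum(!ok_cr))
  out
}

#' Filter genets by missing-call fraction
#'
#' Removes genets whose fraction of missing marker calls strictly exceeds
#' `spec$max_genet_missing`. Removed IDs are reported in attribute
#' `"filter_report"`.
#'
#' @param calls a [genotype_calls()] object.
#' @param spec a [filter_spec()].
#' @return the filtered call set.
#' @export
filter_genets <- function(calls, spec = filter_spec()) {
  stopifnot(inherits(calls, "genotype_calls"), inherits(spec, "filter_spec"))
  miss <- rowMeans(is.na(calls$calls))
  keep <- miss <= spec$max_genet_missing
  out <- subset_calls(calls, genets = which(keep))
  attr(out, "filter_report") <- list(
    n_in = length(miss), n_kept = sum(keep),
    removed_ids = rownames(calls$calls)[!keep])
  out
}

#' Run the full genotype filtering pipeline
#'
#' Fixed stage order: depth rules (skipped with a warning when the input has
#' no depth evidence) \eqn{\to} marker filters \eqn{\to} genet filter
#' \eqn{\to} one final marker-filter pass with statistics recomputed on the
#' retained genets. The combined per-stage report is attached as attribute
#' `"filter_report"`.
#'
#' @param calls a [genotype_calls()] object.
#' @param spec a [filter_spec()].
#' @return the filtered call set with a stage-by-stage retention report.
#' @export
apply_filters <- function(calls, spec = filter_spec()) {
  report <- list()
  if (!is.null(calls$depth) || !is.null(calls$ad_ref)) {
    calls <- apply_depth_rules(calls, spec)
    report$depth_rules <- attr(calls, "depth_rule_report")
  } else {
    warning("no depth information: depth rules skipped")
    report$depth_rules <- "skipped (no depth)"
  }
  calls <- filter_markers(calls, spec)
  report$markers <- attr(calls, "filter_report")
  calls <- filter_genets(calls, spec)
  report$genets <- attr(calls, "filter_report")
  calls <- filter_markers(calls, spec)
  report$markers_recheck <- attr(calls, "filter_report")
  attr(calls, "filter_report") <- report
  calls
}
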