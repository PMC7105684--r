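#' Genotype call set
#'
#' Container for raw per-genet, per-marker genotype calls together with the
#' read-depth evidence needed by the depth-based call filters. Calls are
#' coded as the count of the alternate allele: `0` = homozygous reference,
#' `1` = heterozygous, `2` = homozygous alternate, `NA` = missing. Rows are
#' genets, columns are markers.
#'
#' @param calls integer matrix (genets x markers) with values in
#'   `{0, 1, 2, NA}`; must carry unique row and column names.
#' @param depth optional non-negative integer matrix of total read depth per
#'   call, same shape as `calls`.
#' @param ad_ref,ad_alt optional matrices of per-allele read counts
#'   (reference / alternate tags supporting the call).
#' @param alleles optional data.frame with columns `marker_id`, `ref`, `alt`.
#' @param n_alleles optional integer vector giving the number of observed
#'   alleles per marker (used to flag non-biallelic sites); defaults to 2.
#' @param meta optional data.frame with column `genet_id` plus any of
#'   `cycle`, `program`.
#' @return An object of class `genotype_calls`.
#' @export
genotype_calls <- function(calls, depth = NULL, ad_ref = NULL, ad_alt = NULL,
                           alleles = NULL, n_alleles = NULL, meta = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  gid <- rownames(calls)
  mid <- colnames(calls)
  if (nrow(calls) == 0 && is.null(gid)) gid <- rownames(calls) <- character(0)
  if (ncol(calls) == 0 && is.null(mid)) mid <- colnames(calls) <- character(0)
  if (is.null(gid) || is.null(mid))
    stop("`calls` must have genet row names and marker column names")
  if (anyDuplicated(gid))
    stop("duplicate genet IDs: ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(mid))
    stop("duplicate marker IDs: ", paste(unique(mid[duplicated(mid)]), collapse = ", "))
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("calls must be coded 0 (hom ref), 1 (het), 2 (hom alt) or NA")
  for (nm in c("depth", "ad_ref", "ad_alt")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (!identical(dim(m), dim(calls)))
        stop("`", nm, "` must have the same dimensions as `calls`")
      if (any(m[!is.na(m)] < 0)) stop("`", nm, "` must be non-negative")
    }
  }
  if (is.null(n_alleles)) n_alleles <- rep(2L, ncol(calls))
  if (length(n_alleles) != ncol(calls))
    stop("`n_alleles` must have one entry per marker")
  if (is.null(alleles))
    alleles <- data.frame(marker_id = mid, ref = NA_character_,
                          alt = NA_character_, stringsAsFactors = FALSE)
  if (is.null(meta))
    meta <- data.frame(genet_id = gid, cycle = NA_character_,
                       program = NA_character_, stringsAsFactors = FALSE)
  if (!"genet_id" %in% names(meta)) stop("`meta` needs a genet_id column")
  meta <- meta[match(gid, meta$genet_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(
    list(calls = calls, depth = depth, ad_ref = ad_ref, ad_alt = ad_alt,
         alleles = alleles, n_alleles = as.integer(n_alleles), meta = meta),
    class = "genotype_calls")
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat("genotype_calls:", nrow(x$calls), "genets x", ncol(x$calls), "markers\n")
  cat(sprintf("  missing calls: %.1f%%; depth %s; allele depths %s\n",
              100 * mean(is.na(x$calls)),
              if (is.null(x$depth)) "unavailable" else "available",
              if (is.null(x$ad_ref)) "unavailable" else "available"))
  nb <- sum(x$n_alleles != 2L)
  if (nb > 0) cat("  non-biallelic markers flagged:", nb, "\n")
  invisible(x)
}

#' @export
dim.genotype_calls <- function(x) dim(x$calls)

#' Genet identifiers of an object
#' @param x a `genotype_calls`, `marker_matrix` or `grm` object.
#' @return character vector of genet IDs.
#' @export
genet_ids <- function(x) UseMethod("genet_ids")
#' @export
genet_ids.genotype_calls <- function(x) rownames(x$calls)
#' @export
genet_ids.marker_matrix <- function(x) rownames(x$dosage)
#' @export
genet_ids.grm <- function(x) rownames(unclass(x))

#' Marker identifiers of an object
#' @param x a `genotype_calls` or `marker_matrix` object.
#' @return character vector of marker IDs.
#' @export
marker_ids <- function(x) UseMethod("marker_ids")
#' @export
marker_ids.genotype_calls <- function(x) colnames(x$calls)
#' @export
marker_ids.marker_matrix <- function(x) colnames(x$dosage)

## subset a call set, keeping all per-call evidence matrices aligned
subset_calls <- function(x, genets = NULL, markers = NULL) {
  gi <- if (is.null(genets)) seq_len(nrow(x$calls)) else genets
  mi <- if (is.null(markers)) seq_len(ncol(x$calls)) else markers
  sub <- function(m) if (is.null(m)) NULL else m[gi, mi, drop = FALSE]
  midx <- seq_len(ncol(x$calls))[mi]
  gidx <- seq_len(nrow(x$calls))[gi]
  genotype_calls(
    calls = x$calls[gi, mi, drop = FALSE],
    depth = sub(x$depth), ad_ref = sub(x$ad_ref), ad_alt = sub(x$ad_alt),
    alleles = x$alleles[midx, , drop = FALSE],
    n_alleles = x$n_alleles[midx],
    meta = x$meta[gidx, , drop = FALSE])
}

#' Read genotype data into a call set
#'
#' Reads biallelic SNP genotypes from a VCF (via \pkg{vcfR}), a HapMap-style
#' diploid table, or a generic CSV table of `{0,1,2,NA}` dosages, into a
#' [genotype_calls()] object. Sites with more than one alternate allele are
#' retained but flagged non-biallelic so the marker filter can drop them.
#'
#' @param path path to the genotype file.
#' @param format one of `"vcf"`, `"hapmap"`, `"tabular"`.
#' @param meta optional genet metadata data.frame (`genet_id`, `cycle`,
#'   `program`).
#' @return a [genotype_calls()] object; read depths are populated when the
#'   source provides them (VCF `DP`/`AD`), otherwise left unavailable.
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap", "tabular"),
                           meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         vcf = read_genotypes_vcf(path, meta),
         hapmap = read_genotypes_hapmap(path, meta),
         tabular = read_genotypes_tabular(path, meta))
}

read_genotypes_vcf <- function(path, meta = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  mid <- fix[, "ID"]
  noid <- is.na(mid) | mid == "."
  mid[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  alt <- fix[, "ALT"]
  n_alleles <- 1L + vapply(strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE),
                           length, integer(1))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  rownames(gt) <- mid
  code_gt <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- apply(gt, 2, code_gt)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt), dimnames = dimnames(gt))
  rownames(calls) <- mid
  calls <- t(calls)  # genets x markers
  depth <- ad_ref <- ad_alt <- NULL
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("AD" %in% fmt_keys) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    spl <- strsplit(ifelse(is.na(ad), ",", ad), ",", fixed = TRUE)
    ref_ct <- vapply(spl, function(v) suppressWarnings(as.integer(v[1])), integer(1))
    alt_ct <- vapply(spl, function(v)
      if (length(v) >= 2) suppressWarnings(as.integer(v[2])) else NA_integer_, integer(1))
    ad_ref <- t(matrix(ref_ct, nrow = nrow(ad), dimnames = dimnames(ad)))
    ad_alt <- t(matrix(alt_ct, nrow = nrow(ad), dimnames = dimnames(ad)))
    colnames(ad_ref) <- colnames(ad_alt) <- mid
    depth <- ad_ref + ad_alt
  }
  if (is.null(depth) && "DP" %in% fmt_keys) {
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    depth <- t(dp)
    colnames(depth) <- mid
  }
  alleles <- data.frame(marker_id = mid, ref = fix[, "REF"],
                        alt = vapply(strsplit(ifelse(is.na(alt), "", alt), ","),
                                     `[`, character(1), 1),
                        stringsAsFactors = FALSE)
  genotype_calls(calls, depth = depth, ad_ref = ad_ref, ad_alt = ad_alt,
                 alleles = alleles, n_alleles = n_alleles, meta = meta)
}

## IUPAC ambiguity codes for heterozygous single-letter HapMap genotypes
.iupac <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

read_genotypes_hapmap <- function(path, meta = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  std <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#", "center",
           "protLSID", "assayLSID", "panelLSID", "QCcode")
  ngt <- max(which(names(tab) %in% std | seq_along(tab) <= 11))
  if (!all(c("rs#", "alleles") %in% names(tab)[1:2]))
    stop("malformed HapMap table: expected 'rs#' and 'alleles' in the first columns")
  mid <- as.character(tab[["rs#"]])
  al <- strsplit(as.character(tab[["alleles"]]), "/", fixed = TRUE)
  ref <- vapply(al, `[`, character(1), 1)
  alt <- vapply(al, function(v) if (length(v) >= 2) v[2] else NA_character_, character(1))
  n_alleles <- vapply(al, length, integer(1))
  gcols <- names(tab)[(ngt + 1):ncol(tab)]
  n <- length(gcols)
  m <- nrow(tab)
  calls <- matrix(NA_integer_, n, m, dimnames = list(gcols, mid))
  for (j in seq_len(m)) {
    g <- toupper(as.character(unlist(tab[j, gcols])))
    rj <- ref[j]; aj <- alt[j]
    two <- nchar(g) == 2
    g[two & g == paste0(rj, rj)] <- "RR"
    g[two & g == paste0(aj, aj)] <- "AA"
    g[two & g %in% c(paste0(rj, aj), paste0(aj, rj))] <- "RA"
    het1 <- names(.iupac)[match(paste0(rj, aj), .iupac)]
    g[!two & g == rj] <- "RR"
    g[!two & g == aj] <- "AA"
    if (!is.na(het1) && length(het1)) g[!two & g == het1] <- "RA"
    out <- rep(NA_integer_, n)
    out[g == "RR"] <- 0L
    out[g == "RA"] <- 1L
    out[g == "AA"] <- 2L
    calls[, j] <- out
  }
  alleles <- data.frame(marker_id = mid, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  genotype_calls(calls, alleles = alleles, n_alleles = n_alleles, meta = meta)
}

read_genotypes_tabular <- function(path, meta = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  gid <- as.character(tab[[1]])
  if (anyDuplicated(gid))
    stop("duplicate genet IDs in ", path, ": ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- gid
  genotype_calls(mat, meta = meta)
}

#' Write a call set as a plain-text VCF
#'
#' Emits a minimal VCF v4.2 with `GT`, and `DP`/`AD` when depth evidence is
#' present. Intended for exporting simulated genotypes in a standard format;
#' the output reads back identically with [read_genotypes()].
#'
#' @param x a [genotype_calls()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(x, path) {
  n <- nrow(x$calls); m <- ncol(x$calls)
  has_ad <- !is.null(x$ad_ref) && !is.null(x$ad_alt)
  has_dp <- !is.null(x$depth)
  fmt <- paste(c("GT", if (has_ad) "AD", if (has_dp) "DP"), collapse = ":")
  gt_str <- matrix("./.", n, m)
  gt_str[!is.na(x$calls) & x$calls == 0L] <- "0/0"
  gt_str[!is.na(x$calls) & x$calls == 1L] <- "0/1"
  gt_str[!is.na(x$calls) & x$calls == 2L] <- "1/1"
  if (has_ad)
    gt_str <- matrix(paste(gt_str, paste(x$ad_ref, x$ad_alt, sep = ","), sep = ":"),
                     n, m)
  if (has_dp)
    gt_str <- matrix(paste(gt_str, as.integer(x$depth), sep = ":"), n, m)
  ref <- x$alleles$ref; alt <- x$alleles$alt
  ref[is.na(ref)] <- "A"; alt[is.na(alt)] <- "C"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gsbreed",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (has_ad) '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(x$calls)), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    paste(c("1", j, colnames(x$calls)[j], ref[j], alt[j], ".", "PASS", ".",
            fmt, gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
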