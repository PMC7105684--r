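# Fixtures and independent oracles shared across the test files.
# Everything is generated in code; no data files.

## hand-constructed call set: 4 genets x 5 markers with depth evidence
toy_calls <- function() {
  calls <- matrix(
    c(0L, 1L, 2L, NA, 0L,
      1L, 1L, 0L, 2L, 0L,
      2L, 0L, 1L, 1L, 0L,
      NA, NA, NA, NA, NA),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("g", 1:4), paste0("m", 1:5)))
  depth <- matrix(
    c(3L,  6L, 4L, 0L, 10L,
      6L,  3L, 5L, 4L, 10L,
      4L, 10L, 6L, 2L, 10L,
      0L,  0L, 0L, 0L,  0L),
    nrow = 4, byrow = TRUE, dimnames = dimnames(calls))
  ad_alt <- matrix(
    c(0L, 2L, 4L, 0L, 0L,
      5L, 1L, 0L, 4L, 0L,
      4L, 0L, 3L, 1L, 0L,
      0L, 0L, 0L, 0L, 0L),
    nrow = 4, byrow = TRUE, dimnames = dimnames(calls))
  genotype_calls(calls, depth = depth, ad_ref = depth - ad_alt,
                 ad_alt = ad_alt,
                 meta = data.frame(genet_id = paste0("g", 1:4),
                                   cycle = c("C1", "C1", "C2", "C2"),
                                   program = "P1"))
}

## write a small VCF with DP/AD fields; 3 genets x 4 markers, one
## multiallelic site
toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "g1", "g2", "g3", sep = "\t"),
    paste("1", "100", "s1", "A", "G", ".", "PASS", ".", "GT:AD:DP",
          "0/0:8,0:8", "0/1:3,4:7", "1/1:0,9:9", sep = "\t"),
    paste("1", "200", "s2", "C", "T", ".", "PASS", ".", "GT:AD:DP",
          "0/1:2,2:4", "./.:0,0:0", "0/0:5,0:5", sep = "\t"),
    paste("1", "300", "s3", "G", "A,T", ".", "PASS", ".", "GT:AD:DP",
          "0/0:6,0:6", "0/1:3,3:6", "1/2:0,3:6", sep = "\t"),
    paste("1", "400", "s4", "T", "C", ".", "PASS", ".", "GT:AD:DP",
          "1/1:0,6:6", "0/0:7,0:7", "0/1:4,4:8", sep = "\t"))
  writeLines(lines, path)
  path
}

## same genotype content as toy_vcf (biallelic sites) as a HapMap table
toy_hapmap <- function(path) {
  hdr <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                 "g1", "g2", "g3"), collapse = "\t")
  rows <- c(
    paste(c("s1", "A/G", "1", "100", "+", rep("NA", 6), "AA", "AG", "GG"),
          collapse = "\t"),
    paste(c("s2", "C/T", "1", "200", "+", rep("NA", 6), "CT", "NN", "CC"),
          collapse = "\t"),
    paste(c("s4", "T/C", "1", "400", "+", rep("NA", 6), "CC", "TT", "TC"),
          collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

## brute-force VanRaden GRM: explicit double loop over genet pairs
oracle_grm <- function(dosage) {
  p <- colMeans(dosage) / 2
  poly <- p > 0 & p < 1
  d <- dosage[, poly, drop = FALSE]
  p <- p[poly]
  n <- nrow(d)
  k <- matrix(0, n, n)
  denom <- 2 * sum(p * (1 - p))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      k[i, j] <- sum((d[i, ] - 2 * p) * (d[j, ] - 2 * p)) / denom
    }
  }
  dimnames(k) <- list(rownames(dosage), rownames(dosage))
  k
}

## closed-form dense REML log-likelihood for y ~ N(Xb, sigma2_a*ZKZ' + R),
## computed directly from determinants and solves (no shared code with the
## package's profiled engine)
oracle_reml_ll <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  b <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  q <- drop(t(r) %*% Vi %*% r)
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            q + (n - p) * log(2 * pi))
}

## simple single-cycle simulated data set for stage-1 / GBLUP tests
small_sim <- function(seed = 11, n = 150, m = 300, h2 = 0.5, rho = 0.4,
                      spatial = 0.5, cycles = 1) {
  cfg <- sim_config(n_cycles = cycles, genets_per_cycle = n, n_markers = m,
                    n_qtl = min(100L, m %/% 2L), h2_target = h2,
                    rho_row = rho, rho_col = rho,
                    spatial_variance_fraction = spatial, depth_mean = 0,
                    seed = seed)
  sim <- simulate_breeding_program(cfg)
  k <- suppressMessages(compute_grm(sim$genotypes))
  list(cfg = cfg, sim = sim, k = k)
}
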