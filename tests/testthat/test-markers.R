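test_that("VCF parsing populates calls, depths and multiallelic flags", {
  path <- toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  gc <- read_genotypes(path, "vcf")
  expect_equal(dim(gc), c(3L, 4L))
  ## one ./. call and one unrepresentable 1/2 call are missing
  expect_equal(sum(!is.na(gc$calls)), 10L)
  expect_equal(unname(gc$calls["g1", ]), c(0L, 1L, 0L, 2L))
  expect_equal(unname(gc$calls["g3", c("s1", "s4")]), c(2L, 1L))
  ## the 1/2 genotype at the multiallelic site is unrepresentable as a
  ## biallelic dosage and must be missing
  expect_true(is.na(gc$calls["g3", "s3"]))
  expect_equal(gc$n_alleles, c(2L, 2L, 3L, 2L))
  expect_equal(unname(gc$depth["g1", ]), c(8L, 4L, 6L, 6L))
  expect_equal(unname(gc$ad_alt["g2", "s1"]), 4L)
})

test_that("HapMap table yields the same call matrix as the VCF", {
  vcf <- read_genotypes(toy_vcf(withr::local_tempfile(fileext = ".vcf")), "vcf")
  hmp <- read_genotypes(toy_hapmap(withr::local_tempfile(fileext = ".txt")),
                        "hapmap")
  shared <- intersect(marker_ids(vcf), marker_ids(hmp))
  expect_equal(vcf$calls[, shared], hmp$calls[, shared])
})

test_that("tabular round trip and duplicate genet detection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genet,m1,m2", "a,0,2", "b,1,NA"), path)
  gc <- read_genotypes(path, "tabular")
  expect_equal(unname(gc$calls["b", ]), c(1L, NA))
  writeLines(c("genet,m1", "a,0", "a,1"), path)
  expect_error(read_genotypes(path, "tabular"), "duplicate genet")
})

test_that("simulated VCF export reads back identically", {
  s <- small_sim(seed = 5, n = 12, m = 20)
  cfg <- sim_config(n_cycles = 1, genets_per_cycle = 12, n_markers = 20,
                    depth_mean = 6, seed = 5)
  calls <- degrade_genotypes(s$sim$genotypes, cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(calls, path)
  back <- read_genotypes(path, "vcf")
  expect_equal(back$calls, calls$calls)
  expect_equal(back$depth, calls$depth, ignore_attr = TRUE)
})

test_that("depth rules blank exactly the under-supported calls", {
  gc <- toy_calls()
  out <- apply_depth_rules(gc, filter_spec(min_hom_depth = 4,
                                           min_het_contrasting = 2))
  ## hom with depth 3 -> missing; hom with depth 4 (boundary) -> kept
  expect_true(is.na(out$calls["g1", "m1"]))
  expect_equal(out$calls["g3", "m1"], 2L)
  ## het with allele depths (1,5) -> missing; (2,2)-style balanced -> kept
  expect_true(is.na(out$calls["g2", "m1"]))
  expect_equal(out$calls["g1", "m2"], 1L)
  ## het with only one contrasting alt read -> missing
  expect_true(is.na(out$calls["g3", "m4"]))
  ## depthless input errors
  bare <- genotype_calls(gc$calls)
  expect_error(apply_depth_rules(bare), "depth unavailable")
})

test_that("marker filter boundaries follow their rule phrasing", {
  ## 10 genets; m1 has 2/10 calls (call rate .2 < .3 -> removed),
  ## m2 has 3/10 (boundary, kept), m3 monomorphic, m4 fine
  calls <- matrix(NA_integer_, 10, 4,
                  dimnames = list(paste0("g", 1:10), paste0("m", 1:4)))
  calls[1:2, 1] <- c(0L, 1L)
  calls[1:3, 2] <- c(0L, 1L, 2L)
  calls[, 3] <- 0L
  calls[, 4] <- rep(c(0L, 1L, 2L), length.out = 10)
  gc <- genotype_calls(calls)
  out <- filter_markers(gc, filter_spec(min_maf = 0.01,
                                        min_marker_call_rate = 0.30))
  expect_setequal(marker_ids(out), c("m2", "m4"))
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_kept, 2L)

  ## MAF strictly-greater-than boundary: alt freq 0.005 out, 0.02 in
  n <- 100
  m5 <- c(rep(0L, 99), 1L)           # p = 0.005
  m6 <- c(rep(0L, 96), rep(1L, 4))   # p = 0.02
  cm <- cbind(m5 = m5, m6 = m6)
  rownames(cm) <- paste0("g", 1:n)
  gc2 <- genotype_calls(cm)
  out2 <- filter_markers(gc2, filter_spec(min_maf = 0.01,
                                          min_marker_call_rate = 0))
  expect_setequal(marker_ids(out2), "m6")

  ## non-biallelic markers dropped when flagged
  gc3 <- genotype_calls(calls[, 4, drop = FALSE], n_alleles = 3L)
  expect_warning(out3 <- filter_markers(gc3), "all markers removed")
  expect_equal(ncol(out3$calls), 0L)
})

test_that("genet filter is strict at the 95% missingness boundary", {
  calls <- matrix(0L, 3, 100,
                  dimnames = list(c("keep_full", "keep_95", "drop_96"),
                                  paste0("m", 1:100)))
  calls["keep_95", 1:95] <- NA_integer_
  calls["drop_96", 1:96] <- NA_integer_
  gc <- genotype_calls(calls)
  out <- filter_genets(gc, filter_spec(max_genet_missing = 0.95))
  expect_setequal(genet_ids(out), c("keep_full", "keep_95"))
  expect_equal(attr(out, "filter_report")$removed_ids, "drop_96")
})

test_that("marker and genet filters are idempotent and the pipeline is stable", {
  cfg <- sim_config(n_cycles = 1, genets_per_cycle = 60, n_markers = 150,
                    depth_mean = 3, missing_rate = 0.1, seed = 21)
  sim <- simulate_breeding_program(cfg)
  spec <- filter_spec()
  f1 <- filter_markers(sim$calls, spec)
  f2 <- filter_markers(f1, spec)
  expect_equal(f2$calls, f1$calls)
  g1 <- filter_genets(sim$calls, spec)
  expect_equal(filter_genets(g1, spec)$calls, g1$calls)
  p1 <- suppressWarnings(apply_filters(sim$calls, spec))
  p2 <- suppressWarnings(apply_filters(p1, spec))
  expect_equal(p2$calls, p1$calls)
})

test_that("dosage coding and allele frequencies", {
  calls <- matrix(c(0L, 1L, 2L,
                    0L, 0L, NA), ncol = 2,
                  dimnames = list(paste0("g", 1:3), c("mA", "mB")))
  mm <- to_dosage(genotype_calls(calls))
  expect_equal(unname(mm$dosage[, "mA"]), c(0, 1, 2))
  expect_equal(unname(mm$allele_freq), c(0.5, 0))
  expect_equal(unname(mm$call_rate), c(1, 2 / 3))
  gc_multi <- genotype_calls(calls, n_alleles = c(2L, 3L))
  expect_error(to_dosage(gc_multi), "mB")
})

test_that("imputation fills every gap with the right moments", {
  calls <- matrix(c(0L, 1L, 2L, NA,
                    0L, 0L, 0L, NA), ncol = 2,
                  dimnames = list(paste0("g", 1:4), c("m1", "m2")))
  mm <- to_dosage(genotype_calls(calls))
  mi <- impute_naive(mm, "marker_mean")
  expect_false(anyNA(mi$dosage))
  expect_equal(mi$dosage["g4", "m1"], 1.0)   # p = 0.5 -> 2p = 1
  expect_equal(mi$dosage["g4", "m2"], 0)     # p = 0 -> 0 under any method
  ## column means equal 2p exactly after marker-mean imputation
  expect_equal(unname(colMeans(mi$dosage)), unname(2 * mm$allele_freq))
  ## random HWE draws have binomial moments: p = 0.25, 10,000 draws
  n <- 10000
  calls2 <- matrix(NA_integer_, n, 1, dimnames = list(paste0("g", 1:n), "m"))
  calls2[1:4, 1] <- c(1L, 0L, 0L, 0L)        # observed p = 1/8... use known p
  calls2[1:4, 1] <- c(1L, 1L, 0L, 0L)        # p = 0.25
  m2 <- to_dosage(genotype_calls(calls2))
  m2i <- impute_naive(m2, "random_hwe", seed = 99)
  imputed <- m2i$dosage[-(1:4), 1]
  se <- sqrt(2 * 0.25 * 0.75 / length(imputed))
  expect_lt(abs(mean(imputed) - 0.5), 3 * se)
  ## determinism under the seed
  m2j <- impute_naive(m2, "random_hwe", seed = 99)
  expect_identical(m2i$dosage, m2j$dosage)
  ## all-missing marker errors
  calls3 <- matrix(NA_integer_, 3, 1, dimnames = list(letters[1:3], "m"))
  expect_error(impute_naive(to_dosage(genotype_calls(calls3))), "missing")
})

test_that("marker PCA matches an independent eigen-decomposition", {
  set.seed(42)
  d <- matrix(sample(0:2, 20, TRUE), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("m", 1:4)))
  storage.mode(d) <- "double"
  mm <- impute_naive(to_dosage(genotype_calls(
    matrix(as.integer(d), 5, 4, dimnames = dimnames(d)))), "marker_mean")
  pc <- pca_markers(mm, n_components = 3, maf_subset = 0, call_rate_subset = 0)
  ## oracle: eigen-decomposition of the centred cross-product
  xc <- scale(d, center = TRUE, scale = FALSE)
  ev <- eigen(tcrossprod(xc), symmetric = TRUE)
  for (j in 1:3) {
    expect_equal(abs(ev$values[j] / sum(ev$values)),
                 pc$var_explained[j], tolerance = 1e-10)
    sc_oracle <- ev$vectors[, j] * sqrt(ev$values[j])
    agree <- min(sum((sc_oracle - pc$scores[, j])^2),
                 sum((sc_oracle + pc$scores[, j])^2))
    expect_lt(agree, 1e-16)
  }
})

test_that("PCA invariances: duplicate genets, rank-1, genet order", {
  d <- matrix(c(0, 2, 0, 2,
                0, 2, 0, 2,
                2, 0, 2, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "a2", "b"), paste0("m", 1:4)))
  mm <- new_mm <- gsbreed:::new_marker_matrix(d, imputed = TRUE)
  pc <- pca_markers(mm, n_components = 2, maf_subset = 0,
                    call_rate_subset = 0)
  expect_equal(pc$scores["a", ], pc$scores["a2", ])
  expect_equal(pc$var_explained[1], 1.0, tolerance = 1e-12)
  ## rank truncation warns
  expect_warning(pca_markers(mm, n_components = 5, maf_subset = 0,
                             call_rate_subset = 0), "rank")
  ## permuting genets permutes scores (up to sign)
  s <- small_sim(seed = 3, n = 30, m = 60)
  mm2 <- gsbreed:::new_marker_matrix(s$sim$genotypes$dosage, imputed = TRUE)
  perm <- sample(nrow(mm2$dosage))
  mm2p <- gsbreed:::new_marker_matrix(mm2$dosage[perm, ], imputed = TRUE)
  p1 <- pca_markers(mm2, n_components = 2)
  p2 <- pca_markers(mm2p, n_components = 2)
  ids <- rownames(p1$scores)
  for (j in 1:2) {
    agree <- min(max(abs(p1$scores[ids, j] - p2$scores[ids, j])),
                 max(abs(p1$scores[ids, j] + p2$scores[ids, j])))
    expect_lt(agree, 1e-8)
  }
})
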