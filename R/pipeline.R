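`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a pipeline run configuration
#'
#' @param genotypes a [genotype_calls()] object, or a list
#'   `list(path =, format =)` understood by [read_genotypes()].
#' @param phenotypes a phenotype data.frame (see [assemble_stage1()]) or a
#'   CSV path with those columns.
#' @param seed integer seed (mandatory); all scheme-level randomness
#'   derives from it.
#' @param filter named list of [filter_spec()] arguments.
#' @param impute_method `"marker_mean"` or `"random_hwe"`.
#' @param stage1 named list of [stage1_control()] arguments.
#' @param min_obs stage-1 per-cycle-trait observation floor (default 350).
#' @param override_min_obs disable the observation floor.
#' @param stage2_input `"value_adj"` or `"blup"` — response passed to
#'   stage-2 GBLUP.
#' @param schemes evaluation schemes to run, any of `"within_cv"`,
#'   `"across_cycle"`, `"leave_one_cycle_out"`, `"pca_subset"`,
#'   `"program_subset"`.
#' @param folds,reps cross-validation folds and repetitions.
#' @param min_train minimum training-population size (default 100).
#' @param pca_component,pca_threshold PCA-similarity split settings.
#' @param traits optional character vector restricting the traits analysed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(genotypes, phenotypes, seed,
                       filter = list(), impute_method = "marker_mean",
                       stage1 = list(), min_obs = 350L,
                       override_min_obs = FALSE,
                       stage2_input = c("value_adj", "blup"),
                       schemes = c("within_cv", "across_cycle",
                                   "leave_one_cycle_out", "pca_subset",
                                   "program_subset"),
                       folds = 5L, reps = 100L, min_train = 100L,
                       pca_component = 2L, pca_threshold = 0,
                       traits = NULL) {
  if (missing(seed)) stop("`seed` is mandatory")
  stage2_input <- match.arg(stage2_input)
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (is.character(phenotypes)) {
    if (!file.exists(phenotypes)) stop("phenotype file not found: ", phenotypes)
  }
  if (is.list(genotypes) && !inherits(genotypes, "genotype_calls")) {
    if (is.null(genotypes$path) || !file.exists(genotypes$path))
      stop("genotype file not found: ", genotypes$path %||% "<missing>")
  }
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 seed = as.integer(seed), filter = filter,
                 impute_method = impute_method, stage1 = stage1,
                 min_obs = min_obs, override_min_obs = override_min_obs,
                 stage2_input = stage2_input, schemes = schemes,
                 folds = as.integer(folds), reps = as.integer(reps),
                 min_train = as.integer(min_train),
                 pca_component = as.integer(pca_component),
                 pca_threshold = pca_threshold, traits = traits),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; `genotypes`
#' must be a mapping with `path` and `format`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full genomic-selection pipeline
#'
#' Filtering, imputation, relationship matrix, stage-1 spatial REML per
#' cycle and trait-year, stage-2 GBLUP, and the configured evaluation
#' schemes, writing every report table to `out_dir`: `filter_report.json`,
#' `kinship.csv`, `blups.csv`, `gebv.csv`, `within_cv.csv`,
#' `across_cycle.csv`, `leave_one_out.csv`, `subset_models.csv`,
#' `best_model.csv` and a structured `run_log.json` recording the seed,
#' the configuration echo and per-stage notes. Stage failures propagate
#' with the stage name; tables already written are retained.
#'
#' @param config a [run_config()] (or YAML path).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with all in-memory results.
#' @export
run_gs_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(package = as.character(utils::packageVersion("gsbreed")),
              seed = config$seed,
              config = config[setdiff(names(config),
                                      c("genotypes", "phenotypes"))],
              notes = character(0))
  note <- function(...) log$notes <<- c(log$notes, paste0(...))
  set.seed(config$seed)

  calls <- pipeline_stage("genotypes", {
    g <- config$genotypes
    if (inherits(g, "genotype_calls")) g
    else read_genotypes(g$path, g$format %||% "vcf")
  })
  pheno <- pipeline_stage("phenotypes", {
    p <- config$phenotypes
    if (is.character(p)) p <- utils::read.csv(p, stringsAsFactors = FALSE)
    need <- c("genet_id", "cycle", "site", "year", "row", "col", "trait",
              "value")
    miss <- setdiff(need, names(p))
    if (length(miss)) stop("phenotype table lacks columns: ",
                           paste(miss, collapse = ", "))
    p
  })

  fspec <- do.call(filter_spec, config$filter)
  calls <- pipeline_stage("filter", apply_filters(calls, fspec))
  freport <- attr(calls, "filter_report")
  jsonlite::write_json(freport, file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  mm <- pipeline_stage("dosage", {
    m <- to_dosage(calls)
    impute_naive(m, config$impute_method, seed = config$seed)
  })
  note("imputation: ", config$impute_method)

  k <- pipeline_stage("kinship", {
    k0 <- compute_grm(mm)
    kb <- bend_to_psd(k0)
    if (isTRUE(attr(kb, "bend_applied")))
      note("kinship bent to PSD (ridge ", format(attr(kb, "bend")), ")")
    kb
  })
  write_grm(k, file.path(out_dir, "kinship.csv"))

  pca <- NULL
  if ("pca_subset" %in% config$schemes)
    pca <- pipeline_stage("pca",
      pca_markers(mm, n_components = max(config$pca_component, 2L)))

  ## stage 1 per cycle x trait x year
  traits <- config$traits %||% unique(pheno$trait)
  combos <- unique(pheno[pheno$trait %in% traits & !is.na(pheno$value),
                         c("trait", "year", "cycle")])
  s1ctrl <- do.call(stage1_control, config$stage1)
  fits <- list()
  blups <- list()
  for (i in seq_len(nrow(combos))) {
    tr <- combos$trait[i]; yr <- combos$year[i]; cy <- combos$cycle[i]
    key <- paste(tr, yr, cy, sep = "|")
    fit <- pipeline_stage(paste0("stage1[", key, "]"),
      fit_stage1(pheno, k, trait = tr, cycle = cy, year = yr,
                 control = s1ctrl))
    if (!fit$converged) note("stage1[", key, "]: not converged")
    fits[[key]] <- fit
    blups[[key]] <- extract_blups(fit, min_obs = config$min_obs,
                                  override = config$override_min_obs)
  }
  blup_tab <- do.call(rbind, blups)
  rownames(blup_tab) <- NULL
  utils::write.csv(blup_tab, file.path(out_dir, "blups.csv"),
                   row.names = FALSE)

  ## stage 2: GEBVs for all genotyped genets, per trait-year
  ty <- unique(blup_tab[, c("trait", "year")])
  gebv_tab <- list()
  gs_summaries <- list()
  for (i in seq_len(nrow(ty))) {
    bt <- blup_tab[blup_tab$trait == ty$trait[i] & blup_tab$year == ty$year[i], ]
    if (nrow(bt) < 2) next
    fit <- pipeline_stage("gblup", fit_gblup(bt, k, response = config$stage2_input))
    gebv_tab[[i]] <- data.frame(trait = ty$trait[i], year = ty$year[i],
                                genet_id = names(fit$gebv),
                                gebv = unname(fit$gebv),
                                stringsAsFactors = FALSE)
    ## variance components / heritability from the shrinkage-free response
    vc <- pipeline_stage("gblup",
      if ("value_raw" %in% names(bt)) fit_gblup(bt, k, response = "value_raw")
      else fit)
    gs_summaries[[paste(ty$trait[i], ty$year[i], sep = "|")]] <-
      list(sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e, h2 = vc$h2)
  }
  gebv_tab <- do.call(rbind, gebv_tab)
  utils::write.csv(gebv_tab, file.path(out_dir, "gebv.csv"),
                   row.names = FALSE)

  ## evaluation schemes per trait-year
  resp <- config$stage2_input
  res_cv <- res_across <- res_loo <- res_subset <- res_best <- list()
  for (i in seq_len(nrow(ty))) {
    bt <- blup_tab[blup_tab$trait == ty$trait[i] & blup_tab$year == ty$year[i], ]
    cyc <- unique(bt$cycle)
    tag <- paste(ty$trait[i], ty$year[i], sep = "|")
    if ("within_cv" %in% config$schemes) {
      for (ci in seq_along(cyc)) {
        b1 <- bt[bt$cycle == cyc[ci], ]
        if (nrow(b1) < config$folds) next
        r <- pipeline_stage("within_cv",
          within_cycle_cv(b1, k, folds = config$folds, reps = config$reps,
                          seed = config$seed + 100L + ci, response = resp))
        r$year <- ty$year[i]
        res_cv[[paste(tag, cyc[ci])]] <- r
      }
    }
    if ("across_cycle" %in% config$schemes && length(cyc) > 1) {
      for (tc in cyc) {
        r <- withCallingHandlers(
          pipeline_stage("across_cycle",
            across_cycle(bt, k, train_cycle = tc,
                         min_train = config$min_train, response = resp)),
          warning = function(w) {
            note("across_cycle[", tag, " train=", tc, "]: ",
                 conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        r$year <- ty$year[i]
        res_across[[paste(tag, tc)]] <- r
      }
    }
    if (any(c("leave_one_cycle_out", "pca_subset", "program_subset") %in%
            config$schemes) && length(cyc) > 1) {
      for (pc in cyc) {
        loo <- withCallingHandlers(
          pipeline_stage("leave_one_cycle_out",
            leave_one_cycle_out(bt, k, predict_cycle = pc,
                                min_train = config$min_train,
                                response = resp)),
          warning = function(w) {
            note("leave_one_out[", tag, " predict=", pc, "]: ",
                 conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        loo$year <- ty$year[i]
        if ("leave_one_cycle_out" %in% config$schemes)
          res_loo[[paste(tag, pc)]] <- loo
        cands <- list()
        if ("pca_subset" %in% config$schemes && !is.null(pca)) {
          grp <- pca_split(pca, config$pca_component, config$pca_threshold)
          for (g in c("high", "low")) {
            cands[[paste0("pca_", g)]] <- subset_prediction(
              bt, k, train_ids = grp[[g]], predict_cycle = pc,
              train_label = paste0("pca_", g),
              min_train = config$min_train, response = resp)
          }
        }
        if ("program_subset" %in% config$schemes &&
            "program" %in% names(pheno)) {
          progmap <- unique(pheno[, c("genet_id", "program")])
          for (pg in unique(progmap$program)) {
            if (is.na(pg)) next
            ids <- progmap$genet_id[progmap$program %in% pg]
            cands[[paste0("program_", pg)]] <- subset_prediction(
              bt, k, train_ids = ids, predict_cycle = pc,
              train_label = paste0("program_", pg),
              min_train = config$min_train, response = resp)
          }
        }
        if (length(cands)) {
          cand_tab <- do.call(rbind, cands)
          cand_tab$year <- ty$year[i]
          res_subset[[paste(tag, pc)]] <- cand_tab
          if (isTRUE(loo$eligible) && is.finite(loo$r)) {
            bm <- best_model(cand_tab, loo)
            bm$best_overall <- attr(bm, "best")
            res_best[[paste(tag, pc)]] <- bm
          }
        }
      }
    }
  }
  bind_write <- function(lst, file) {
    tab <- if (length(lst)) do.call(rbind, lst) else
      data.frame(scheme = character(0))
    rownames(tab) <- NULL
    utils::write.csv(tab, file.path(out_dir, file), row.names = FALSE)
    tab
  }
  cv_tab <- bind_write(res_cv, "within_cv.csv")
  across_tab <- bind_write(res_across, "across_cycle.csv")
  loo_tab <- bind_write(res_loo, "leave_one_out.csv")
  subset_tab <- bind_write(res_subset, "subset_models.csv")
  best_tab <- bind_write(res_best, "best_model.csv")

  log$gs_fit <- gs_summaries
  log$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(filter_report = freport, kinship = k, pca = pca,
                 stage1 = fits, blups = blup_tab, gebv = gebv_tab,
                 within_cv = cv_tab, across_cycle = across_tab,
                 leave_one_out = loo_tab, subset_models = subset_tab,
                 best_model = best_tab, log = log))
}
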