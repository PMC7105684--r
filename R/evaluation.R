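#' Fisher 95% confidence interval for a Pearson correlation
#'
#' \eqn{z = \mathrm{atanh}(r)} with half-width \eqn{1.96/\sqrt{n-3}}
#' (normal quantile for the requested level), back-transformed by tanh. The
#' interval always contains `r`.
#'
#' @param r sample correlation.
#' @param n number of pairs (`n >= 4`).
#' @param level confidence level, default 0.95.
#' @return named numeric `c(low, high)`.
#' @export
correlation_ci <- function(r, n, level = 0.95) {
  if (n < 4) stop("`n` must be at least 4")
  if (!is.finite(r) || abs(r) > 1) stop("`r` must lie in [-1, 1]")
  if (abs(r) == 1) {
    warning("|r| = 1: degenerate interval")
    return(c(low = r, high = r))
  }
  z <- atanh(r)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  c(low = tanh(z - hw), high = tanh(z + hw))
}

prediction_result <- function(scheme, trait, predict_cycle, train_label, r,
                              n, sd_over_reps = NA_real_, eligible = TRUE,
                              note = "") {
  ci <- if (eligible && is.finite(r) && n >= 4) correlation_ci(r, n)
        else c(low = NA_real_, high = NA_real_)
  data.frame(scheme = scheme, trait = trait, predict_cycle = predict_cycle,
             train_label = train_label, r = r, ci_low = unname(ci["low"]),
             ci_high = unname(ci["high"]), n = n,
             sd_over_reps = sd_over_reps, eligible = eligible, note = note,
             stringsAsFactors = FALSE)
}

blup_response <- function(blups, response) {
  if (!response %in% names(blups))
    response <- intersect(c("value_adj", "blup", "value_raw"), names(blups))[1]
  response
}

## first value of a possibly-absent label column
lab1 <- function(x) if (length(x)) unique(x)[1] else NA_character_

#' Within-cycle fivefold cross-validation
#'
#' Genets of one cycle are randomly partitioned (sampling without
#' replacement) into `folds` folds; each fold is predicted from a GBLUP
#' model trained on the remainder. Per repetition the held-out predictions
#' of all folds are pooled and correlated with the observed values; the
#' mean and SD over `reps` repetitions are reported. Full and half sibs may
#' fall on both sides of a split, as in routine within-program validation.
#'
#' @param blups single-cycle per-genet table ([extract_blups()] output).
#' @param k a `grm` covering the genets.
#' @param folds number of folds, default 5.
#' @param reps number of repetitions, default 100.
#' @param seed integer seed (mandatory: fold draws are reproducible).
#' @param response response column, see [fit_gblup()].
#' @param pool `"rep"` (default) pools all folds of a repetition before
#'   correlating; `"fold"` correlates each fold separately and averages.
#' @return one-row `data.frame` (`scheme = "within_cv"`) with mean `r`,
#'   Fisher CI at the cycle size, and `sd_over_reps`.
#' @export
within_cycle_cv <- function(blups, k, folds = 5L, reps = 100L, seed,
                            response = c("value_adj", "blup", "value_raw"),
                            pool = c("rep", "fold")) {
  response <- match.arg(response)
  pool <- match.arg(pool)
  if (missing(seed)) stop("`seed` is mandatory")
  response <- blup_response(blups, response)
  ids <- intersect(blups$genet_id, genet_ids(k))
  b <- blups[match(ids, blups$genet_id), , drop = FALSE]
  n <- length(ids)
  if (n < folds) stop("fewer genets (", n, ") than folds (", folds, ")")
  set.seed(as.integer(seed))
  rs <- numeric(reps)
  for (rep_i in seq_len(reps)) {
    fold_of <- sample(rep_len(seq_len(folds), n))   # partition, no replacement
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      hold <- which(fold_of == f)
      fit <- fit_gblup(b, k, training_ids = ids[-hold], response = response)
      pred[hold] <- fit$gebv[ids[hold]]
    }
    if (pool == "rep") {
      rs[rep_i] <- stats::cor(pred, b[[response]])
    } else {
      rf <- vapply(seq_len(folds), function(f) {
        hold <- which(fold_of == f)
        stats::cor(pred[hold], b[[response]][hold])
      }, numeric(1))
      rs[rep_i] <- mean(rf)
    }
  }
  prediction_result("within_cv", trait = lab1(b$trait),
                    predict_cycle = lab1(b$cycle),
                    train_label = lab1(b$cycle),
                    r = mean(rs), n = n, sd_over_reps = stats::sd(rs))
}

#' Across-cycle prediction
#'
#' One GBLUP model is trained on a single cycle and used to predict every
#' other requested cycle; prediction ability is the Pearson correlation
#' between GEBVs and the held-out cycle's adjusted values, with a Fisher
#' 95% CI. Training cycles below `min_train` genets are ineligible. A
#' predicted cycle equal to the training cycle is redirected to
#' [within_cycle_cv()] and flagged, never silently compared.
#'
#' @param blups multi-cycle per-genet table.
#' @param k a `grm`.
#' @param train_cycle cycle label to train on.
#' @param predict_cycles cycles to predict; default all others present.
#' @param min_train minimum training-set size, default 100.
#' @param response response column.
#' @param cv_seed,cv_reps,cv_folds passed to the within-cycle fallback.
#' @return `data.frame` with one row per predicted cycle.
#' @export
across_cycle <- function(blups, k, train_cycle, predict_cycles = NULL,
                         min_train = 100L, response = c("value_adj", "blup", "value_raw"),
                         cv_seed = 1L, cv_reps = 10L, cv_folds = 5L) {
  response <- match.arg(response)
  response <- blup_response(blups, response)
  cyc <- unique(blups$cycle)
  if (!train_cycle %in% cyc) stop("training cycle not present: ", train_cycle)
  if (is.null(predict_cycles)) predict_cycles <- setdiff(cyc, train_cycle)
  train <- blups[blups$cycle == train_cycle, , drop = FALSE]
  train_ids <- intersect(train$genet_id, genet_ids(k))
  trait <- lab1(blups$trait)
  if (length(train_ids) < min_train) {
    warning("training cycle ", train_cycle, " has ", length(train_ids),
            " genets < min_train = ", min_train, "; ineligible")
    return(do.call(rbind, lapply(predict_cycles, function(pc)
      prediction_result("across_cycle", trait, pc, train_cycle,
                        r = NA_real_, n = 0L, eligible = FALSE,
                        note = "training set below min_train"))))
  }
  fit <- fit_gblup(train, k, training_ids = train_ids, response = response)
  out <- lapply(predict_cycles, function(pc) {
    if (pc == train_cycle) {
      res <- within_cycle_cv(train, k, folds = cv_folds, reps = cv_reps,
                             seed = cv_seed, response = response)
      res$note <- "train == predict: within-cycle CV fallback"
      return(res)
    }
    tgt <- blups[blups$cycle == pc, , drop = FALSE]
    tgt <- tgt[tgt$genet_id %in% names(fit$gebv), , drop = FALSE]
    if (nrow(tgt) < 3) {
      message("cycle ", pc, " lacks trait '", trait, "' data; skipped")
      return(prediction_result("across_cycle", trait, pc, train_cycle,
                               r = NA_real_, n = nrow(tgt), eligible = FALSE,
                               note = "predicted cycle lacks data"))
    }
    r <- stats::cor(fit$gebv[tgt$genet_id], tgt[[response]])
    prediction_result("across_cycle", trait, pc, train_cycle, r = r,
                      n = nrow(tgt))
  })
  do.call(rbind, out)
}

#' Leave-one-cycle-out prediction
#'
#' The training population is the union of every other cycle's genets with
#' data for the trait; one GBLUP fit predicts the held-out cycle.
#'
#' @inheritParams across_cycle
#' @param predict_cycle the held-out cycle.
#' @return one-row `data.frame` (`scheme = "leave_one_cycle_out"`); when
#'   only one other cycle has data the result degenerates to across-cycle
#'   prediction and is flagged in `note`.
#' @export
leave_one_cycle_out <- function(blups, k, predict_cycle, min_train = 100L,
                                response = c("value_adj", "blup", "value_raw")) {
  response <- match.arg(response)
  response <- blup_response(blups, response)
  cyc <- unique(blups$cycle)
  others <- setdiff(cyc, predict_cycle)
  trait <- lab1(blups$trait)
  if (length(others) == 0) stop("no other cycles to train on")
  train <- blups[blups$cycle %in% others, , drop = FALSE]
  train_ids <- intersect(unique(train$genet_id), genet_ids(k))
  note <- if (length(others) == 1)
    "single training cycle: degenerates to across-cycle" else ""
  if (length(train_ids) < min_train) {
    warning("leave-one-out training union has ", length(train_ids),
            " genets < min_train = ", min_train, "; ineligible")
    return(prediction_result("leave_one_cycle_out", trait, predict_cycle,
                             "all_other_cycles", r = NA_real_, n = 0L,
                             eligible = FALSE,
                             note = "training set below min_train"))
  }
  fit <- fit_gblup(train, k, training_ids = train_ids, response = response)
  tgt <- blups[blups$cycle == predict_cycle, , drop = FALSE]
  tgt <- tgt[tgt$genet_id %in% names(fit$gebv), , drop = FALSE]
  if (nrow(tgt) < 3) stop("held-out cycle has fewer than 3 genets with data")
  r <- stats::cor(fit$gebv[tgt$genet_id], tgt[[response]])
  res <- prediction_result("leave_one_cycle_out", trait, predict_cycle,
                           "all_other_cycles", r = r, n = nrow(tgt))
  res$note <- note
  res
}

#' Prediction from an explicit training subset
#'
#' Shared backend of the PCA-similarity and breeding-program training-set
#' designs: train on the given genets (those with data), predict a cycle.
#'
#' @inheritParams across_cycle
#' @param train_ids genets forming the training population; genets of the
#'   predicted cycle are excluded from training.
#' @param predict_cycle cycle to predict.
#' @param train_label label recorded in the result row.
#' @return one-row `data.frame`.
#' @export
subset_prediction <- function(blups, k, train_ids, predict_cycle,
                              train_label = "subset", min_train = 100L,
                              response = c("value_adj", "blup", "value_raw")) {
  response <- match.arg(response)
  response <- blup_response(blups, response)
  trait <- lab1(blups$trait)
  tgt <- blups[blups$cycle == predict_cycle, , drop = FALSE]
  train <- blups[blups$genet_id %in% setdiff(train_ids, tgt$genet_id), ,
                 drop = FALSE]
  tids <- intersect(unique(train$genet_id), genet_ids(k))
  if (length(tids) < min_train) {
    return(prediction_result("subset", trait, predict_cycle, train_label,
                             r = NA_real_, n = 0L, eligible = FALSE,
                             note = "training set below min_train"))
  }
  fit <- fit_gblup(train, k, training_ids = tids, response = response)
  tgt <- tgt[tgt$genet_id %in% names(fit$gebv), , drop = FALSE]
  if (nrow(tgt) < 3)
    return(prediction_result("subset", trait, predict_cycle, train_label,
                             r = NA_real_, n = nrow(tgt), eligible = FALSE,
                             note = "predicted cycle lacks data"))
  r <- stats::cor(fit$gebv[tgt$genet_id], tgt[[response]])
  res <- prediction_result("subset", trait, predict_cycle, train_label,
                           r = r, n = nrow(tgt))
  res
}

#' Split genets into two similarity groups on a principal component
#'
#' Partitions genets by their score on the chosen component relative to a
#' threshold (default 0, the natural dividing line of a centred PCA) — the
#' device used to separate breeding-program material when pedigree labels
#' are unavailable or mixed.
#'
#' @param pca a [pca_markers()] result.
#' @param component component index, default 2.
#' @param threshold dividing score value, default 0.
#' @return list with `high` (score > threshold) and `low` id vectors and
#'   the `component`/`threshold` used.
#' @export
pca_split <- function(pca, component = 2L, threshold = 0) {
  stopifnot(inherits(pca, "gs_pca"))
  if (component > ncol(pca$scores))
    stop("component ", component, " not present in the PCA scores")
  sc <- pca$scores[, component]
  high <- rownames(pca$scores)[sc > threshold]
  low <- rownames(pca$scores)[sc <= threshold]
  if (length(high) == 0 || length(low) == 0)
    warning("all genets fall on one side of the threshold")
  list(high = high, low = low, component = component, threshold = threshold)
}

#' Rank candidate training-set designs against a reference
#'
#' Each candidate is declared `better` / `worse` than the reference when
#' the 95% confidence intervals do not overlap, and `indistinguishable`
#' otherwise; no multiplicity correction is applied. The best model (the
#' largest `r` among reference and candidates) is recorded in attribute
#' `"best"`.
#'
#' @param results `data.frame` of candidate prediction rows (same trait and
#'   predicted cycle).
#' @param reference one-row `data.frame`, typically the leave-one-cycle-out
#'   result.
#' @return `results` with a `verdict` column; attribute `"best"` names the
#'   top design.
#' @export
best_model <- function(results, reference) {
  stopifnot(nrow(reference) == 1)
  verdict <- vapply(seq_len(nrow(results)), function(i) {
    if (!isTRUE(results$eligible[i]) || !is.finite(results$r[i]))
      return("ineligible")
    if (results$ci_low[i] > reference$ci_high) "better"
    else if (results$ci_high[i] < reference$ci_low) "worse"
    else "indistinguishable"
  }, character(1))
  out <- results
  out$verdict <- verdict
  all_r <- c(stats::setNames(reference$r, reference$train_label),
             stats::setNames(results$r, results$train_label))
  all_r <- all_r[is.finite(all_r)]
  attr(out, "best") <- names(all_r)[which.max(all_r)]
  out
}
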