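#' Write / read a cohort table as CSV with a provenance sidecar
#'
#' The CSV carries the documented long-format header (one row per
#' participant-wave); an adjacent `<path>.provenance.json` records the seed
#' and generation parameters so a cohort file can be regenerated exactly.
#'
#' @param table Cohort tibble.
#' @param path CSV path.
#' @param config The [cohort_config()] used (optional, stored in the
#'   sidecar).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, config = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  side <- list(seed = attr(table, "seed"),
               n_rows = nrow(table),
               clipping = as.list(attr(table, "clipping") %||% list()),
               config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(side, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run the full shape-analysis pipeline
#'
#' Orchestrates generate -> derive -> (missingness) -> impute -> fit ->
#' compare -> classify -> effect share (-> power), writing a deterministic
#' artifact directory: cohort CSV + provenance, imputation log, per-outcome
#' fit summaries (JSON), per-imputation partial-effect and effect-share
#' CSVs, a verdict table, an optional power report, and a top-level
#' manifest with the seed, per-stage child seeds and a config hash. A single
#' global seed expands into per-stage child seeds so any stage can be re-run
#' independently.
#'
#' @param config Named list (or YAML file path) with elements `cohort`
#'   (arguments to [cohort_config()]), `shapes` (outcome -> [shape_spec()]
#'   arguments), and optionally `missingness` (`mechanism`, `rates`), `m`
#'   (imputations, default 5), `outcomes`, `tiers`, `weighted`,
#'   `observed_only`, `power` (arguments to [power_config()]).
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed Global seed (overrides `config$seed` if given).
#' @return An object of class `pipeline_result`: list with `cohort`,
#'   `imputed`, `results` (per outcome-tier tibbles), `verdicts`, `shares`,
#'   `power`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  cfg_hash <- digest_config(config)
  stage_seeds <- setNames(vapply(1:5, child_seed, integer(1), seed = seed),
                          c("generate", "missingness", "impute", "analysis",
                            "power"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  manifest <- list(seed = seed, stage_seeds = as.list(stage_seeds),
                   config_hash = cfg_hash, stages = list())
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- paste("failed:", conditionMessage(err))
    if (!is.null(out_dir))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE)
    abort(sprintf("pipeline stage `%s` failed: %s", stage,
                  conditionMessage(err)))
  }

  # --- generate + derive
  cohort <- tryCatch({
    cc <- do.call(cohort_config,
                  c(config$cohort, list(seed = stage_seeds[["generate"]])))
    shapes <- purrr::map(config$shapes, function(s)
      if (inherits(s, "shape_spec")) s else do.call(shape_spec, s))
    tab <- sample_cohort(cc, shapes)
    derive_measures(tab)
  }, error = function(e) fail("generate", e))
  manifest$stages$generate <- "ok"
  if (!is.null(out_dir)) write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  # --- missingness + imputation
  m <- config$m %||% 5
  observed_only <- isTRUE(config$observed_only)
  imputed <- tryCatch({
    tab <- cohort
    if (!is.null(config$missingness)) {
      tab <- inject_missingness(tab,
                                mechanism = config$missingness$mechanism %||% "MCAR",
                                rates = unlist(config$missingness$rates),
                                seed = stage_seeds[["missingness"]])
    }
    if (observed_only) {
      structure(list(m = 1L, tables = list(tab[complete.cases(
        tab[intersect(c("bmi", "hypertension", "diabetes"), names(tab))]), ]),
        models = character()), class = "imputed_set")
    } else {
      impute_chained(tab, m = m, seed = stage_seeds[["impute"]])
    }
  }, error = function(e) fail("impute", e))
  manifest$stages$impute <- "ok"
  if (!is.null(out_dir))
    jsonlite::write_json(list(m = imputed$m, models = as.list(imputed$models)),
                         file.path(out_dir, "imputation_log.json"),
                         auto_unbox = TRUE)

  # --- analysis
  outcomes <- config$outcomes %||% names(config$shapes)
  tiers <- config$tiers %||% 1
  weighted <- config$weighted %||% TRUE
  analysis <- tryCatch({
    set.seed(stage_seeds[["analysis"]])
    grid <- tidyr::expand_grid(outcome = outcomes, tier = tiers)
    res <- purrr::pmap(grid, function(outcome, tier) {
      run_outcome(imputed, outcome, tier = tier, weighted = weighted)
    })
    results <- dplyr::bind_rows(res)
    # FDR within the cognitive family per imputation x tier
    results <- results |>
      dplyr::group_by(.data$imputation, .data$tier) |>
      dplyr::group_modify(function(df, key) {
        df$q_smooth <- unname(fdr_family(setNames(df$p_smooth, df$outcome)))
        df
      }) |>
      dplyr::ungroup()
    verdicts <- purrr::map_dfr(seq_len(nrow(results)), function(i) {
      cls <- classify_shape(results$comparison[[i]],
                            results$partial_effect[[i]])
      dplyr::bind_cols(results[i, c("outcome", "tier", "imputation",
                                    "q_smooth", "p_anova", "delta_bic",
                                    "preferred")], cls)
    })
    shares <- purrr::map_dfr(seq_len(nrow(results)), function(i) {
      es <- effect_share(results$full_fit[[i]], weighted = FALSE)
      dplyr::bind_cols(results[i, c("outcome", "tier", "imputation")],
                       glance(es))
    })
    list(results = results, verdicts = verdicts, shares = shares)
  }, error = function(e) fail("analysis", e))
  manifest$stages$analysis <- "ok"
  if (!is.null(out_dir)) {
    utils::write.csv(analysis$verdicts, file.path(out_dir, "verdicts.csv"),
                     row.names = FALSE)
    utils::write.csv(analysis$shares, file.path(out_dir, "effect_shares.csv"),
                     row.names = FALSE)
    for (i in seq_len(nrow(analysis$results))) {
      r <- analysis$results[i, ]
      utils::write.csv(
        as.data.frame(r$partial_effect[[1]]),
        file.path(out_dir, sprintf("partial_effect_%s_tier%d_imp%d.csv",
                                   r$outcome, r$tier, r$imputation)),
        row.names = FALSE)
      fit <- r$full_fit[[1]]
      jsonlite::write_json(
        list(outcome = r$outcome, tier = r$tier, imputation = r$imputation,
             coefficients = as.list(fit$coefficients),
             lambda = as.list(fit$lambda),
             edf = as.list(fit$edf_by_term), bic = fit$bic,
             p_smooth = r$p_smooth, q_smooth = r$q_smooth,
             p_anova = r$p_anova, delta_bic = r$delta_bic,
             converged = fit$converged),
        file.path(out_dir, sprintf("fit_%s_tier%d_imp%d.json",
                                   r$outcome, r$tier, r$imputation)),
        auto_unbox = TRUE, digits = NA)
    }
  }

  # --- optional power stage
  power <- NULL
  if (!is.null(config$power)) {
    power <- tryCatch({
      pc <- do.call(power_config,
                    c(config$power, list(seed = stage_seeds[["power"]])))
      run_power(pc, keep_partial_effects = FALSE)
    }, error = function(e) fail("power", e))
    manifest$stages$power <- "ok"
    if (!is.null(out_dir)) {
      jsonlite::write_json(as.list(glance(power)),
                           file.path(out_dir, "power_report.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(power$reps[c("rep", "converged", "p", "delta_bic",
                                    "preferred")],
                       file.path(out_dir, "power_reps.csv"),
                       row.names = FALSE)
    }
  }

  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  structure(list(cohort = cohort, imputed = imputed,
                 results = analysis$results, verdicts = analysis$verdicts,
                 shares = analysis$shares, power = power,
                 manifest = manifest),
            class = "pipeline_result")
}

# order-stable hash of the configuration (no external digest dependency)
digest_config <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

#' Summarize a pipeline run the way the study tables report results
#'
#' Per outcome and model tier: the q-value range across imputations, the
#' count of significant imputations as an `"x/m"` string, the
#' smooth-vs-linear delta-BIC range, the majority shape verdict and the
#' below-cutoff effect-share range.
#'
#' @param result A `pipeline_result` (or a directory containing
#'   `verdicts.csv` and `effect_shares.csv`).
#' @param alpha Significance level for counting significant imputations.
#' @return A tibble, one row per outcome x tier.
#' @export
summarize_pipeline <- function(result, alpha = 0.05) {
  if (is.character(result)) {
    verdicts <- tibble::as_tibble(utils::read.csv(
      file.path(result, "verdicts.csv")))
    shares <- tibble::as_tibble(utils::read.csv(
      file.path(result, "effect_shares.csv")))
  } else {
    verdicts <- result$verdicts
    shares <- result$shares
  }
  if (nrow(verdicts) == 0) return(tibble::tibble())
  vs <- verdicts |>
    dplyr::group_by(.data$outcome, .data$tier) |>
    dplyr::summarise(
      q_range = sprintf("%.3g-%.3g", min(.data$q_smooth), max(.data$q_smooth)),
      significant = sprintf("%d/%d", sum(.data$q_smooth < alpha),
                            dplyr::n()),
      delta_bic_range = sprintf("%.3g-%.3g", min(.data$delta_bic),
                                max(.data$delta_bic)),
      verdict = names(sort(table(.data$hypothesis), decreasing = TRUE))[1],
      .groups = "drop")
  sh <- shares |>
    dplyr::group_by(.data$outcome, .data$tier) |>
    dplyr::summarise(share_below_range = sprintf("%.1f-%.1f%%",
                                                 100 * min(.data$share_below),
                                                 100 * max(.data$share_below)),
                     .groups = "drop")
  dplyr::left_join(vs, sh, by = c("outcome", "tier"))
}
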