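#' Run the full classification pipeline end-to-end
#'
#' Orchestrates the stages in dependency order: obtain the panel (synthetic
#' generation or CSV input), classify both waves, build the summary tables,
#' derive the scores, compute quota weights, estimate the transition matrix,
#' fit the association models, and write every table plus a run manifest to
#' `out_dir`. Any stage failure aborts with the stage name.
#'
#' @param config a configuration list, or the path to a YAML file holding
#'   one. Recognised sections:
#'   * `seed` — integer, flows into the generator;
#'   * `generator` — overrides passed to [generator_config()] (used when no
#'     input files are given);
#'   * `input` — list with `wave2`, `wave3` CSV paths (skips generation);
#'   * `classification` — overrides for [dichotomy_config()];
#'   * `weighting` — `targets` (named lists `gender`, `age_band`) and
#'     `mode`; omit the section to skip weighting;
#'   * `models` — logical, fit the standard model set (default `TRUE`).
#' @param out_dir output directory.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stage <- "setup"
  manifest <- list(package_version = as.character(utils::packageVersion("worrytype")),
                   seed = config$seed, stages = list())
  on_fail <- function(e) stop("pipeline failed at stage '", stage, "': ",
                              conditionMessage(e), call. = FALSE)

  tryCatch({
    stage <- "input"
    cb <- default_codebook()
    if (!is.null(config$input)) {
      w2 <- read_wave(config$input$wave2, cb, 2L)
      w3 <- read_wave(config$input$wave3, cb, 3L)
      truth <- NULL
    } else {
      gen_args <- config$generator
      if (is.null(gen_args)) gen_args <- list()
      if (!is.null(config$seed)) gen_args$seed <- config$seed
      sim <- do.call(generator_config, gen_args)
      panel_sim <- generate_panel(sim)
      w2 <- panel_sim$wave2; w3 <- panel_sim$wave3
      truth <- panel_sim$truth
    }
    manifest$stages$input <- list(n_wave2 = nrow(w2), n_wave3 = nrow(w3),
                                  warnings_wave2 = sum(validation_report(w2)$n_invalid),
                                  warnings_wave3 = sum(validation_report(w3)$n_invalid))

    stage <- "classify"
    cls_args <- config$classification
    cfg <- if (is.null(cls_args)) dichotomy_config() else do.call(dichotomy_config, cls_args)
    panel <- link_panel(w2, w3)
    tabs <- build_group_tables(w2, cfg)
    out_tables <- list(groups_wave2 = tabs$groups,
                       worry_precautions_wave2 = tabs$worry_precautions,
                       precautions_qol_wave2 = tabs$precautions_qol)
    manifest$stages$classify <- list(n_classified = tabs$n_classified)

    stage <- "scores"
    w2s <- cbind(w2, covid_impact_score(w2))
    w2s$emotion_score <- emotion_score(w2)
    reeng <- reengagement_score(panel)
    alpha <- tryCatch(cronbach_alpha(emotion_item_matrix(w2)), error = function(e) NA_real_)
    out_tables$reengagement <- reeng
    out_tables$score_summary <- data.frame(
      statistic = c("emotion_alpha_wave2", "mean_impact_score", "mean_emotion_score",
                    "mean_reengagement"),
      value = c(alpha, mean(w2s$impact_score), mean(w2s$emotion_score, na.rm = TRUE),
                mean(reeng$value, na.rm = TRUE)))
    manifest$stages$scores <- list(emotion_alpha = alpha)

    stage <- "weights"
    if (!is.null(config$weighting)) {
      wt <- config$weighting
      if (is.null(wt$targets)) stop("weighting requested without targets")
      targets <- margin_targets(gender = unlist(wt$targets$gender),
                                age_band = unlist(wt$targets$age_band),
                                total = wt$targets$total)
      mode <- if (is.null(wt$mode)) "cell" else wt$mode
      wts <- compute_weights(w2, targets, mode = mode)
      w2cls <- cbind(w2, classify_full(w2, cfg))
      out_tables$weights_wave2 <- wts
      out_tables$groups_wave2_weighted <-
        weighted_counts(w2cls, wts, by = "worry_group")
      manifest$stages$weights <- list(mode = mode, total = sum(wts$weight))
    }

    stage <- "transitions"
    tr <- transitions(panel, cfg)
    out_tables$transition_counts <- as.data.frame(tr$counts)
    out_tables$transition_flows <- sankey_table(tr)
    manifest$stages$transitions <- list(n_linked = tr$n_linked,
                                        stability_share = tr$stability_share)

    stage <- "models"
    if (is.null(config$models) || isTRUE(config$models)) {
      cls2 <- classify_full(w2s, cfg)
      w2s$worry_group <- cls2$worry_group
      dat <- w2s[w2s$worry_group %in% worry_groups(), , drop = FALSE]
      dat$worry_group <- droplevels(dat$worry_group)
      fit_notes <- character(0)
      quiet_fit <- function(...) withCallingHandlers(
        fit_model(...),
        warning = function(w) {
          fit_notes <<- c(fit_notes, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      fits <- list(
        group_membership = quiet_fit(model_spec(
          "multinomial_logit", "worry_group", c("had_covid", "impact_score"),
          reference_outcome = "unworried"), dat),
        emotion = quiet_fit(model_spec(
          "negative_binomial", "emotion_score", "worry_group",
          reference_levels = list(worry_group = "unworried")), dat))
      out_tables$model_tables <- model_report(fits)
      manifest$stages$models <- list(fitted = names(fits),
                                     warnings = unique(fit_notes))
    }

    stage <- "write"
    paths <- write_outputs(out_tables, out_dir)
    manifest$outputs <- as.list(tools::md5sum(sort(paths)))
    manifest$timestamp <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }, error = on_fail)
  invisible(manifest)
}
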