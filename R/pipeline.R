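# Config-driven pipeline: simulate (or read) -> encounter histories ->
# candidate-model fits -> GOF / c-hat -> QAICc ranking -> survival,
# mortality and behavior reports, all written to an artifact directory
# with a machine-readable manifest. Identical config + seed gives
# identical numerical outputs.

#' Default candidate model set
#'
#' A structured family crossing the population-grouping factors with linear
#' and multiplicative segment effects and the release-date covariate, over
#' the two standard detection structures (shared line probabilities with
#' river-mouth-specific rates, with or without release date).
#'
#' @param fixed_p terminal detection probability pinned in every model
#' @return character vector of model strings
#' @export
candidate_models <- function(fixed_p = 0.685) {
  phis <- c("segment",
            "segment + SkokH", "segment * SkokH", "segment * SkokH + rd",
            "segment * reartype + rd", "segment * DuckH + rd",
            "segment * SkokH + year + rd",
            "segment * population + year")
  ps <- c("segment + RM:line", "segment + RM:line + rd")
  unlist(lapply(phis, function(f) {
    vapply(ps, function(g) {
      sprintf("phi ~ %s; p ~ %s; fix p[JDF]=%g", f, g, fixed_p)
    }, character(1))
  }), use.names = FALSE)
}

#' Build or load a run configuration
#'
#' @param x a list, or path to a JSON config file with the same fields:
#'   either `simulate = TRUE` (with optional `sim` overrides) or `inputs`
#'   (paths to fish/receivers/events CSVs); `models` (character vector,
#'   default [candidate_models()]); `fixed_p` and `p_bounds`; `n_eff`
#'   convention (`"released"`); `seed`; `out` directory
#' @return a validated `run_config` list
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    simulate = TRUE, inputs = NULL, sim = list(),
    models = NULL, fixed_p = 0.685,
    p_bounds = c(0.428, 0.863), n_eff = "released",
    seed = 1L, out = "pipeline-out"
  ), x)
  if (!is.null(cfg$inputs)) cfg$simulate <- FALSE
  if (cfg$simulate && !is.null(cfg$inputs)) {
    stop("config must supply exactly one of simulation or input paths",
         call. = FALSE)
  }
  if (!cfg$simulate && is.null(cfg$inputs)) {
    stop("config must supply input paths when simulate = FALSE", call. = FALSE)
  }
  if (is.null(cfg$models)) cfg$models <- candidate_models(cfg$fixed_p)
  if (!length(cfg$models)) stop("no candidate models configured", call. = FALSE)
  if (diff(cfg$p_bounds) <= 0) stop("p_bounds must be ordered", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' @param config a [run_config()] (or list / JSON path coerced through it)
#' @return invisibly, a list of the main artifacts; files are written
#'   under `config$out`
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  data <- pipeline_stage("data", {
    if (config$simulate) {
      sc <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                  config$sim))
      simulate_dataset(sc)
    } else {
      read_tables(config$inputs$fish, config$inputs$receivers,
                  config$inputs$events)
    }
  })

  eh <- pipeline_stage("histories", {
    eh <- build_encounter_histories(data$events, data$fish, data$receivers)
    utils::write.csv(data.frame(fish_id = rownames(eh$history),
                                history = history_strings(eh)),
                     file.path(out, "histories.csv"), row.names = FALSE)
    write_inp(eh, grouping = "population",
              path = file.path(out, "histories.inp"))
    eh
  })

  gof <- pipeline_stage("gof", release_gof(build_marray(eh)))

  fits <- pipeline_stage("fits", {
    lapply(config$models, function(m) cjs_fit(m, eh, c_hat = gof$c_hat))
  })

  ranked <- pipeline_stage("ranking", {
    tab <- rank_models(fits, c_hat = gof$c_hat,
                       n_eff = if (identical(config$n_eff, "released"))
                         nrow(eh$history) else config$n_eff)
    utils::write.csv(tab, file.path(out, "model_table.csv"),
                     row.names = FALSE)
    tab
  })

  best <- fits[[match(ranked$model[1],
                      vapply(fits, function(f) f$spec$string, character(1)))]]

  survival <- pipeline_stage("survival", {
    utils::write.csv(best$real_phi, file.path(out, "survival_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(best$real_p, file.path(out, "detection_estimates.csv"),
                     row.names = FALSE)
    ms <- marine_survival(best)
    sens <- sensitivity_range(best$spec, eh,
                              p_values = sort(c(config$p_bounds,
                                                config$fixed_p)),
                              c_hat = gof$c_hat)
    utils::write.csv(cbind(ms, sens$range[, c("min", "max")]),
                     file.path(out, "marine_survival.csv"),
                     row.names = FALSE)
    list(marine = ms, sensitivity = sens)
  })

  mortality <- pipeline_stage("mortality", {
    f <- cjs_fit(sprintf(
      "phi ~ segment * population + year; p ~ segment + RM:line; fix p[JDF]=%g",
      config$fixed_p), eh, c_hat = gof$c_hat)
    grid <- f$real_phi
    tab <- NULL
    if (all(c("population", "year") %in% names(grid))) {
      phi_long <- data.frame(population = grid$population, year = grid$year,
                             segment = grid$segment, phi = grid$estimate)
      phi_long <- phi_long[phi_long$segment != SEGMENT_NAMES[1], ]
      tab <- mortality_rate_table(phi_long)
      utils::write.csv(tab, file.path(out, "mortality_rates.csv"),
                       row.names = FALSE)
    }
    tab
  })

  behavior <- pipeline_stage("behavior", {
    res <- list()
    skh <- data$fish[data$fish$population == "SkokomishH", ]
    if (nrow(skh) && length(unique(skh$smolt_index)) > 1) {
      tab <- si_detection_table(skh, eh)
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        res$g_test <- g_test_adj(tab)
        res$si_table <- tab
      }
    }
    skok <- data$fish[data$fish$population %in%
                        c("SkokomishW", "SkokomishH"), ]
    if (nrow(skok)) {
      skok$fw_rate <- travel_rate(data$events, skok, data$receivers,
                                  "release", "RM-Skokomish", 13.5)[skok$fish_id]
      skok$marine_rate <- travel_rate(data$events, skok, data$receivers,
                                      "RM-Skokomish", "HCB", 75)[skok$fish_id]
      skok$range_km <- migration_range(data$events, skok,
                                       data$receivers)[skok$fish_id]
      for (v in c("fw_rate", "marine_rate", "range_km")) {
        ok <- tryCatch({
          a <- two_way_anova(skok, v)
          res[[paste0("anova_", v)]] <- a$table
          if (!is.na(a$table$p[3]) && a$table$p[3] <= 0.05) {
            res[[paste0("tukey_", v)]] <- tukey_hsd(a)
          }
          TRUE
        }, error = function(e) FALSE)
      }
      dens <- density_table(data$events, skok$fish_id, data$receivers)
      utils::write.csv(dens, file.path(out, "density_table.csv"),
                       row.names = FALSE)
      res$density <- dens
    }
    for (nm in grep("^(anova|tukey)_", names(res), value = TRUE)) {
      utils::write.csv(res[[nm]], file.path(out, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    res
  })

  manifest <- list(
    seed = config$seed,
    n_fish = nrow(data$fish),
    n_models = length(config$models),
    c_hat = gof$c_hat,
    best_model = ranked$model[1],
    config_hash = sum(utf8ToInt(paste(deparse(unclass(config)),
                                      collapse = ""))),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(data = data, histories = eh, gof = gof, ranked = ranked,
                 best = best, survival = survival, mortality = mortality,
                 behavior = behavior, manifest = manifest, out = out))
}
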