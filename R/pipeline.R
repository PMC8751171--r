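PIPELINE_STAGES <- c("scene", "truth", "observe", "aod_met", "predictors",
                     "selection", "gtwr", "neighborhood", "mapping")

#' Run the two-stage analysis in memory
#'
#' Chains the pipeline on a synthetic study area: scene generation, truth
#' simulation, observation sampling, AOD QA/merge/resampling and meteorology
#' kriging, predictor-table assembly, distance-decay + stepwise screening,
#' seasonal GTWR fitting with bandwidth selection and LOOCV, the
#' neighbourhood delta model from the mobile campaign, and the seasonal /
#' annual / delta / final maps.
#'
#' @param config a [pipeline_config()].
#' @param params a [truth_params()].
#' @param through last stage to run (default "mapping").
#' @param scene optionally reuse an existing scene.
#' @return list with one entry per executed stage.
#' @export
lur_pipeline <- function(config, params = truth_params(),
                         through = "mapping", scene = NULL) {
  validate_config(config)
  last <- match.arg(through, PIPELINE_STAGES)
  k <- match(last, PIPELINE_STAGES)
  res <- list(config = config, params = params)
  run <- function(st) match(st, PIPELINE_STAGES) <= k

  if (run("scene"))
    res$scene <- if (is.null(scene)) generate_scene(config) else scene
  if (run("truth"))
    res$truth <- simulate_truth(res$scene, params, config)
  if (run("observe"))
    res$obs <- sample_observations(res$truth, res$scene, params, config)
  if (run("aod_met")) res <- stage_aod_met(res, config)
  if (run("predictors")) res <- stage_predictors(res, config)
  if (run("selection")) {
    # distance-decay correlation on the within-season response: the seasonal
    # background is common to every radius candidate and only dilutes the
    # spatial correlation ranking
    se_mean <- stats::ave(res$table$pm25, res$table$season)
    res$radii_sel <- select_buffer_radii(res$table,
                                         response = res$table$pm25 - se_mean)
    res$stepwise <- stepwise_select(res$table, res$table$pm25,
                                    res$radii_sel$candidates, forced = "AOD")
  }
  if (run("gtwr")) res <- stage_gtwr(res, config)
  if (run("neighborhood")) res <- stage_neighborhood(res, config)
  if (run("mapping")) res <- stage_mapping(res, config)
  res
}

stage_aod_met <- function(res, config) {
  scene <- res$scene; obs <- res$obs
  tpl <- scene$landuse
  nr <- grid_nrow(tpl); nc <- grid_ncol(tpl)
  acc <- lapply(config$seasons, function(s)
    list(sum = matrix(0, nr, nc), n = matrix(0, nr, nc)))
  names(acc) <- config$seasons
  days <- res$truth$days
  st <- scene$stations
  aod_valid <- matrix(FALSE, nrow(days), nrow(st))
  for (d in seq_len(nrow(days))) {
    merged <- daily_merge(qa_filter(obs$aod[[d]]$terra),
                          qa_filter(obs$aod[[d]]$aqua))
    fine <- resample_bilinear(merged, config$cell_size)
    v <- grid_values(fine)
    ok <- !is.na(v)
    se <- days$season[d]
    acc[[se]]$sum[ok] <- acc[[se]]$sum[ok] + v[ok]
    acc[[se]]$n[ok] <- acc[[se]]$n[ok] + 1
    aod_valid[d, ] <- !is.na(grid_sample(fine, st$x, st$y))
  }
  res$aod_valid <- aod_valid
  res$aod_seasonal <- lapply(acc, function(a) {
    m <- a$sum / a$n; m[a$n == 0] <- NA_real_
    grid_set_values(tpl, m)
  })
  # meteorology kriged to the monitoring stations, daily, then season means
  wst <- res$scene$weather_stations
  stc <- cbind(res$scene$stations$x, res$scene$stations$y)
  met_vars <- c("TEMP", "RH", "WSPD", "RF", "MSLP")
  clip <- c(TEMP = NA, RH = 0, WSPD = 0, RF = 0, MSLP = NA)
  recs <- list()
  for (d in unique(obs$weather$day)) {
    wd <- obs$weather[obs$weather$day == d, ]
    wd <- wd[match(wst$id, wd$station), ]
    row <- data.frame(station = res$scene$stations$id, day = d,
                      season = wd$season[1])
    for (v in met_vars) {
      cm <- if (is.na(clip[[v]])) NULL else clip[[v]]
      row[[v]] <- as.vector(krige_met(wd[[v]], cbind(wst$x, wst$y), stc,
                                      clip_min = cm))
    }
    recs[[length(recs) + 1]] <- row
  }
  met_daily <- do.call(rbind, recs)
  agg <- stats::aggregate(met_daily[met_vars],
                          by = met_daily[c("station", "season")], mean)
  snd <- merge(res$obs$sounding, res$truth$days, by = "day")
  snd_se <- stats::aggregate(snd[setdiff(names(res$obs$sounding), "day")],
                             by = snd["season"], mean)
  res$temporal <- merge(agg, snd_se, by = "season", sort = FALSE)
  res$met_daily <- met_daily
  res
}

stage_predictors <- function(res, config) {
  # matched-day averaging: the seasonal PM response pools only the days with
  # a valid AOD retrieval at the station's cell, so the response and the
  # seasonal AOD surface average identical day sets
  stn <- res$obs$stations
  sid <- match(stn$station, res$scene$stations$id)
  stn <- stn[res$aod_valid[cbind(stn$day, sid)], , drop = FALSE]
  lost <- setdiff(res$scene$stations$id, unique(stn$station))
  if (length(lost))
    message(length(lost), " station(s) dropped for missing AOD coverage: ",
            paste(lost, collapse = ", "))
  pm <- stats::aggregate(pm25 ~ station + season, data = stn, FUN = mean)
  res$table <- assemble_table(res$scene, pm, res$aod_seasonal,
                              temporal = res$temporal,
                              radii = config$buffer_radii,
                              rose = res$scene$rose)
  res
}

season_midpoints <- function(config) {
  nd <- config$days_per_season
  stats::setNames((seq_along(config$seasons) - 1) * nd + (nd + 1) / 2,
                  config$seasons)
}

stage_gtwr <- function(res, config) {
  vars <- c("AOD", res$stepwise$selected)
  # seasonal refits have only the season's rows: keep the strongest terms
  # (by |t| in the pooled screen) if the design would be under-determined
  nmin <- min(table(res$table$season))
  if (length(vars) + 1 > nmin - 4) {
    tv <- abs(summary(res$stepwise$fit)$coefficients[, 3])
    keep <- names(sort(tv[res$stepwise$selected], decreasing = TRUE))
    keep <- keep[seq_len(max(0, nmin - 5))]
    message("seasonal GTWR design reduced to: AOD + ",
            paste(keep, collapse = " + "))
    vars <- c("AOD", keep)
  }
  fml <- stats::reformulate(vars, response = "pm25")
  mids <- season_midpoints(config)
  st <- res$scene$stations
  # temporal variables are constant within one season's rows: they act
  # through the seasonal intercept and cannot carry a within-season slope
  con <- vars[vapply(vars, function(v)
    all(tapply(res$table[[v]], res$table$season, stats::sd) < 1e-9), TRUE)]
  if (length(con)) {
    message("dropped within-season-constant term(s) from seasonal GTWR: ",
            paste(con, collapse = ", "))
    vars <- setdiff(vars, con)
    fml <- stats::reformulate(vars, response = "pm25")
  }
  fits <- list(); cv <- list()
  for (se in config$seasons) {
    rows <- res$table[res$table$season == se, , drop = FALSE]
    coords <- cbind(st$x[match(rows$station, st$id)],
                    st$y[match(rows$station, st$id)])
    times <- rep(mids[[se]], nrow(rows))
    bw <- select_bandwidth(fml, rows, coords, times, kernel = config$kernel,
                           h_grid = config$h_grid, lambda_grid = 0)
    fits[[se]] <- gtwr(fml, rows, coords, times, bw$spec)
    cv[[se]] <- loocv(fml, rows, coords, times, bw$spec)
    attr(fits[[se]], "cv_r2") <- cv[[se]]
  }
  res$gtwr_fits <- fits
  res$cv_r2 <- unlist(cv)
  res$gtwr_formula <- fml
  res
}

stage_neighborhood <- function(res, config) {
  mob <- res$obs$mobile
  mob$pm <- rh_correct(mob$pm_raw, mob$RH)
  mob$hour <- mob$hour_index
  mob <- background_adjust(mob, res$obs$background)
  mob <- delta_pm25(mob)
  res$metrics <- segment_metrics(res$scene$roads)
  res$delta_table <- attach_neighborhood_predictors(
    mob, res$scene, res$metrics, max_dist = config$snap_distance,
    morph = res$truth$morph)
  res$delta_model <- fit_delta_mlr(res$delta_table)
  res
}

stage_mapping <- function(res, config) {
  vars <- setdiff(colnames(res$gtwr_fits[[1]]$X), "(Intercept)")
  met_vars <- c("TEMP", "RH", "WSPD", "RF", "MSLP")
  snd_vars <- setdiff(names(res$obs$sounding), "day")
  spatial <- setdiff(vars, c("AOD", met_vars, snd_vars))
  sp_grids <- if (length(spatial))
    predictor_grids(res$scene, cols = spatial, rose = res$scene$rose)
  else list()
  tpl <- res$scene$landuse
  wst <- res$scene$weather_stations
  grids_by_season <- list()
  for (se in config$seasons) {
    g <- sp_grids
    g$AOD <- res$aod_seasonal[[se]]
    for (v in intersect(vars, met_vars)) {
      wd <- res$obs$weather[res$obs$weather$season == se, ]
      m <- stats::aggregate(wd[[v]], by = list(station = wd$station), mean)
      m <- m[match(wst$id, m$station), ]
      g[[v]] <- krige_met(m$x, cbind(wst$x, wst$y), tpl)
    }
    for (v in intersect(vars, snd_vars)) {
      val <- res$temporal[[v]][match(se, res$temporal$season)]
      g[[v]] <- grid_set_values(tpl, matrix(val, grid_nrow(tpl),
                                            grid_ncol(tpl)))
    }
    grids_by_season[[se]] <- g
  }
  mids <- season_midpoints(config)
  res$maps_seasonal <- seasonal_maps(res$gtwr_fits, grids_by_season, mids)
  dc <- stats::setNames(rep(config$days_per_season, length(config$seasons)),
                        config$seasons)
  res$map_annual <- annual_combine(res$maps_seasonal, dc)
  dl <- delta_layer(res$delta_model, res$truth$morph, res$metrics)
  res$delta_map <- dl$delta
  res$delta_mask_report <- dl$report
  res$map_final <- overlay_maps(res$map_annual, res$delta_map)
  res
}

#' Run pipeline stages and write logged artifacts
#'
#' Executes the requested stages (which must form a prefix of the canonical
#' order `r paste(PIPELINE_STAGES, collapse = " -> ")`) and writes each
#' stage's outputs under `out_dir`, plus a manifest recording the
#' configuration, seed, package version and the MD5 checksum of every written
#' file. Deterministic stages reproduce bit-identical manifests on rerun.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stage names (default: all).
#' @param out_dir output directory (created if needed).
#' @param params a [truth_params()].
#' @return the manifest, invisibly; artifacts and `manifest.json` on disk.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES, out_dir,
                         params = truth_params()) {
  validate_config(config)
  idx <- match(stages, PIPELINE_STAGES)
  if (anyNA(idx)) stop("unknown stage(s): ",
                       paste(stages[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  if (!identical(idx, seq_len(length(idx))))
    stop("stage '", PIPELINE_STAGES[idx[which(idx != seq_along(idx))[1]]],
         "' requested before its dependencies (stages must form a prefix of: ",
         paste(PIPELINE_STAGES, collapse = " -> "), ")")
  last <- PIPELINE_STAGES[max(idx)]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- lur_pipeline(config, params, through = last)
  files <- character(0)
  emit <- function(f) files <<- c(files, f)
  p <- function(...) file.path(out_dir, ...)
  if ("scene" %in% stages) {
    emit(write_raster(res$scene$landuse, p("landuse.asc")))
    emit(write_raster(res$scene$dsm, p("dsm.asc")))
    emit(write_raster(res$scene$population, p("population.asc")))
    emit(write_roads(res$scene$roads, p("roads.geojson")))
    emit(write_buildings(res$scene$buildings, p("buildings.geojson")))
    emit(write_points(res$scene$stations, p("stations.geojson")))
    emit(write_points(res$scene$weather_stations, p("weather_stations.geojson")))
    emit(write_points(res$scene$bus_stops, p("bus_stops.geojson")))
  }
  if ("truth" %in% stages) {
    emit(write_raster(res$truth$static, p("truth_static.asc")))
    utils::write.csv(data.frame(day = seq_along(res$truth$background),
                                background = res$truth$background),
                     p("truth_background.csv"), row.names = FALSE)
    emit(p("truth_background.csv"))
  }
  if ("observe" %in% stages) {
    for (nm in c("stations", "weather", "sounding", "mobile", "background")) {
      utils::write.csv(res$obs[[nm]], p(paste0(nm, ".csv")), row.names = FALSE)
      emit(p(paste0(nm, ".csv")))
    }
  }
  if ("aod_met" %in% stages)
    for (se in names(res$aod_seasonal))
      emit(write_raster(res$aod_seasonal[[se]], p(paste0("aod_", se, ".asc"))))
  if ("predictors" %in% stages) {
    utils::write.csv(res$table, p("predictor_table.csv"), row.names = FALSE)
    emit(p("predictor_table.csv"))
    jsonlite::write_json(attr(res$table, "schema"), p("predictor_schema.json"),
                         dataframe = "rows", na = "null")
    emit(p("predictor_schema.json"))
  }
  if ("selection" %in% stages) {
    jsonlite::write_json(list(
      chosen_radii = res$radii_sel$chosen,
      selected = res$stepwise$selected, forced = res$stepwise$forced,
      p = as.list(res$stepwise$p), vif = as.list(res$stepwise$vif),
      trace = res$stepwise$trace),
      p("selection.json"), dataframe = "rows", auto_unbox = TRUE, digits = NA,
      na = "null")
    emit(p("selection.json"))
  }
  if ("gtwr" %in% stages) {
    di <- lapply(res$gtwr_fits, function(f)
      c(f$diagnostics[c("r2", "adj_r2", "aicc", "n")],
        list(trS = f$trS, h = f$spec$h, lambda = f$spec$lambda,
             cv_r2 = attr(f, "cv_r2"))))
    jsonlite::write_json(di, p("gtwr_diagnostics.json"), auto_unbox = TRUE,
                         digits = NA)
    emit(p("gtwr_diagnostics.json"))
    for (se in names(res$gtwr_fits)) {
      utils::write.csv(as.data.frame(res$gtwr_fits[[se]]$coefficients),
                       p(paste0("gtwr_coef_", se, ".csv")), row.names = FALSE)
      emit(p(paste0("gtwr_coef_", se, ".csv")))
    }
  }
  if ("neighborhood" %in% stages) {
    utils::write.csv(res$delta_table, p("delta_table.csv"), row.names = FALSE)
    emit(p("delta_table.csv"))
    jsonlite::write_json(delta_report(res$delta_model), p("delta_model.json"),
                         auto_unbox = TRUE, digits = NA)
    emit(p("delta_model.json"))
  }
  if ("mapping" %in% stages) {
    for (se in names(res$maps_seasonal))
      emit(write_raster(res$maps_seasonal[[se]], p(paste0("map_", se, ".asc"))))
    emit(write_raster(res$map_annual, p("map_annual.asc")))
    emit(write_raster(res$delta_map, p("map_delta.asc")))
    emit(write_raster(res$map_final, p("map_final.asc")))
  }
  files <- unique(files)
  manifest <- list(config = unclass(config),
                   params = unclass(res$params),
                   package = as.character(utils::packageVersion("mslur")),
                   stages = PIPELINE_STAGES[idx],
                   files = as.list(tools::md5sum(sort(files))))
  names(manifest$files) <- basename(sort(files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
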