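#' Default pipeline configuration
#'
#' Nested list mirroring the acquisition protocol (Table-1-style), phantom,
#' reconstruction and analysis blocks. Any entry can be overridden from a
#' YAML/JSON file or with `key=value` pairs on the command line.
#'
#' @return Named list of configuration blocks.
#' @export
default_config <- function() {
  list(
    protocol = list(fov_mm = 300, res_mm = 2.3, tr_ms = 11,
                    readout_ms = 5.32, scan_time_s = 4,
                    center_fraction = 0.30, center_density = 2.0,
                    outer_density = 0.6, gmax_mT_m = 26, smax_T_m_s = 45,
                    bw_px = 1116, venc_cm_s = 150),
    phantom = list(rr_mean_ms = 900, rr_cv = 0.04, resp_period_s = 4,
                   resp_amp = 0.08, n_coils = 6, noise_sigma = NULL,
                   maxwell = TRUE, b0_T = 0.55, preset = "default"),
    recon = list(lambda_spatial = 2e-3, lambda_temporal = 1e-2,
                 max_iters = 40, tol = 1e-5, coil_maps = "espirit"),
    analysis = list(peak_velocity_percentile = 1),
    seed = 1234
  )
}

#' Load a pipeline configuration
#'
#' @param path YAML or JSON file (optional).
#' @param overrides Character vector of `block.key=value` overrides.
#' @return Configuration list (defaults filled in).
#' @export
load_config <- function(path = NULL, overrides = character(0)) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file %s not found", path)
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, user)
  }
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("override '%s' is not key=value", ov)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    cfg <- assign_path(cfg, keys, val)
  }
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else base[[nm]] <- new[[nm]]
  }
  base
}

assign_path <- function(cfg, keys, val) {
  if (length(keys) == 1) { cfg[[keys]] <- val; return(cfg) }
  cfg[[keys[1]]] <- assign_path(cfg[[keys[1]]] %||% list(), keys[-1], val)
  cfg
}

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  ## small stable polynomial rolling hash (no digest dependency)
  bytes <- utf8ToInt(as.character(js))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

phantom_from_config <- function(cfg) {
  p <- cfg$phantom; pr <- cfg$protocol
  maker <- if (identical(p$preset, "arrhythmia")) {
    phantom_preset_arrhythmia
  } else phantom_config
  args <- list(fov_mm = pr$fov_mm, res_mm = pr$res_mm,
               rr_mean_ms = p$rr_mean_ms, resp_period_s = p$resp_period_s,
               resp_amp = p$resp_amp, venc_cm_s = pr$venc_cm_s,
               n_coils = p$n_coils, maxwell = isTRUE(p$maxwell),
               b0_T = p$b0_T, scan_time_s = pr$scan_time_s,
               tr_ms = pr$tr_ms, seed = cfg$seed)
  if (!identical(p$preset, "arrhythmia")) args$rr_cv <- p$rr_cv
  if (!is.null(p$noise_sigma)) args$noise_sigma <- p$noise_sigma
  do.call(maker, args)
}

spec_from_config <- function(cfg) {
  pr <- cfg$protocol
  spiral_spec(fov_mm = pr$fov_mm, res_mm = pr$res_mm,
              readout_ms = pr$readout_ms,
              center_fraction = pr$center_fraction,
              center_density = pr$center_density,
              outer_density = pr$outer_density, bw_px = pr$bw_px,
              limits = gradient_limits(pr$gmax_mT_m, pr$smax_T_m_s))
}

pipe_log <- function(out_dir, stage, msg, cfg = NULL) {
  line <- sprintf("%s | %-8s | %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = file.path(out_dir, "pipeline.log"),
      append = TRUE)
}

#' Run pipeline stages
#'
#' Verbs: `simulate` (phantom + undersampled acquisition, writes the k-space
#' bundle and analytic ground truth), `recon` (ESPIRiT maps + CS-SENSE,
#' writes FC/FE NIfTI series), `quantify` (velocimetry + per-beat measures,
#' writes velocity NIfTI, beats CSV and a summary JSON), `report`
#' (agreement statistics of recovered vs ground-truth beats plus the blur
#' metric, writes stats JSON), `run-all` (the full chain). Each verb
#' consumes the previous verb's artifacts from `out_dir` and fails with an
#' actionable message when they are missing.
#'
#' @param verb One of `simulate`, `recon`, `quantify`, `report`, `run-all`.
#' @param config Configuration list from [load_config()].
#' @param out_dir Artifact directory.
#' @return Invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(verb = c("run-all", "simulate", "recon", "quantify",
                                  "report"),
                         config = default_config(), out_dir = "spiralflow_out") {
  verb <- match.arg(verb)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  hash <- config_hash(cfg)
  jsonlite::write_json(c(cfg, list(config_hash = hash)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (verb == "run-all") {
    for (v in c("simulate", "recon", "quantify", "report")) {
      run_pipeline(v, config = cfg, out_dir = out_dir)
    }
    return(invisible(pipeline_paths(out_dir)))
  }
  paths <- pipeline_paths(out_dir)
  t0 <- Sys.time()
  switch(verb,
    simulate = {
      pcfg <- phantom_from_config(cfg)
      spec <- spec_from_config(cfg)
      il <- design_dual_density_spiral(spec)
      sched <- build_schedule(cfg$protocol$scan_time_s, cfg$protocol$tr_ms)
      ks <- simulate_acquisition(sched, pcfg, interleaf = il)
      write_kspace(ks, paths$kspace)
      truth <- ground_truth_measures(pcfg)
      write_beat_csv(truth, paths$truth)
      write_stats_json(list(config_hash = hash, seed = cfg$seed,
                            qp_qs_truth = attr(truth, "qp_qs"),
                            n_full = il$n_full, n_arms = il$n_arms,
                            acceleration_R = acceleration_factor(il, 2)),
                       paths$sim_meta)
      pipe_log(out_dir, "simulate",
               sprintf("wrote %d readouts (config %s, seed %d) in %.1fs",
                       ncol(ks$samples), hash, cfg$seed,
                       as.numeric(Sys.time() - t0, units = "secs")))
    },
    recon = {
      if (!dir.exists(paths$kspace)) {
        stopf("missing k-space bundle %s: run the `simulate` verb first",
              paths$kspace)
      }
      ks <- read_kspace(paths$kspace)
      maps <- if (identical(cfg$recon$coil_maps, "espirit")) {
        estimate_coil_maps(ks)
      } else {
        simulate_coils(ks$header$n_coils, ks$header$matrix, ks$header$fov,
                       seed = ks$header$seed + 1L)
      }
      rp <- recon_params(lambda_spatial = cfg$recon$lambda_spatial,
                         lambda_temporal = cfg$recon$lambda_temporal,
                         max_iters = cfg$recon$max_iters, tol = cfg$recon$tol)
      rec <- cs_sense_reconstruct(ks, maps, rp)
      write_image_series(rec$FC, paths$fc)
      write_image_series(rec$FE, paths$fe)
      pipe_log(out_dir, "recon",
               sprintf("CS-SENSE done (FC %d, FE %d iters) in %.1fs",
                       rec$FC$iters, rec$FE$iters,
                       as.numeric(Sys.time() - t0, units = "secs")))
    },
    quantify = {
      if (!file.exists(paste0(paths$fc, ".json"))) {
        stopf("missing reconstructed series %s: run the `recon` verb first",
              paths$fc)
      }
      ks_header <- jsonlite::read_json(file.path(paths$kspace, "header.json"),
                                       simplifyVector = TRUE)
      fc <- read_image_series(paths$fc)
      fe <- read_image_series(paths$fe)
      dphi <- phase_difference(fc, fe)
      pcfg <- phantom_from_config(cfg)
      if (isTRUE(cfg$phantom$maxwell)) {
        wf <- venc_waveforms(ks_header$venc,
                             gradient_limits(cfg$protocol$gmax_mT_m,
                                             cfg$protocol$smax_T_m_s))
        corrected <- maxwell_correction(dphi$phase, wf, ks_header$fov,
                                        b0_T = cfg$phantom$b0_T)
      } else corrected <- dphi$phase
      vs <- to_velocity(corrected, ks_header$venc, dphi$frame_times_ms %||%
                          fc$frame_times_ms)
      vs$mask_low <- dphi$mask_low
      vs <- unwrap_temporal(vs)
      write_image_series(vs, paths$vel)
      masks <- phantom_masks(pcfg)
      onsets <- phantom_beat_onsets(pcfg)
      px_area <- pcfg$res^2
      all_beats <- list(); summaries <- list()
      for (lbl in names(masks)) {
        roi <- vessel_roi(masks[[lbl]], lbl, px_area)
        curve <- extract_flow_curve(vs, roi)
        beats <- segment_beats(curve, trigger_times_ms = onsets)
        bm <- beat_measures(curve, beats,
                            cfg$analysis$peak_velocity_percentile)
        all_beats[[lbl]] <- bm
        summaries[[lbl]] <- list(
          n_beats = nrow(bm),
          mean = as.list(colMeans(bm[, c("rr_ms", "net_flow_ml",
                                         "peak_flow_ml_s",
                                         "peak_velocity_cm_s")])),
          cv_pct = lapply(bm[, c("rr_ms", "net_flow_ml", "peak_flow_ml_s",
                                 "peak_velocity_cm_s")],
                          function(x) if (length(x) >= 2)
                            coefficient_of_variation(x) else NA_real_))
      }
      bm_all <- dplyr::bind_rows(all_beats)
      write_beat_csv(bm_all, paths$beats)
      qpqs <- if (all(c("AO", "MPA") %in% names(summaries))) {
        qp_qs(summaries$MPA$mean$net_flow_ml, summaries$AO$mean$net_flow_ml)
      } else NA_real_
      write_stats_json(list(config_hash = hash, seed = cfg$seed,
                            vessels = summaries, qp_qs = qpqs),
                       paths$summary)
      pipe_log(out_dir, "quantify",
               sprintf("quantified %d beats, Qp/Qs %.3f in %.1fs",
                       nrow(bm_all), qpqs,
                       as.numeric(Sys.time() - t0, units = "secs")))
    },
    report = {
      if (!file.exists(paths$beats)) {
        stopf("missing beat table %s: run the `quantify` verb first",
              paths$beats)
      }
      meas <- utils::read.csv(paths$beats)
      truth <- utils::read.csv(paths$truth)
      fc <- read_image_series(paths$fc)
      stats <- list(config_hash = hash, seed = cfg$seed)
      for (lbl in unique(meas$vessel)) {
        m <- meas[meas$vessel == lbl, ]
        tr <- truth[truth$vessel == lbl, ]
        nb <- min(nrow(m), nrow(tr))
        if (nb >= 3) {
          per_param <- lapply(c(net_flow = "net_flow_ml",
                                peak_flow = "peak_flow_ml_s",
                                peak_velocity = "peak_velocity_cm_s"),
                              function(colnm) {
            gl <- glance(agreement_summary(m[[colnm]][seq_len(nb)],
                                           tr[[colnm]][seq_len(nb)]))
            as.list(gl)
          })
          stats[[lbl]] <- per_param
        } else {
          stats[[lbl]] <- list(note = sprintf(
            "only %d paired beats; agreement statistics need >= 3", nb))
        }
      }
      tavg <- apply(Mod(fc$frames), c(1, 2), mean)
      stats$blur_metric <- blur_metric(tavg)
      write_stats_json(stats, paths$stats)
      txt <- utils::capture.output(utils::str(stats, max.level = 3))
      writeLines(txt, paths$stats_txt)
      pipe_log(out_dir, "report",
               sprintf("report written (blur %.3f) in %.1fs",
                       stats$blur_metric,
                       as.numeric(Sys.time() - t0, units = "secs")))
    })
  invisible(paths)
}

pipeline_paths <- function(out_dir) {
  list(kspace = file.path(out_dir, "kspace"),
       truth = file.path(out_dir, "truth_beats.csv"),
       sim_meta = file.path(out_dir, "simulate.json"),
       fc = file.path(out_dir, "recon_fc"),
       fe = file.path(out_dir, "recon_fe"),
       vel = file.path(out_dir, "velocity"),
       beats = file.path(out_dir, "beats.csv"),
       summary = file.path(out_dir, "summary.json"),
       stats = file.path(out_dir, "stats.json"),
       stats_txt = file.path(out_dir, "stats.txt"))
}
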