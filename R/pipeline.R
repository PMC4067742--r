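#' Demonstration pipeline configuration
#'
#' A two-condition synthetic study emulating the structure of the live-cell
#' experiments: a 40-residue-like peptide condition (lagged lifetime
#' kinetics, spherical aggregates of 160 nm) against a 42-residue-like
#' condition (no lag, 225 nm elongated aggregates), plus a two-region FLIM
#' image (monomer 3.7 ns / fibril 3.3 ns). Sized to run in seconds while
#' exercising every stage.
#'
#' @param seed Integer seed for all stage randomness.
#' @param out_dir Output directory.
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("flimstorm_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("simulate", "flim", "storm", "morph", "kinetics"),
    flim = list(
      image_size = 12L, tau_regions = c(3.7, 3.3), n_photons = 4200,
      amplitude_fraction = 0.95,
      irf = list(fwhm = 0.2, n_channels = 128L, window = 25),
      target_min = 3500, target_max = 5000, max_factor = 3L
    ),
    storm = list(
      conditions = list(
        list(name = "ab40_24h", kind = "sphere", size = 160),
        list(name = "ab42_24h", kind = "rod", size = 225)
      ),
      n_fluorophores = 250L, n_frames = 1200L,
      photons_mean = 2000, on_probability = 0.002,
      camera = list(pixel_size = 100, psf_sigma = 150, background_rate = 2,
                    read_noise_sd = 0),
      bin_nm = 10, min_count = 2L, resolution_nm = 55
    ),
    kinetics = list(
      conditions = list(
        list(name = "ab40", L0 = 3.7, Linf = 3.35, k = 2.0, t50 = 3.5),
        list(name = "ab42", L0 = 3.7, Linf = 3.31, k = 2.0, t50 = 0.6)
      ),
      times = seq(0, 8, by = 0.5), noise_sd = 0.03, replicate_sd = 0.1,
      n_replicates = 6L
    )
  )
}

validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or YAML path",
                              class = "flimstorm_config_error")
  if (is.null(config$seed) || !is.numeric(config$seed))
    stopf("config$seed (integer) is required", class = "flimstorm_config_error")
  if (is.null(config$out_dir))
    stopf("config$out_dir is required", class = "flimstorm_config_error")
  known <- c("simulate", "flim", "storm", "morph", "kinetics")
  config$stages <- config$stages %||% known
  bad <- setdiff(config$stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "),
                         class = "flimstorm_config_error")
  needs_sim <- intersect(c("flim", "storm", "morph", "kinetics"), config$stages)
  if (length(needs_sim) && !"simulate" %in% config$stages)
    stopf("analysis stages require the simulate stage (no external inputs configured)",
          class = "flimstorm_config_error")
  blocks <- unique(sub("^morph$", "storm", intersect(c("flim", "storm", "morph", "kinetics"),
                                                     config$stages)))
  for (block in blocks)
    if (is.null(config[[block]]))
      stopf("config$%s block is required", block, class = "flimstorm_config_error")
  config
}

md5_of <- function(paths) unname(tools::md5sum(paths))

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the requested stages in order — `simulate` (write all synthetic
#' inputs), `flim` (lifetime map + summaries), `storm` (localization +
#' rendering), `morph` (segmentation, sizing, resolution filter), `kinetics`
#' (sigmoid fits, lag times, endpoint statistics) — and writes a JSON run
#' manifest with the seed, parameter hash, per-stage outputs and their MD5
#' checksums, sufficient to reproduce the run bit-for-bit.
#'
#' @param config Config list (see [demo_config()]) or path to a YAML file.
#' @return The manifest, invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(seed = config$seed, config = cfg_path,
                   config_md5 = md5_of(cfg_path), stages = list())
  outputs <- character(0)
  log <- function(...) message("[flimstorm] ", sprintf(...))
  od <- config$out_dir
  set.seed(config$seed)
  state <- new.env()

  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error"))
      stopf("stage '%s' failed: %s", name, conditionMessage(res),
            class = "flimstorm_stage_error")
    manifest$stages[[name]] <<- res
  }

  if ("simulate" %in% config$stages) run_stage("simulate", function() {
    out <- list()
    if (!is.null(config$flim)) {
      fc <- config$flim
      the_irf <- simulate_irf(fc$irf$fwhm, fc$irf$n_channels, fc$irf$window)
      n <- fc$image_size
      tau <- matrix(fc$tau_regions[1L], n, n)
      tau[, (n %/% 2 + 1L):n] <- fc$tau_regions[2L]
      cube <- simulate_tcspc_image(
        decay_truth_map(tau, fc$n_photons, fc$amplitude_fraction), the_irf)
      write_decay_cube(cube, file.path(od, "tcspc_cube.tif"))
      write_irf_csv(the_irf, file.path(od, "irf.csv"))
      utils::write.csv(data.frame(row = rep(seq_len(n), n),
                                  col = rep(seq_len(n), each = n),
                                  tau_true = as.vector(tau)),
                       file.path(od, "tcspc_truth.csv"), row.names = FALSE)
      state$irf <- the_irf; state$tau_true <- tau
      out$tcspc <- c("tcspc_cube.tif", "irf.csv", "tcspc_truth.csv")
      log("simulate: TCSPC cube %dx%d, %d photons/pixel", n, n, fc$n_photons)
    }
    if (!is.null(config$storm)) {
      sc <- config$storm
      cam <- do.call(camera_model, sc$camera)
      state$camera <- cam
      n_agg <- sc$n_aggregates %||% 3L
      centres <- list(c(7, 7), c(17, 8), c(11, 17), c(18, 18), c(6, 16))
      for (cond in sc$conditions) {
        sets <- lapply(seq_len(n_agg), function(k)
          simulate_aggregate_emitters(
            cond$kind, cond$size, sc$n_fluorophores,
            center = centres[[k]] * cam$pixel_size, shape_label = k,
            photons_mean = sc$photons_mean,
            on_probability = sc$on_probability))
        em <- do.call(combine_emitters, sets)
        mv <- simulate_blinking_movie(em, cam, sc$n_frames, fov = c(24L, 24L))
        write_movie(mv, file.path(od, paste0("movie_", cond$name, ".tif")))
        utils::write.csv(as.data.frame(em),
                         file.path(od, paste0("emitters_", cond$name, ".csv")),
                         row.names = FALSE)
        out$movies <- c(out$movies, paste0("movie_", cond$name, ".tif"))
        log("simulate: movie '%s' (%s, %g nm), %d frames", cond$name,
            cond$kind, cond$size, sc$n_frames)
      }
    }
    if (!is.null(config$kinetics)) {
      kc <- config$kinetics
      rep_sd <- kc$replicate_sd %||% 0
      for (cond in kc$conditions) {
        truth <- sigmoid_params(cond$L0, cond$Linf, cond$k, cond$t50)
        for (r in seq_len(kc$n_replicates)) {
          tr <- simulate_lifetime_timecourse(truth, kc$times, kc$noise_sd)
          # image-to-image variability: a common offset per replicate trace
          if (rep_sd > 0) tr$value <- tr$value + stats::rnorm(1L, 0, rep_sd)
          write_trace_csv(tr, file.path(od, sprintf("trace_%s_rep%d.csv",
                                                    cond$name, r)))
        }
        out$traces <- c(out$traces,
                        sprintf("trace_%s_rep%d.csv", cond$name,
                                seq_len(kc$n_replicates)))
      }
      log("simulate: %d kinetic conditions x %d replicates",
          length(kc$conditions), kc$n_replicates)
    }
    out
  })

  if ("flim" %in% config$stages) run_stage("flim", function() {
    fc <- config$flim
    cube <- read_decay_cube(file.path(od, "tcspc_cube.tif"))
    the_irf <- read_irf_csv(file.path(od, "irf.csv"))
    map <- fit_lifetime_map(cube, the_irf,
                            mask = matrix(TRUE, dim(cube)[1L], dim(cube)[2L]),
                            target_min = fc$target_min,
                            target_max = fc$target_max,
                            max_factor = fc$max_factor)
    write_lifetime_map(map, file.path(od, "lifetime_map.tif"))
    n <- dim(cube)[2L]
    left <- col(map$tau) <= n %/% 2
    s1 <- region_mean_lifetime(map, left, "monomer_like")
    s2 <- region_mean_lifetime(map, !left, "fibril_like")
    summ <- data.frame(region = c(s1$region_label, s2$region_label),
                       mean_tau_ns = c(s1$mean_tau, s2$mean_tau),
                       sem_tau_ns = c(s1$sem_tau, s2$sem_tau))
    utils::write.csv(summ, file.path(od, "lifetime_summary.csv"),
                     row.names = FALSE)
    log("flim: binning %d, region means %.3f / %.3f ns", map$binning_factor,
        s1$mean_tau, s2$mean_tau)
    list(outputs = c("lifetime_map.tif", "lifetime_map.tif.csv",
                     "lifetime_summary.csv"),
         binning_factor = map$binning_factor,
         n_converged = sum(map$converged),
         region_means = summ$mean_tau_ns)
  })

  if ("storm" %in% config$stages) run_stage("storm", function() {
    sc <- config$storm
    res <- list(outputs = character(0), n_localizations = integer(0))
    for (cond in sc$conditions) {
      mv <- read_movie(file.path(od, paste0("movie_", cond$name, ".tif")))
      tab <- localize_stack(mv)
      write_localizations_csv(tab, file.path(od, paste0("locs_", cond$name, ".csv")))
      sr <- render_density(tab, sc$bin_nm)
      write_sr_image(sr, file.path(od, paste0("sr_", cond$name, ".tif")))
      res$outputs <- c(res$outputs, paste0("locs_", cond$name, ".csv"),
                       paste0("sr_", cond$name, ".tif"))
      res$n_localizations[cond$name] <- nrow(tab)
      log("storm: '%s' %d localizations", cond$name, nrow(tab))
    }
    res
  })

  if ("morph" %in% config$stages) run_stage("morph", function() {
    sc <- config$storm
    recs <- list()
    for (cond in sc$conditions) {
      sr <- read_sr_image(file.path(od, paste0("sr_", cond$name, ".tif")))
      tab <- read_localizations_csv(file.path(od, paste0("locs_", cond$name, ".csv")),
                                    pixel_size = sc$camera$pixel_size)
      reso <- sc$resolution_nm %||% as.numeric(estimate_resolution(tab, sr))
      r <- measure_aggregates(sr, sc$min_count, condition = cond$name)
      recs[[cond$name]] <- filter_by_resolution(r, reso, keep_only = FALSE)
    }
    all_recs <- do.call(rbind, recs)
    utils::write.csv(as.data.frame(all_recs), file.path(od, "aggregates.csv"),
                     row.names = FALSE)
    summ <- summarize_sizes(all_recs)
    utils::write.csv(as.data.frame(summ), file.path(od, "size_summary.csv"),
                     row.names = FALSE)
    log("morph: %d aggregates, %d conditions", nrow(all_recs), nrow(summ))
    list(outputs = c("aggregates.csv", "size_summary.csv"),
         mean_sizes = stats::setNames(summ$mean_size, summ$condition))
  })

  if ("kinetics" %in% config$stages) run_stage("kinetics", function() {
    kc <- config$kinetics
    lag_rows <- list()
    endpoints <- list()
    for (cond in kc$conditions) {
      lags <- t50s <- ends <- numeric(kc$n_replicates)
      for (r in seq_len(kc$n_replicates)) {
        tr <- read_trace_csv(file.path(od, sprintf("trace_%s_rep%d.csv",
                                                   cond$name, r)))
        fit <- fit_sigmoid(tr)
        lags[r] <- lag_time(fit); t50s[r] <- fit$t50
        ends[r] <- fit$Linf
      }
      lag_rows[[cond$name]] <- data.frame(condition = cond$name,
                                          lag_hr = stats::median(lags),
                                          t50_hr = stats::median(t50s),
                                          n = kc$n_replicates)
      endpoints[[cond$name]] <- ends
    }
    lag_df <- do.call(rbind, lag_rows)
    utils::write.csv(lag_df, file.path(od, "lag_times.csv"), row.names = FALSE)
    st <- paired_t_test(endpoints[[1L]], endpoints[[2L]],
                        comparison = paste(names(endpoints)[1:2], collapse = " vs "))
    write_stats_csv(st, file.path(od, "endpoint_stats.csv"))
    log("kinetics: lags %s hr; endpoint p = %.3g",
        paste(sprintf("%.2f", lag_df$lag_hr), collapse = " / "), st$p_value)
    list(outputs = c("lag_times.csv", "endpoint_stats.csv"),
         lag_hr = stats::setNames(lag_df$lag_hr, lag_df$condition),
         endpoint_p = st$p_value)
  })

  files <- setdiff(list.files(od, recursive = TRUE), "manifest.json")
  manifest$outputs <- data.frame(
    file = files, md5 = md5_of(file.path(od, files)), row.names = NULL)
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
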