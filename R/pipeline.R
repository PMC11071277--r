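#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with every field
#' at its default; supplied values (possibly nested) override defaults.
#' Mirrors the command-line flags one to one.
#'
#' @param ... Named overrides, e.g. `phantom = list(dims = c(64, 64, 64))`.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    outdir = ".",
    input_volume = NULL,           # path; skips the simulate stage
    phantom = list(kind = "spheres", dims = c(64L, 64L, 64L), n_objects = 8L,
                   diameter_range = c(8, 24), hollow = TRUE,
                   shell_thickness = 2, density = 1, lowpass_cutoff = 0.25),
    geometry = list(alpha = 2, beta = 60, angles_file = NULL),
    network = list(hidden_layers = 4L, width = 32L, pe_frequencies = 6L,
                   omega0 = 30),
    train = list(iters_first = 500L, iters_rest = 100L,
                 lr_first = c(1e-3, 1e-4), lr_rest = c(1e-4, 1e-5),
                 lambda = 0, regularizer = "none"),
    ratio = 1 / 8,
    slab_width = NULL,
    single_network = FALSE,
    methods = c("cn", "wbp"),
    wbp_filter = "ramp",
    evaluate = TRUE,
    register = TRUE,
    verbose = TRUE
  )
  modifyList(cfg, list(...))
}

read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full simulate-project-reconstruct-evaluate pipeline
#'
#' Executes, as configured: phantom simulation (or loading a ground-truth
#' volume), forward projection, \[0, 1\] normalization, coordinate-network
#' and/or WBP reconstruction, and reference-based evaluation. All artifacts
#' (volumes as MRC, angles as `.tlt`, FSC tables as TSV) plus a JSON run
#' manifest (config snapshot, seed, angles, per-stage timings, per-slab
#' final losses, metrics) are written under `config$outdir`.
#'
#' @param config A configuration list from [pipeline_config()], or a path to
#'   a YAML file with the same structure.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("cntomo")),
                   config = config, seed = config$seed, timings = list())
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    r
  }
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  # ground truth
  v_star <- timed("simulate", {
    if (!is.null(config$input_volume)) {
      say("reading ground-truth volume %s", config$input_volume)
      read_volume(config$input_volume)
    } else {
      say("simulating %s phantom %s", config$phantom$kind,
          paste(config$phantom$dims, collapse = "x"))
      ph <- config$phantom
      recipe <- phantom_recipe(kind = ph$kind, dims = ph$dims,
                               n_objects = ph$n_objects,
                               diameter_range = ph$diameter_range,
                               hollow = ph$hollow %||% TRUE,
                               shell_thickness = ph$shell_thickness %||% 2,
                               density = ph$density %||% 1,
                               lowpass_cutoff = ph$lowpass_cutoff,
                               seed = config$seed)
      simulate_phantom(recipe)
    }
  })
  dims <- dim(v_star)
  write_mrc(v_star, out("ground_truth.mrc"))

  geometry <- if (!is.null(config$geometry$angles_file)) {
    read_angles(config$geometry$angles_file)
  } else {
    angles_from_params(config$geometry$alpha, config$geometry$beta)
  }
  manifest$angles <- geometry$angles

  p <- timed("project", {
    say("projecting at %d tilt angles", geometry$n_tilts)
    normalize_series(project(v_star, geometry))
  })
  write_tilt_series(p, out("tilt_series.mrc"), out("angles.tlt"))

  spec <- do.call(network_spec, config$network)
  plan <- do.call(train_plan, c(config$train, list(seed = config$seed)))
  recons <- list()
  if ("cn" %in% config$methods) {
    recons$cn <- timed("reconstruct_cn", {
      say("coordinate-network reconstruction")
      cn_reconstruct(p, nz = dims[3], spec = spec, plan = plan,
                     ratio = config$ratio, slab_width = config$slab_width,
                     single_network = isTRUE(config$single_network),
                     verbose = isTRUE(config$verbose))
    })
    write_mrc(recons$cn, out("recon_cn.mrc"))
    manifest$slab_losses <- attr(recons$cn, "fit_summary")$final_loss
  }
  if ("wbp" %in% config$methods) {
    recons$wbp <- timed("reconstruct_wbp", {
      say("weighted back-projection baseline")
      wbp_reconstruct(p, nz = dims[3], filter = config$wbp_filter)
    })
    write_mrc(recons$wbp, out("recon_wbp.mrc"))
  }

  if (isTRUE(config$evaluate) && length(recons)) {
    manifest$metrics <- timed("evaluate", {
      lapply(recons, function(v) {
        r <- metrics_report(v, v_star, geometry = geometry,
                            register = isTRUE(config$register))
        list(psnr = r$psnr, ssim = r$ssim, vif = r$vif,
             fsc_full_mean = mean(r$fsc_full$correlation, na.rm = TRUE),
             fsc_missing_mean = mean(r$fsc_missing$correlation, na.rm = TRUE))
      })
    })
    for (m in names(recons)) {
      r <- metrics_report(recons[[m]], v_star, geometry = geometry,
                          register = isTRUE(config$register))
      write_fsc_table(r, out(sprintf("fsc_%s.tsv", m)))
    }
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Acquisition-parameter sweep
#'
#' Re-runs the full pipeline over lists of angular steps (at the base range)
#' and angular ranges (at the base step), collecting the voxel-based metrics
#' per condition — the standard experiment for judging how a method degrades
#' as tilt sampling coarsens or the wedge widens.
#'
#' @param alphas Angular steps to sweep (degrees); each must divide the base
#'   range.
#' @param betas Half-ranges to sweep (degrees).
#' @param config Base [pipeline_config()]; each condition writes into a
#'   subdirectory of `config$outdir`.
#' @return Data frame: one row per (method, condition) with PSNR/SSIM/VIF and
#'   mean full/missing FSC.
#' @export
sweep_acquisition <- function(alphas = NULL, betas = NULL,
                              config = pipeline_config()) {
  conditions <- rbind(
    if (length(alphas)) data.frame(alpha = alphas, beta = config$geometry$beta),
    if (length(betas)) data.frame(alpha = config$geometry$alpha, beta = betas)
  )
  if (is.null(conditions) || !nrow(conditions)) stop("nothing to sweep")
  conditions <- unique(conditions)
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    cfg <- config
    cfg$geometry$alpha <- conditions$alpha[i]
    cfg$geometry$beta <- conditions$beta[i]
    cfg$outdir <- file.path(config$outdir,
                            sprintf("alpha%g_beta%g", cfg$geometry$alpha,
                                    cfg$geometry$beta))
    man <- run_pipeline(cfg)
    for (m in names(man$metrics)) {
      rows[[length(rows) + 1L]] <-
        data.frame(method = m, alpha = cfg$geometry$alpha,
                   beta = cfg$geometry$beta,
                   psnr = man$metrics[[m]]$psnr,
                   ssim = man$metrics[[m]]$ssim,
                   vif = man$metrics[[m]]$vif,
                   fsc_full_mean = man$metrics[[m]]$fsc_full_mean,
                   fsc_missing_mean = man$metrics[[m]]$fsc_missing_mean)
    }
  }
  res <- do.call(rbind, rows)
  utils::write.table(res, file.path(config$outdir, "sweep.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  res
}
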