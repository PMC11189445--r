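#' Run a configured analysis pipeline
#'
#' Executes a YAML-configured sequence of analysis stages with full
#' reproducibility metadata: every output file records the configuration
#' hash, the global seed and the package version, and a manifest of
#' outputs is written at the end.  Stage failures leave completed outputs
#' intact and are listed in the manifest.
#'
#' Supported stages and their parameters:
#'
#' * `simulate` - Brownian ion traces ([simulate_ion_langevin()]);
#'   any [langevin_spec()] field; writes `traces.tsv` +
#'   `simulate_summary.json`.
#' * `profile` - pore-radius profile ([compute_profile()]); `structure`
#'   (path), `gate`, `filter`, `step`, `radius_set`, `gate_residues`;
#'   writes `profile.tsv` + `constrictions.json`.
#' * `permeation` - event counting ([detect_events()],
#'   [estimate_conductance()]); `traces` (path or `from: simulate`),
#'   `upper`, `lower`, `hysteresis`, `duration`, `voltage`,
#'   `domain_length`; writes `events.tsv` + `conductance.json`.
#' * `pmf` - Boltzmann inversion ([ion_density_profile()],
#'   [pmf_from_density()]); `traces`, `z_min`, `z_max`, `bin`,
#'   `reference`; writes `pmf.tsv`.
#' * `hydration` - [hydration_profile()]; `structure`, `gate`, `filter`,
#'   `cylinder_radius`; writes `hydration.tsv`.
#' * `gv` - Boltzmann fit ([fit_boltzmann()]); `input` TSV
#'   (`voltage_mV<TAB>g_norm`); writes `gv_fit.json`.
#' * `conform` - superposition of two structures ([superpose_kabsch()]);
#'   `mobile`, `reference`, `selection`; writes `superpose.json`.
#'
#' @param config Path to a YAML config file, or an equivalent list with
#'   fields `seed`, `output_dir` and `stages` (list of stage blocks, each
#'   with a `stage` name and parameters).
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  seed <- cfg$seed %||% 1L
  meta <- list(config_hash = cfg_hash, seed = seed,
               version = as.character(utils::packageVersion("porekinetics")))
  manifest <- list(config_hash = cfg_hash, seed = seed, outputs = list(),
                   failures = list())
  state <- new.env(parent = emptyenv())
  for (i in seq_along(cfg$stages)) {
    blk <- cfg$stages[[i]]
    res <- tryCatch({
      set.seed(seed + i)
      run_stage(blk$stage, blk, out_dir, meta, state)
    }, error = function(e) {
      message("stage ", blk$stage, " failed: ", conditionMessage(e))
      structure(conditionMessage(e), class = "stage_failure")
    })
    if (inherits(res, "stage_failure")) {
      manifest$failures[[blk$stage]] <- unclass(res)
    } else {
      manifest$outputs <- c(manifest$outputs, res)
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list or YAML file")
  if (is.null(cfg$output_dir)) stop("config validation: 'output_dir' is required")
  if (is.null(cfg$stages) || !length(cfg$stages))
    stop("config validation: 'stages' must be a non-empty list")
  known <- c("simulate", "profile", "permeation", "pmf", "hydration",
             "gv", "conform")
  for (blk in cfg$stages) {
    if (is.null(blk$stage)) stop("config validation: every stage block needs 'stage'")
    if (!blk$stage %in% known)
      stop("config validation: unknown stage '", blk$stage, "' (known: ",
           paste(known, collapse = ", "), ")")
  }
  invisible(TRUE)
}

## TSV writer with a metadata comment header (hash, seed, version).
write_tsv_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%s version=%s",
                     meta$config_hash, meta$seed, meta$version), con)
  ## fixed formatting for byte-stable reruns
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.9g", x))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json_meta <- function(x, path, meta) {
  jsonlite::write_json(c(x, list(meta = meta)), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  path
}

run_stage <- function(stage, p, out_dir, meta, state) {
  switch(stage,
    simulate = {
      spec_args <- p[intersect(names(p),
        c("n_ions", "duration", "dt", "diffusion_D", "voltage",
          "membrane_span", "domain_length", "temperature", "seed"))]
      spec <- do.call(langevin_spec, lapply(spec_args, unlist))
      sim <- simulate_ion_langevin(spec)
      state$sim <- sim
      tp <- file.path(out_dir, "traces.tsv")
      write_ion_traces(sim$traces, tp)
      jp <- write_json_meta(list(
        expected_crossings_per_ion = sim$expected_crossings_per_ion,
        spec = sim$spec[c("n_ions", "duration", "voltage", "domain_length")]),
        file.path(out_dir, "simulate_summary.json"), meta)
      list(traces = tp, simulate_summary = jp)
    },
    profile = {
      model <- read_structure(p$structure)
      model <- assign_radii(model, radius_set(p$radius_set %||% "simple"),
                            exclude = "water")
      fr <- build_pore_frame(model,
        gate_expr = p$gate %||% "resid 394-398 and heavy",
        filter_expr = p$filter %||% "resid 358-361 and heavy")
      prof <- compute_profile(model, fr, step = p$step %||% 0.25)
      tp <- write_tsv_meta(as.data.frame(prof), file.path(out_dir, "profile.tsv"),
                           meta)
      summ <- list(min_radius = min(prof$radius[prof$converged]),
                   min_diameter = 2 * min(prof$radius[prof$converged]),
                   radius_set = attr(prof, "radius_set"),
                   step = attr(prof, "step"))
      if (!is.null(p$gate_residues)) {
        gm <- gate_metrics(prof, model, fr, unlist(p$gate_residues))
        summ$gate_diameters <- setNames(as.list(gm$diameter),
                                        paste0("resid_", gm$resid))
      }
      jp <- write_json_meta(summ, file.path(out_dir, "constrictions.json"), meta)
      list(profile = tp, constrictions = jp)
    },
    permeation = {
      traces <- stage_traces(p, state)
      ev <- detect_events(traces,
                          upper_gate_z = p$upper %||% 18,
                          lower_gate_z = p$lower %||% -18,
                          hysteresis = p$hysteresis %||% 2,
                          domain_length = p$domain_length)
      tp <- write_tsv_meta(ev, file.path(out_dir, "events.tsv"), meta)
      est <- estimate_conductance(nrow(ev), duration = p$duration %||% 500,
                                  voltage = p$voltage %||% -500)
      jp <- write_json_meta(list(
        n_events = nrow(ev), g_mean_pS = est$g_mean,
        g_spread_pS = est$g_spread,
        spread_convention = est$spread_convention,
        thresholds = list(upper = p$upper %||% 18, lower = p$lower %||% -18,
                          hysteresis = p$hysteresis %||% 2)),
        file.path(out_dir, "conductance.json"), meta)
      list(events = tp, conductance = jp)
    },
    pmf = {
      traces <- stage_traces(p, state)
      br <- seq(p$z_min %||% -40, p$z_max %||% 40, by = p$bin %||% 1)
      dens <- ion_density_profile(traces, br, radial_cutoff = Inf)
      ref <- unlist(p$reference %||% c(br[1], br[1] + 5))
      pmf <- pmf_from_density(dens, reference_window = ref)
      tp <- write_tsv_meta(as.data.frame(pmf), file.path(out_dir, "pmf.tsv"), meta)
      list(pmf = tp)
    },
    hydration = {
      model <- read_structure(p$structure)
      fr <- build_pore_frame(model,
        gate_expr = p$gate %||% "resid 394-398 and heavy",
        filter_expr = p$filter %||% "resid 358-361 and heavy")
      hp <- hydration_profile(model, fr,
                              cylinder_radius = p$cylinder_radius %||% 12)
      tp <- write_tsv_meta(as.data.frame(hp), file.path(out_dir, "hydration.tsv"),
                           meta)
      list(hydration = tp)
    },
    gv = {
      tab <- read.delim(p$input)
      names(tab) <- c("voltage", "g_norm")
      fit <- fit_boltzmann(tab)
      jp <- write_json_meta(list(v_half_mV = unname(coef(fit)[["v_half"]]),
                                 k_mV = unname(coef(fit)[["k"]]),
                                 sse = fit$residual_sse),
                            file.path(out_dir, "gv_fit.json"), meta)
      list(gv_fit = jp)
    },
    conform = {
      ma <- read_structure(p$reference)
      mb <- read_structure(p$mobile)
      sup <- superpose_kabsch(mb, ma, p$selection %||% "name CA")
      jp <- write_json_meta(list(rmsd = sup$rmsd, n_pairs = sup$n_pairs,
                                 rotation = sup$rotation,
                                 translation = sup$translation),
                            file.path(out_dir, "superpose.json"), meta)
      list(superpose = jp)
    },
    stop("unknown stage: ", stage))
}

stage_traces <- function(p, state) {
  if (!is.null(p$traces) && identical(p$traces, "from:simulate")) {
    if (is.null(state$sim)) stop("no simulate stage ran before this stage")
    state$sim$traces
  } else if (!is.null(p$traces)) {
    read_ion_traces(p$traces)
  } else stop("stage needs 'traces'")
}
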