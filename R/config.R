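# Schema of known configuration keys per command; unknown keys are rejected.
config_schema <- function() {
  common <- list(seed = 1L, outdir = ".", log_level = "INFO")
  list(
    generate = c(common, list(
      n_frames = 2000L, alpha_fraction = 0.5, noise_sd = 0.3,
      write_pdb = FALSE)),
    states = c(common, list(
      input = NULL, n_vectors = 3L,
      thresholds = list(pY = 10, sheet = 8, plus5 = 9.5))),
    cluster = c(common, list(
      input = NULL, n_windows = 10L, window_lo = NULL, window_hi = NULL)),
    wham = c(common, list(
      windows = NULL, bins = 200L, tolerance = 1e-4, max_iter = 100000L,
      n_boot = 100L)),
    cft = c(common, list(
      work = NULL, n_boot = 200L, tolerance = 1e-6)),
    temper = c(common, list(
      potential = list(kind = "double_well", h = 10, a = 0.5),
      ladder = "sheet_opening", pull_k = 1000, velocity = 0.05,
      ref_start = -0.5, ref_end = 0.5, n_per_direction = 20L,
      friction = 10, dt = 0.002))
  )
}

#' Parse and validate a run configuration
#'
#' Reads a YAML configuration with a top-level `command` field plus the
#' command's parameter block, fills in documented defaults, rejects unknown
#' keys, and (when `write_resolved = TRUE`) writes the fully-resolved copy
#' beside the outputs so every run is reproducible from its artefacts.
#'
#' @param path Path to a YAML configuration file.
#' @param write_resolved Write `<outdir>/resolved_config.yaml`.
#' @return Object of class `run_config`: the resolved parameter list with
#'   fields `command`, `params`, and `hash` (digest of the resolved
#'   configuration embedded in output artefacts).
#' @export
parse_config <- function(path, write_resolved = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$command)) {
    stop("config is missing the required 'command' field", call. = FALSE)
  }
  schema <- config_schema()
  if (!raw$command %in% names(schema)) {
    stop(sprintf("unknown command '%s' (known: %s)", raw$command,
                 paste(names(schema), collapse = ", ")), call. = FALSE)
  }
  defaults <- schema[[raw$command]]
  given <- raw[setdiff(names(raw), "command")]
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s) for command '%s': %s", raw$command,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  params <- utils::modifyList(defaults, given)
  required <- names(defaults)[vapply(defaults, is.null, logical(1))]
  missing <- required[vapply(params[required], is.null, logical(1))]
  if (length(missing) > 0L) {
    stop(sprintf("missing required config field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(params$seed) || params$seed <= 0 ||
        params$seed != round(params$seed)) {
    stop("seed must be a positive integer", call. = FALSE)
  }
  resolved <- c(list(command = raw$command), params)
  hash <- config_hash(resolved)
  if (write_resolved) {
    dir.create(params$outdir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(c(resolved, list(config_hash = hash)),
                     file.path(params$outdir, "resolved_config.yaml"))
  }
  structure(list(command = raw$command, params = params, hash = hash),
            class = "run_config")
}

# Deterministic hash of the resolved configuration (polynomial rolling hash
# over its YAML rendering; provenance marker, not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(yaml::as.yaml(x))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

run_log <- function(params, msg, level = "INFO") {
  line <- sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  if (identical(params$log_level, "DEBUG") || level != "DEBUG") {
    message(line)
    logf <- file.path(params$outdir, "run.log")
    if (dir.exists(params$outdir)) cat(line, "\n", file = logf, append = TRUE)
  }
  invisible(line)
}

#' Execute a configured pipeline run
#'
#' Dispatches on `config$command`:
#' * `generate` — synthetic two-state fixtures (frame table, labels, PDB),
#' * `states` — superpose, PCA, subvectors, order parameters, correlations,
#'   classification report,
#' * `cluster` — pull-trace windowing with per-window cutoff + GROMOS
#'   clustering seeds,
#' * `wham` — profile + Bayesian bootstrap from window tables,
#' * `cft` — BAR + crossing estimates with bootstrap errors from a work
#'   table,
#' * `temper` — tempered pulling producing a forward/reverse work set.
#' Every run writes a JSON record embedding the resolved-config hash, the
#' seeds and the package version.
#'
#' @param config A [parse_config()] result.
#' @return List of output paths, invisibly; errors propagate with the stage
#'   name prefixed.
#' @export
run_command <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  dir.create(p$outdir, showWarnings = FALSE, recursive = TRUE)
  record <- list(command = config$command, config_hash = config$hash,
                 seed = p$seed,
                 package_version = as.character(utils::packageVersion("sh2states")))
  out <- tryCatch(
    switch(config$command,
      generate = cmd_generate(p),
      states = cmd_states(p),
      cluster = cmd_cluster(p),
      wham = cmd_wham(p),
      cft = cmd_cft(p),
      temper = cmd_temper(p)),
    error = function(e) {
      stop(sprintf("stage '%s' failed: %s", config$command,
                   conditionMessage(e)), call. = FALSE)
    })
  record$outputs <- out$outputs
  record$results <- out$results
  rec_path <- file.path(p$outdir, sprintf("%s_record.json", config$command))
  jsonlite::write_json(record, rec_path, auto_unbox = TRUE, digits = NA)
  run_log(p, sprintf("command '%s' complete; record at %s",
                     config$command, rec_path))
  invisible(c(out$outputs, record = rec_path))
}

cmd_generate <- function(p) {
  run_log(p, sprintf("generating two-state ensemble (n=%d, alpha=%g, noise=%g A, seed=%d)",
                     p$n_frames, p$alpha_fraction, p$noise_sd, p$seed))
  gen <- build_two_state_ensemble(p$n_frames, p$alpha_fraction,
                                  noise_sd = p$noise_sd, seed = p$seed)
  ft <- file.path(p$outdir, "ensemble_frames.dat")
  write_frame_table(gen$ensemble, ft)
  lab <- file.path(p$outdir, "true_labels.dat")
  writeLines(c("# frame true_label",
               sprintf("%d %s", seq_along(gen$labels), gen$labels)), lab)
  outs <- c(frames = ft, labels = lab)
  if (isTRUE(p$write_pdb)) {
    pdb <- file.path(p$outdir, "ensemble.pdb")
    write_pdb_ensemble(gen$ensemble, pdb)
    outs <- c(outs, pdb = pdb)
  }
  list(outputs = as.list(outs),
       results = list(n_frames = p$n_frames, generation_log = gen$log))
}

cmd_states <- function(p) {
  ens <- read_ensemble_input(p$input)
  run_log(p, sprintf("state analysis on %d frames", n_frames(ens)))
  sup <- superpose(ens, 1L, nsh2_selection("core"))
  cvs <- pca(sup$ensemble, nsh2_selection("analysis"), n_vectors = p$n_vectors)
  ops <- order_parameters(ens)
  eta <- project(sup$ensemble, cvs[[1]])
  thr <- unlist(p$thresholds)
  cls <- classify_states(ops, thr)
  cors <- c(sheet_vs_pY = pearson(ops$sheet, ops$pY),
            pY_vs_plus5 = pearson(ops$pY, ops$plus5),
            sheet_vs_plus5 = pearson(ops$sheet, ops$plus5))
  op_path <- file.path(p$outdir, "order_parameters.dat")
  utils::write.table(
    data.frame(frame = rep(ops$frame, 3L),
               name = rep(c("pY", "sheet", "plus5"), each = nrow(ops)),
               value = c(ops$pY, ops$sheet, ops$plus5),
               unit = "angstrom"),
    op_path, row.names = FALSE, quote = FALSE)
  eta_path <- file.path(p$outdir, "eta1.dat")
  utils::write.table(data.frame(frame = ops$frame, name = "eta1",
                                value = eta, unit = "nm"),
                     eta_path, row.names = FALSE, quote = FALSE)
  cv_path <- file.path(p$outdir, "pca_vector1.json")
  write_collective_vector(cvs[[1]], cv_path)
  list(outputs = list(order_parameters = op_path, eta = eta_path,
                      vector = cv_path),
       results = list(
         variance_fraction_1 = cvs[[1]]$variance_fraction,
         correlations = as.list(cors),
         fractions = as.list(cls$fractions),
         ci = apply(cls$ci, 1, as.list),
         thresholds = as.list(thr),
         subvector_agreement = list(
           py = subvector_agreement(cvs[[1]], sup$ensemble,
                                    nsh2_selection("py_loop")),
           plus5 = subvector_agreement(cvs[[1]], sup$ensemble,
                                       nsh2_selection("plus5_site")))))
}

cmd_cluster <- function(p) {
  ens <- read_ensemble_input(p$input)
  ops <- order_parameters(ens)
  trace <- data.frame(value = angstrom_to_nm(ops$sheet), frame = ops$frame)
  lo <- if (is.null(p$window_lo)) min(trace$value) else p$window_lo
  hi <- if (is.null(p$window_hi)) max(trace$value) else p$window_hi
  run_log(p, sprintf("seeding %d windows over [%.3g, %.3g] nm",
                     p$n_windows, lo, hi))
  seeds <- seed_windows(trace, ens, p$n_windows, c(lo, hi))
  path <- file.path(p$outdir, "window_seeds.json")
  jsonlite::write_json(seeds, path, auto_unbox = TRUE, digits = NA)
  list(outputs = list(seeds = path),
       results = list(n_windows = p$n_windows))
}

cmd_wham <- function(p) {
  windows <- read_window_tables(p$windows)
  run_log(p, sprintf("WHAM on %d windows", length(windows$references)))
  prof <- bayesian_bootstrap(windows, bins = p$bins, n_boot = p$n_boot,
                             seed = p$seed, tolerance = p$tolerance,
                             max_iter = p$max_iter)
  path <- file.path(p$outdir, "profile.dat")
  write_profile_table(prof, path)
  list(outputs = list(profile = path),
       results = list(iterations = attr(prof, "iterations"),
                      max_error = max(prof$error)))
}

cmd_cft <- function(p) {
  work <- read_work_table(p$work)
  run_log(p, sprintf("CFT estimation on %d/%d work values",
                     length(work$forward_work), length(work$reverse_work)))
  seeds <- derive_seeds(p$seed, 2L)
  bar <- work_bootstrap(work, function(w) bar_solve(w, p$tolerance),
                        n_boot = p$n_boot, seed = seeds[1])
  crossing <- work_bootstrap(work, crossing_estimate, n_boot = p$n_boot,
                             seed = seeds[2])
  path <- file.path(p$outdir, "delta_g.json")
  jsonlite::write_json(
    list(bar = unclass(bar), crossing = unclass(crossing),
         true_dg = work$true_dg,
         sign_convention = "forward work: lambda 0->1, work done on the system"),
    path, auto_unbox = TRUE, digits = NA)
  list(outputs = list(delta_g = path),
       results = list(bar = bar$value, bar_error = bar$error,
                      crossing = crossing$value,
                      crossing_error = crossing$error))
}

cmd_temper <- function(p) {
  pot <- do.call(potential_1d, p$potential)
  ladder <- if (is.character(p$ladder)) ladder_preset(p$ladder) else
    temperature_ladder(unlist(p$ladder))
  schedule <- pull_schedule(p$pull_k, p$velocity, p$ref_start, p$ref_end)
  run_log(p, sprintf("tempered pulling: %d pulls/direction at v=%g nm/ps",
                     p$n_per_direction, p$velocity))
  ws <- pull_work_set(pot, schedule, ladder, p$n_per_direction,
                      seed = p$seed, friction = p$friction, dt = p$dt)
  path <- file.path(p$outdir, "pull_work.dat")
  write_work_table(ws, path)
  list(outputs = list(work = path),
       results = list(mean_forward = mean(ws$forward_work),
                      mean_reverse = mean(ws$reverse_work),
                      true_dg = ws$true_dg))
}

read_ensemble_input <- function(path) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    read_pdb_ensemble(path)
  } else {
    read_frame_table(path)
  }
}
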