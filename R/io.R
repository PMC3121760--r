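# Configuration files, delimited-text serialization and the command-line
# dispatcher. Units are fixed package-wide (nM, s, mV, nmol/mg) and stated
# in every output header; configs carry plain numbers in those units.

ramkinVersion <- function()
  as.character(utils::packageVersion("ramkin"))

knownParamFields <- c("X_RaM", "K_Ca", "n", "K_O", "K_I",
                      "k_O_I1", "k_I1_O", "k_I2_R", "k_R_I2",
                      "tissue_label", "balanced")

rejectUnknown <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")))
}

#' Load and validate a run configuration
#'
#' Reads a JSON or YAML configuration (chosen by file extension), applies
#' defaults, rejects unknown keys by name, and materializes the typed
#' objects the simulation and fitting functions consume. The
#' \code{parameter_set} entry is either the name of a built-in set
#' ("heart", "liver") or an inline table of the nine parameter fields; the
#' corroboration block accepts "table2_defaults" for the built-in
#' matrix/buffer parameters.
#'
#' @param path path to a .json, .yaml or .yml file.
#' @return an object of class \code{run_config} with components
#'   \code{params} (\code{ram_params}), \code{env} (\code{membrane_env}),
#'   optional \code{protocol}, \code{scan}, \code{fit}, \code{synthetic}
#'   and \code{corroboration} blocks, plus \code{seed}, \code{output_dir},
#'   \code{log_level} and the canonical \code{raw} list used for
#'   round-trip serialization.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml, got .", ext))
  buildRunConfig(raw, source_path = path)
}

buildRunConfig <- function(raw, source_path = NULL) {
  rejectUnknown(raw, c("parameter_set", "environment", "protocol", "scan",
                       "fit", "synthetic", "corroboration", "output_dir",
                       "seed", "log_level"), "config")
  ps <- raw$parameter_set
  if (is.null(ps)) stop("config requires a 'parameter_set'")
  if (is.character(ps) && length(ps) == 1L) {
    params <- ramParamSet(ps)
  } else {
    ps <- as.list(ps)
    rejectUnknown(ps, knownParamFields, "parameter_set")
    params <- do.call(ramParams, ps)
  }
  envb <- as.list(raw$environment)
  rejectUnknown(envb, c("delta_psi", "temperature"), "environment")
  env <- do.call(membraneEnv, envb)
  protocol <- NULL
  if (!is.null(raw$protocol)) {
    pb <- as.list(raw$protocol)
    rejectUnknown(pb, names(formals(pulseProtocol)), "protocol")
    protocol <- do.call(pulseProtocol, pb)
  }
  scan <- NULL
  if (!is.null(raw$scan)) {
    sb <- as.list(raw$scan)
    rejectUnknown(sb, c("scan_variable", "grid"), "scan")
    if (is.null(protocol))
      stop("a 'scan' block requires a 'protocol' block as its base")
    scan <- scanSpec(sb$scan_variable, sb$grid, protocol)
  }
  fit <- NULL
  if (!is.null(raw$fit)) {
    fb <- as.list(raw$fit)
    rejectUnknown(fb, names(formals(fitSpec)), "fit")
    if (!is.null(fb$fixed)) fb$fixed <- unlist(fb$fixed)
    fit <- do.call(fitSpec, fb)
  }
  synthetic <- NULL
  if (!is.null(raw$synthetic)) {
    yb <- as.list(raw$synthetic)
    rejectUnknown(yb, c("noise_cv"), "synthetic")
    synthetic <- yb
  }
  corro <- NULL
  if (!is.null(raw$corroboration)) {
    cb <- as.list(raw$corroboration)
    rejectUnknown(cb, c("scenario", "parameters", "train"), "corroboration")
    cpars <- cb$parameters
    if (is.null(cpars) || identical(cpars, "table2_defaults")) {
      cp <- corroParams()
    } else {
      cpars <- as.list(cpars)
      rejectUnknown(cpars, names(formals(corroParams)),
                    "corroboration$parameters")
      cp <- do.call(corroParams, cpars)
    }
    train <- NULL
    if (!is.null(cb$train)) {
      tb <- as.list(cb$train)
      rejectUnknown(tb, names(formals(pulseTrain)), "corroboration$train")
      train <- do.call(pulseTrain, tb)
    }
    corro <- list(scenario = cb$scenario, params = cp, train = train)
  }
  structure(
    list(params = params, env = env, protocol = protocol, scan = scan,
         fit = fit, synthetic = synthetic, corroboration = corro,
         output_dir = if (is.null(raw$output_dir)) "." else raw$output_dir,
         seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
         log_level = if (is.null(raw$log_level)) "info" else raw$log_level,
         raw = raw, source_path = source_path),
    class = "run_config")
}

#' Save a run configuration
#'
#' Writes the canonical configuration list back to JSON or YAML (by
#' extension). A saved configuration loads back to an identical
#' \code{run_config}.
#'
#' @param config a \code{run_config} object.
#' @param path destination path (.json, .yaml or .yml).
#' @return \code{path}, invisibly.
#' @export
saveConfig <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(config$raw, path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(config$raw, path),
    stop("config must be .json, .yaml or .yml, got .", ext))
  invisible(path)
}

provenanceHeader <- function(seed, config_path = NULL) {
  hash <- if (!is.null(config_path) && file.exists(config_path))
    unname(tools::md5sum(config_path)) else "none"
  c(sprintf("# ramkin %s", ramkinVersion()),
    sprintf("# seed: %d", as.integer(seed)),
    sprintf("# config: %s", hash),
    "# units: concentrations nM, time s, potential mV, uptake nmol/mg")
}

#' Write a table as delimited text with a provenance header
#'
#' Comma-separated values preceded by comment lines recording the package
#' version, the seed and the md5 of the generating config. Numeric cells
#' are rendered with \code{sprintf("\%.10g")} so output is reproducible
#' bit-for-bit for a given config and seed.
#'
#' @param df data.frame to write.
#' @param path destination file.
#' @param seed seed recorded in the header.
#' @param config_path config recorded (hashed) in the header, if any.
#' @return \code{path}, invisibly.
#' @export
writeTableWithHeader <- function(df, path, seed = 1L, config_path = NULL) {
  lines <- provenanceHeader(seed, config_path)
  cells <- vapply(seq_len(ncol(df)), function(j) {
    col <- df[[j]]
    if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  body <- apply(cells, 1L, paste, collapse = ",")
  writeLines(c(lines, paste(names(df), collapse = ","), body), path)
  invisible(path)
}

#' Read/write uptake datasets as delimited text
#'
#' One row per record: the protocol fields, the observed total pulse
#' uptake and its variance. Comment lines starting with '#' are ignored on
#' read.
#'
#' @param dataset an \code{experiment_dataset}.
#' @param path file path.
#' @param seed,config_path provenance header fields (write only).
#' @return \code{writeDataset} returns \code{path} invisibly;
#'   \code{readDataset} returns an \code{experiment_dataset}.
#' @export
writeDataset <- function(dataset, path, seed = 1L, config_path = NULL) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  rows <- lapply(seq_along(dataset$protocols), function(i) {
    pr <- dataset$protocols[[i]]
    data.frame(prepulse_height = pr$prepulse_height,
               pulse_height = pr$pulse_height,
               pulse_duration = pr$pulse_duration,
               interpulse_height = pr$interpulse_height,
               interpulse_duration = pr$interpulse_duration,
               n_pulses = pr$n_pulses,
               postpulse_height = pr$postpulse_height,
               postpulse_duration = pr$postpulse_duration,
               prepulse_equilibration = pr$prepulse_equilibration,
               tissue_label = dataset$tissue_label,
               observed_uptake = dataset$observed[i],
               variance = dataset$variance[i])
  })
  writeTableWithHeader(do.call(rbind, rows), path, seed, config_path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  protocols <- lapply(seq_len(nrow(df)), function(i)
    pulseProtocol(
      pulse_height = df$pulse_height[i],
      pulse_duration = df$pulse_duration[i],
      prepulse_height = df$prepulse_height[i],
      interpulse_height = df$interpulse_height[i],
      interpulse_duration = df$interpulse_duration[i],
      n_pulses = df$n_pulses[i],
      postpulse_height = df$postpulse_height[i],
      postpulse_duration = df$postpulse_duration[i],
      prepulse_equilibration = as.logical(df$prepulse_equilibration[i])))
  experimentDataset(protocols, df$observed_uptake, df$variance,
                    unique(df$tissue_label))
}

cliUsage <- function() {
  paste(
    "usage: ramkin <subcommand> [options]",
    "subcommands:",
    "  simulate        --config FILE [--out DIR]   pulse-protocol uptake",
    "  scan            --config FILE [--out DIR]   experiment-family scan",
    "  fit             --config FILE --data FILE [--out DIR]",
    "  make-synthetic  --config FILE [--out DIR]   synthetic uptake data",
    "  corroborate     --scenario {high_freq,low_freq} [--out DIR]",
    "  check-balance   --tissue {heart,liver} [--dependent RATE]",
    sep = "\n")
}

parseCliOpts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    if (i == length(args)) stop("missing value for option ", a)
    opts[[substring(a, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line dispatcher
#'
#' Entry point behind the \code{inst/cli/ramkin.R} wrapper script.
#' Subcommands: \code{simulate}, \code{scan}, \code{fit},
#' \code{make-synthetic}, \code{corroborate}, \code{check-balance}. Every
#' output file carries a provenance header (package version, seed, config
#' hash) and is reproducible bit-for-bit for a given config and seed.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit code: 0 on success, non-zero with a one-line
#'   diagnostic on failure.
#' @export
runCli <- function(argv = character()) {
  if (length(argv) == 0L) {
    message(cliUsage())
    return(2L)
  }
  sub <- argv[1]
  known <- c("simulate", "scan", "fit", "make-synthetic", "corroborate",
             "check-balance")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n", cliUsage())
    return(2L)
  }
  tryCatch({
    opts <- parseCliOpts(argv[-1])
    outdir <- if (!is.null(opts$out)) opts$out else "."
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    switch(sub,
      "check-balance" = {
        p <- ramParamSet(opts$tissue)
        dep <- if (is.null(opts$dependent)) "k_I1_O" else opts$dependent
        bal <- enforceDetailedBalance(p, dep)
        cat(sprintf("tissue: %s\n", p$tissue_label))
        cat(sprintf("cycle ln-residual (printed set): %.6g\n",
                    log(balanceResidual(p))))
        cat(sprintf("balance-implied %s: %.6g /s\n", dep, bal[[dep]]))
      },
      simulate = {
        cfg <- loadConfig(opts$config)
        if (is.null(cfg$protocol)) stop("config has no 'protocol' block")
        sim <- simulateProtocol(cfg$protocol, cfg$params, cfg$env)
        writeTableWithHeader(sim$trajectory,
                             file.path(outdir, "uptake_trace.csv"),
                             cfg$seed, opts$config)
        cat(sprintf("total pulse uptake: %.6g nmol/mg\n",
                    sim$total_pulse_uptake))
      },
      scan = {
        cfg <- loadConfig(opts$config)
        if (is.null(cfg$scan)) stop("config has no 'scan' block")
        tab <- runScan(cfg$scan, cfg$params, cfg$env)
        writeTableWithHeader(tab, file.path(outdir, "scan.csv"),
                             cfg$seed, opts$config)
      },
      "make-synthetic" = {
        cfg <- loadConfig(opts$config)
        if (is.null(cfg$scan) || is.null(cfg$synthetic))
          stop("make-synthetic needs 'scan' and 'synthetic' blocks")
        protos <- lapply(cfg$scan$grid, function(v) {
          pr <- cfg$scan$base_protocol
          if (cfg$scan$scan_variable == "n_pulses")
            pr$n_pulses <- as.integer(v)
          else pr[[cfg$scan$scan_variable]] <- v
          pr
        })
        ds <- synthesizeDataset(cfg$params, protos,
                                cfg$synthetic$noise_cv, cfg$seed, cfg$env)
        writeDataset(ds, file.path(outdir, "synthetic_dataset.csv"),
                     cfg$seed, opts$config)
      },
      fit = {
        cfg <- loadConfig(opts$config)
        if (is.null(cfg$fit)) stop("config has no 'fit' block")
        ds <- readDataset(opts$data)
        res <- fitRaM(ds, cfg$fit, cfg$params, cfg$env, cfg$seed)
        out <- list(
          version = ramkinVersion(), seed = cfg$seed,
          objective = res$objective, converged = res$converged,
          parameters = res$p_star[[1]][knownParamFields[1:9]],
          ci = if (is.null(res$ci)) NULL else
            cbind(parameter = rownames(res$ci), res$ci),
          unidentifiable = res$unidentifiable)
        jsonlite::write_json(out, file.path(outdir, "fit.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        print(res)
      },
      corroborate = {
        scen <- if (is.null(opts$scenario)) "high_freq" else opts$scenario
        cp <- corroParams()
        seed <- 1L
        if (!is.null(opts$config)) {
          cfg <- loadConfig(opts$config)
          seed <- cfg$seed
          if (!is.null(cfg$corroboration)) cp <- cfg$corroboration$params
        }
        sim <- simulateScenario(scen, cp)
        writeTableWithHeader(sim$trajectory,
                             file.path(outdir, "corroboration.csv"),
                             seed, opts$config)
        cat("recovery ratios:",
            paste(sprintf("%.4g", sim$recovery_ratio), collapse = ", "),
            "\n")
      })
    0L
  }, error = function(e) {
    message("ramkin ", sub, ": ", conditionMessage(e))
    1L
  })
}
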