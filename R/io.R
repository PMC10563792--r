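#' Load allometric laws from a JSON or YAML config file
#'
#' The file may contain any subset of the [allometric_laws()] fields
#' (`mass_coeff`, `com_fraction`, `gyration_fraction`, `stiffness_coeff`,
#' `damping_coeff`, `damping_exp`, `moment_arm_fraction`, `body_mass_ratio`,
#' `g`); omitted fields fall back to the calibrated defaults.  Unknown keys
#' are rejected so transcription typos do not silently become defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An `allometric_laws` object.
#' @export
load_laws_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::fromJSON(path),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("config must be .json, .yaml or .yml (got .", ext, ")"))
  if (!is.list(cfg)) stop("config file must contain a mapping of field: value")
  known <- names(formals(allometric_laws))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "))
  }
  do.call(allometric_laws, cfg)
}

#' Export a data.frame as CSV (and read it back)
#'
#' Comma-separated, header row, UTF-8, '.' decimal, full double precision so
#' that a round-trip re-imports values to within 1e-12 relative tolerance.
#' Angles are exported in radians; phase shifts in degrees.
#'
#' @param df A data.frame (e.g. a [phase_landscape()], work-loop trace or
#'   EMG prediction table).
#' @param path Output path.
#' @return `export_csv` invisibly returns `path`; `import_csv` returns the
#'   data.frame.
#' @export
export_csv <- function(df, path) {
  stopifnot(is.data.frame(df))
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname export_csv
#' @export
import_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Read damping measurements from CSV
#'
#' Expects the headered columns `length_m,c_linear,label`.
#'
#' @param path CSV path.
#' @return data.frame with columns `L`, `c_linear`, `label`.
#' @export
read_damping_csv <- function(path) {
  d <- import_csv(path)
  need <- c("length_m", "c_linear")
  if (!all(need %in% names(d))) {
    stop("damping CSV must have columns length_m,c_linear[,label]")
  }
  data.frame(L = as.numeric(d$length_m), c_linear = as.numeric(d$c_linear),
             label = if (is.null(d$label)) "" else as.character(d$label),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic damping-versus-length data set
#'
#' Test stand-in for literature joint-damping measurements: lengths drawn
#' log-uniformly over `[1e-3, 1]` m and damping values
#' \eqn{c = a L^b} perturbed by multiplicative lognormal noise.
#'
#' @param n Number of points (>= 3).
#' @param coeff True prefactor \eqn{a}.
#' @param exponent True exponent \eqn{b}.
#' @param noise_sigma_log Standard deviation of the log-scale noise.
#' @param seed Random seed (integer) for reproducibility.
#' @return data.frame with columns `L`, `c_linear`, `label`.
#' @export
#' @examples
#' d <- generate_damping_fixture(30, coeff = 2, exponent = 1,
#'                               noise_sigma_log = 0.2, seed = 1)
#' fit_power_law(d)$exponent     # close to 1
generate_damping_fixture <- function(n = 30L, coeff = 2, exponent = 1,
                                     noise_sigma_log = 0.2, seed = 1L) {
  n <- as.integer(n)
  if (n < 3L) stop("need n >= 3 points")
  if (noise_sigma_log < 0) stop("noise_sigma_log must be >= 0")
  if (coeff <= 0) stop("coeff must be > 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  L <- 10^stats::runif(n, -3, 0)
  c_linear <- coeff * L^exponent * exp(stats::rnorm(n, 0, noise_sigma_log))
  data.frame(L = L, c_linear = c_linear,
             label = sprintf("synthetic_%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Machine-readable summary of a run
#'
#' Collects the resolved configuration, package version and headline outputs
#' of any analysis into a schema-versioned list, optionally written as JSON.
#' Two runs with identical configuration produce identical summaries.
#'
#' @param laws The resolved `allometric_laws`.
#' @param inputs Named list echoing the run inputs.
#' @param outputs Named list of headline outputs (phase shift, region,
#'   classification, crossovers, ...).
#' @param path Optional path; if given the summary is written there as JSON.
#' @return The summary list, invisibly if written to a file.
#' @export
run_summary <- function(laws, inputs = list(), outputs = list(), path = NULL) {
  laws <- validate_laws(laws)
  s <- list(schema = "limbphase/run-summary/1",
            package_version = as.character(utils::packageVersion("limbphase")),
            laws = unclass(laws), inputs = inputs, outputs = outputs)
  if (!is.null(path)) {
    jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(s))
  }
  s
}

#' Command-line entry point
#'
#' Implements the subcommands of the `limbphase` executable (see
#' `exec/limbphase`): `phase`, `landscape`, `workloop`, `perturb`, `emg` and
#' `fit-damping`.  Exposed as a function so the dispatch logic is testable
#' without spawning a process.
#'
#' @param argv Character vector of command-line arguments (after the
#'   program name).
#' @return Integer exit status (0 on success), invisibly.  Diagnostics for
#'   rejected inputs are written to stderr and yield a non-zero status.
#' @export
limbphase_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: limbphase <command> [options]",
    "commands: phase | landscape | workloop | perturb | emg | fit-damping",
    sep = "\n")
  if (length(argv) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- argv[1L]; rest <- argv[-1L]
  res <- tryCatch({
    switch(cmd,
           phase = cli_phase(rest),
           landscape = cli_landscape(rest),
           workloop = cli_workloop(rest),
           perturb = cli_perturb(rest),
           emg = cli_emg(rest),
           `fit-damping` = cli_fit_damping(rest),
           { message("unknown command: ", cmd, "\n", usage); 1L })
  }, error = function(e) { message("limbphase: ", conditionMessage(e)); 1L })
  invisible(if (is.numeric(res)) as.integer(res) else 0L)
}

cli_laws <- function(opts) {
  if (!is.null(opts$config)) load_laws_config(opts$config) else default_laws()
}

common_opts <- function(extra = list()) {
  c(list(
    optparse::make_option("--gait", type = "character", default = "swing",
                          help = "swing or stance [default %default]"),
    optparse::make_option(c("-L", "--length"), type = "double", default = 0.1,
                          help = "limb length in m [default %default]"),
    optparse::make_option(c("-T", "--period"), type = "double", default = 1,
                          help = "cycle period in s [default %default]"),
    optparse::make_option("--amplitude-rad", type = "double", default = 0.5,
                          dest = "amplitude",
                          help = "sweep semi-amplitude in rad [default %default]"),
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON/YAML allometric-laws config"),
    optparse::make_option(c("-o", "--out"), type = "character", default = NULL,
                          help = "output file (CSV for traces, JSON for summaries)")
  ), extra)
}

parse_opts <- function(args, option_list) {
  optparse::parse_args(optparse::OptionParser(option_list = option_list),
                       args = args)
}

cli_phase <- function(args) {
  opts <- parse_opts(args, common_opts())
  laws <- cli_laws(opts)
  ctx <- phase_context(match.arg(opts$gait, c("swing", "stance")),
                       T_cycle = opts$period, L = opts$length, laws = laws,
                       theta_amplitude = opts$amplitude)
  r <- phase_shift(ctx)
  print(r)
  if (!is.null(opts$out)) {
    run_summary(laws,
                inputs = list(gait = r$phase_of_gait, L = r$L, T = r$T,
                              theta_amplitude = ctx$theta_amplitude),
                outputs = list(phi_deg = r$phi_deg, dominant = r$dominant,
                               region = r$region,
                               A_inertial = r$A_inertial, A_viscous = r$A_viscous,
                               A_elastic = r$A_elastic, A_grav = r$A_grav),
                path = opts$out)
  }
  0L
}

cli_landscape <- function(args) {
  extra <- list(
    optparse::make_option("--Lmin", type = "double", default = 1e-4),
    optparse::make_option("--Lmax", type = "double", default = 10),
    optparse::make_option("--Tmin", type = "double", default = 1e-3),
    optparse::make_option("--Tmax", type = "double", default = 1e2),
    optparse::make_option(c("-n", "--n"), type = "integer", default = 200L,
                          help = "grid points per axis [default %default]"))
  opts <- parse_opts(args, common_opts(extra))
  laws <- cli_laws(opts)
  ls <- phase_landscape(10^seq(log10(opts$Lmin), log10(opts$Lmax),
                               length.out = opts$n),
                        10^seq(log10(opts$Tmin), log10(opts$Tmax),
                               length.out = opts$n),
                        match.arg(opts$gait, c("swing", "stance")), laws,
                        theta_amplitude = opts$amplitude)
  out <- if (is.null(opts$out)) stdout() else opts$out
  if (is.character(out)) export_csv(as.data.frame(ls), out) else
    utils::write.csv(ls, out, row.names = FALSE)
  0L
}

cli_workloop <- function(args) {
  opts <- parse_opts(args, common_opts())
  laws <- cli_laws(opts)
  ctx <- phase_context(match.arg(opts$gait, c("swing", "stance")),
                       T_cycle = opts$period, L = opts$length, laws = laws,
                       theta_amplitude = opts$amplitude)
  wl <- work_loop(ctx)
  print(wl)
  if (!is.null(opts$out)) {
    export_csv(data.frame(t_s = wl$t, theta_rad = wl$theta,
                          moment_Nm = wl$moment), opts$out)
  }
  0L
}

cli_perturb <- function(args) {
  extra <- list(
    optparse::make_option("--fraction", type = "double", default = 0.2,
                          help = "perturbation torque fraction [default %default]"),
    optparse::make_option("--cycles", type = "integer", default = 20L),
    optparse::make_option("--nonlinear", action = "store_true", default = FALSE,
                          help = "use sin(theta) gravity"))
  opts <- parse_opts(args, common_opts(extra))
  laws <- cli_laws(opts)
  ctx <- phase_context(match.arg(opts$gait, c("swing", "stance")),
                       T_cycle = opts$period, L = opts$length, laws = laws,
                       theta_amplitude = opts$amplitude)
  traj <- simulate_perturbation(ctx, perturbation_spec(opts$fraction),
                                n_cycles = opts$cycles,
                                nonlinear_gravity = opts$nonlinear)
  print(traj)
  if (!is.null(opts$out)) {
    export_csv(data.frame(t_s = traj$t, theta_rad = traj$theta,
                          theta_dot_rad_s = traj$theta_dot), opts$out)
  }
  0L
}

cli_emg <- function(args) {
  extra <- list(
    optparse::make_option("--preset", type = "character", default = "horse",
                          help = "horse or stick_insect [default %default]"),
    optparse::make_option("--ablate", action = "store_true", default = FALSE),
    optparse::make_option("--lead-ms", type = "double", default = 50,
                          dest = "lead_ms"))
  opts <- parse_opts(args, common_opts(extra))
  laws <- cli_laws(opts)
  spec <- switch(match.arg(opts$preset, c("horse", "stick_insect")),
                 horse = horse_gait(emg_lead = opts$lead_ms / 1000),
                 stick_insect = stick_insect_gait(emg_lead = opts$lead_ms / 1000))
  pred <- predict_emg(spec, laws, ablate = opts$ablate)
  print(pred)
  if (!is.null(opts$out)) {
    export_csv(data.frame(t_s = pred$t, stride_fraction = pred$stride_fraction,
                          phase = pred$phase, torque_Nm = pred$torque,
                          retractor = pred$retractor,
                          protractor = pred$protractor), opts$out)
  }
  0L
}

cli_fit_damping <- function(args) {
  extra <- list(optparse::make_option("--data", type = "character",
                                      default = NULL,
                                      help = "CSV with length_m,c_linear,label"))
  opts <- parse_opts(args, common_opts(extra))
  if (is.null(opts$data)) stop("fit-damping requires --data <csv>")
  fit <- fit_power_law(read_damping_csv(opts$data))
  cat(sprintf("c = %.6g * L^%.4f   (R^2 = %.4f)\n",
              fit$coeff, fit$exponent, fit$r_squared))
  if (!is.null(opts$out)) {
    jsonlite::write_json(fit, opts$out, auto_unbox = TRUE, digits = NA)
  }
  0L
}
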