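# Serialisation of branches and experiment outputs (plain CSV + JSON, full
# float precision) and a thin command-line layer over the package API.

fmt_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a periodic-orbit branch to CSV (+ JSON sidecar)
#'
#' Writes one row per accepted branch point with full (round-trip-safe)
#' float precision, preceded by `#`-prefixed metadata comment lines.
#' Detected bifurcation points go to a sibling `<path>.bif.json`.
#'
#' @param branch An `hkb_branch`.
#' @param path Output CSV path.
#' @return Invisibly, the path.  `read_branch()` returns a list with
#'   `points` (data frame) and `bifurcations`.
#' @export
write_branch <- function(branch, path) {
  df <- branch_points_df(branch)
  if (!nrow(df)) stop("branch has no points")
  # arclength along the branch (weighted by nothing fancier than steps)
  step_len <- sqrt(diff(df$par)^2 + diff(df$period)^2)
  df <- cbind(arclength = c(0, cumsum(step_len)), df)
  # nearest-bifurcation label per point
  if (length(branch$bifurcations)) {
    bp <- vapply(branch$bifurcations, `[[`, 0, "par_value")
    bl <- vapply(branch$bifurcations, `[[`, "", "label")
    near <- vapply(df$par, function(p) bl[which.min(abs(bp - p))], "")
  } else near <- rep("", nrow(df))
  df$nearest_bifurcation <- near
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# hkbdyn branch: free parameter %s", branch$free),
    sprintf("# model: %s  (NTST %d, NCOL %d)", branch$provenance$model,
            branch$provenance$ntst, branch$provenance$ncol),
    sprintf("# status: %s", branch$status)), con)
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], fmt_full)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  bif <- lapply(branch$bifurcations, function(b)
    list(kind = b$kind, label = b$label, par_value = b$par_value,
         period = b$period,
         test_function_residual = b$test_function_residual))
  jsonlite::write_json(bif, paste0(path, ".bif.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_branch
#' @export
read_branch <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  bifp <- paste0(path, ".bif.json")
  bifs <- if (file.exists(bifp))
    jsonlite::read_json(bifp, simplifyVector = FALSE) else list()
  list(points = df, bifurcations = bifs, meta = meta)
}

#' Write sweep and UQ experiment outputs
#'
#' `write_sweep()` writes one CSV row per plateau (step, parameter value,
#' direction, signed and folded lag) plus a JSON sidecar with the detected
#' jumps and the hysteresis verdict.  `write_phase_lag_distribution()`
#' writes one CSV row per draw (draw index, parameter value, lag) plus a
#' JSON sidecar with the histogram and modes.  Full float precision.
#'
#' @param sweep A `sweep_record` from [quasi_static_sweep()].
#' @param d A `phase_lag_distribution` from [uq_phase_distribution()].
#' @param path Output CSV path (the JSON sidecar gets `.summary.json`).
#' @return Invisibly, the path.
#' @export
write_sweep <- function(sweep, path) {
  df <- data.frame(step = sweep$schedule$step,
                   parameter = fmt_full(sweep$schedule$value),
                   direction = sweep$schedule$direction,
                   lag_signed = fmt_full(sweep$lag_signed),
                   lag_folded = fmt_full(sweep$lag_folded))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(param = sweep$param, hysteretic = sweep$hysteretic,
         jumps = sweep$jumps),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sweep
#' @export
write_phase_lag_distribution <- function(d, path) {
  df <- data.frame(draw = seq_along(d$draws),
                   parameter = fmt_full(d$draws),
                   lag = fmt_full(d$lags))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n = d$n, n_excluded = d$n_excluded, signed = d$signed,
         histogram = d$histogram, modes = d$modes),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run configuration records
#'
#' A run configuration captures everything needed to reproduce a run:
#' scenario name or explicit parameters, solver and continuation settings,
#' seeds, and an output directory.  `write_run_config()` persists it as
#' JSON together with an md5 content hash; every artifact written by the
#' CLI carries that hash.
#'
#' @param scenario Scenario name (or `NULL`).
#' @param params Optional explicit parameter object.
#' @param settings Solver/continuation settings list (NTST, NCOL,
#'   tolerances, `T_max`, `R_max`, ...).
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param verbose Verbosity flag.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, params = NULL, settings = list(),
                       seed = 1L, out_dir = ".", verbose = FALSE) {
  s <- modifyList(list(ntst = 50, ncol = 4, newton_tol = 1e-9,
                       rtol = 1e-8, atol = 1e-10, T_max = 1000, R_max = 1e3),
                  settings)
  structure(list(scenario = scenario,
                 params = if (!is.null(params)) as.list(unclass(params)),
                 params_class = if (!is.null(params)) class(params)[1],
                 settings = s, seed = as.integer(seed),
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  h <- unname(tools::md5sum(path))
  x <- unclass(config)
  x$config_hash <- h
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(h)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "run_config")
}

#' Minimal command-line entry point
#'
#' A thin scripted layer over the package functions, used by
#' `inst/cli/hkb.R`.  Subcommands: `scenario list`, `scenario show <name>`,
#' `simulate --scenario <name> [--t-end T]`, `gamma-star --alpha A --beta B
#' --omega W`, `uq --scenario <name> [--n N] [--seed S]`.  All subcommands
#' accept `--out <path>` (JSON output; default stdout).
#'
#' @param argv Character vector of arguments.
#' @return Integer exit code (0 on success, 2 on usage error), invisibly.
#' @export
run_cli <- function(argv = character()) {
  usage <- function() {
    cat("usage: hkb <scenario list|scenario show NAME|simulate|gamma-star|uq> [options]\n",
        " options: --scenario NAME --alpha A --beta B --omega W --t-end T\n",
        "          --n N --seed S --out PATH\n")
    invisible(2L)
  }
  if (!length(argv)) return(usage())
  opt <- function(name, default = NULL, as = as.numeric) {
    i <- which(argv == paste0("--", name))
    if (!length(i) || i == length(argv)) return(default)
    as(argv[i + 1])
  }
  emit <- function(x) {
    out <- opt("out", NULL, as = identity)
    if (is.null(out)) {
      cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE),
          "\n")
    } else jsonlite::write_json(x, out, auto_unbox = TRUE, digits = NA)
    invisible(0L)
  }
  cmd <- argv[1]
  tryCatch({
    if (cmd == "scenario") {
      if (length(argv) >= 2 && argv[2] == "list")
        return(emit(list(scenarios = list_scenarios())))
      if (length(argv) >= 3 && argv[2] == "show") {
        sc <- get_scenario(argv[3])
        return(emit(list(name = sc$name, protocol = sc$protocol,
                         params = as.list(unclass(sc$params)),
                         free_param = sc$free_param, range = sc$range,
                         notes = sc$notes)))
      }
      return(usage())
    }
    if (cmd == "simulate") {
      sc <- get_scenario(opt("scenario", as = identity))
      tend <- opt("t-end", 300)
      seed <- as.integer(opt("seed", 1))
      ic <- random_initial_conditions(1, seed,
                                      dim = if (is_coupled(sc$params)) 4 else 2)[[1]]
      tr <- simulate(sc$params, ic, tend)
      cls <- classify_regime(tr)
      return(emit(list(scenario = sc$name, ic = ic, diverged = tr$meta$diverged,
                       label = cls$label, lag_degrees = cls$lag_degrees)))
    }
    if (cmd == "gamma-star") {
      est <- estimate_gamma_star(opt("alpha"), opt("beta"), opt("omega"))
      if (identical(est$status, "none"))
        return(emit(list(status = "none", reason = est$reason)))
      return(emit(list(gamma_star = est$gamma_star,
                       bracket = unname(est$bracket),
                       r_squared = est$method_diagnostics$r_squared)))
    }
    if (cmd == "uq") {
      sc <- get_scenario(opt("scenario", as = identity))
      n <- as.integer(opt("n", sc$sampler$n))
      seed <- as.integer(opt("seed", sc$sampler$seed))
      sp <- sc$sampler; sp$n <- n; sp$seed <- seed
      d <- uq_phase_distribution(sc, sampler = sp)
      return(emit(list(scenario = sc$name, n = d$n, n_excluded = d$n_excluded,
                       modes = d$modes, counts = d$histogram$counts,
                       mids = d$histogram$mids)))
    }
    usage()
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    invisible(1L)
  })
}
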