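# Serialization of simulation tables and diagnosis results, configuration
# parsing, and the command-line entry point.

#' Write a result table to CSV or JSON
#'
#' CSV: one row per record, header row, UTF-8, '.' decimal, no index
#' column. JSON: a list of objects with the field names of the table.
#'
#' @param x a data frame (`dd_simulations` or `dd_diagnosis`).
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8",
                     na = "")
  } else {
    jsonlite::write_json(as.data.frame(x), path, dataframe = "rows",
                         digits = NA, na = "null", auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path file path (format inferred from the extension unless given).
#' @param format `"csv"` or `"json"`.
#' @return data frame.
#' @export
read_results <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.json$", path)) "json" else "csv"
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::fromJSON(path)
  }
}

#' Parse a run configuration
#'
#' Accepts YAML or JSON, as a file path or literal text. Schema:
#' \preformatted{
#' design: table3_canonical       # catalogue name (required)
#' params: {N: 100}               # design parameters (optional)
#' diagnosands: [bias, power]     # registry names (required)
#' sims: 500                      # number of runs (required, >= 1)
#' bootstrap: 100                 # bootstrap replicates (default 100)
#' seed: 1                        # integer seed (default 1)
#' out: results.csv               # output path (optional)
#' format: csv                    # csv or json (default csv)
#' }
#' Validation errors name the offending field; near-miss diagnosand or
#' design names yield a suggestion.
#'
#' @param text_or_path configuration document or path to one.
#' @return a validated `dd_run_config` list.
#' @export
parse_config <- function(text_or_path) {
  raw <- if (length(text_or_path) == 1 && file.exists(text_or_path)) {
    paste(readLines(text_or_path, warn = FALSE), collapse = "\n")
  } else paste(text_or_path, collapse = "\n")
  cfg <- tryCatch(jsonlite::fromJSON(raw, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(cfg)) {
    # YAML 1.1 resolves bare keys like `n`, `y`, `on` to booleans; quote
    # boolean-looking mapping keys so parameter names survive
    raw <- gsub("(^|[{,[:space:]])(y|n|yes|no|on|off|true|false)(:[[:space:]])",
                "\\1\"\\2\"\\3", raw, ignore.case = TRUE)
    cfg <- tryCatch(yaml::yaml.load(raw),
                    error = function(e)
                      stop_config("malformed configuration document: ",
                                  conditionMessage(e)))
  }
  if (!is.list(cfg)) stop_config("configuration must be a mapping")
  if (is.null(cfg$design)) stop_config("field 'design' is required")
  reg_names <- names(design_registry())
  if (!cfg$design %in% reg_names) {
    near <- agrep(cfg$design, reg_names, max.distance = 3, value = TRUE)
    stop_config("field 'design': unknown design '", cfg$design, "'",
                if (length(near)) paste0("; did you mean '", near[1], "'?"))
  }
  if (is.null(cfg$diagnosands)) stop_config("field 'diagnosands' is required")
  known <- names(diagnosand_registry())
  for (d in cfg$diagnosands) {
    if (!d %in% known) {
      near <- agrep(d, known, max.distance = 2, value = TRUE)
      stop_config("field 'diagnosands': unknown diagnosand '", d, "'",
                  if (length(near)) paste0("; did you mean '", near[1], "'?"))
    }
  }
  sims <- cfg$sims %||% cfg$m
  if (is.null(sims) || !is_count(sims) || sims < 1)
    stop_config("field 'sims' must be a count >= 1")
  boot <- cfg$bootstrap %||% 100
  if (!is_count(boot)) stop_config("field 'bootstrap' must be a count >= 0")
  seed <- cfg$seed %||% 1
  if (!is.numeric(seed) || seed != floor(seed))
    stop_config("field 'seed' must be an integer")
  fmt <- cfg$format %||% "csv"
  if (!fmt %in% c("csv", "json"))
    stop_config("field 'format' must be 'csv' or 'json'")
  params <- cfg$params %||% list()
  if (length(params)) {
    schema <- design_schema(cfg$design)
    builder_args <- names(formals(design_registry()[[cfg$design]]$builder))
    bad <- setdiff(names(params), union(names(schema), builder_args))
    if (length(bad))
      stop_config("field 'params': unknown parameter(s) ",
                  paste(bad, collapse = ", "), " for design '", cfg$design, "'")
  }
  structure(list(design = cfg$design, params = params,
                 diagnosands = unlist(cfg$diagnosands),
                 sims = as.integer(sims), bootstrap = as.integer(boot),
                 seed = as.integer(seed), out = cfg$out %||% NULL,
                 format = fmt), class = "dd_run_config")
}

#' Serialize a run configuration to YAML
#'
#' Round-trips with [parse_config()].
#'
#' @param config a `dd_run_config`.
#' @return YAML text.
#' @export
format_config <- function(config) {
  stopifnot(inherits(config, "dd_run_config"))
  yaml::as.yaml(unclass(config)[!vapply(unclass(config), is.null, logical(1))])
}

log_line <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
}

cli_usage <- function() {
  paste(
    "usage: designdiag <command> [options]",
    "",
    "commands:",
    "  list                      list the design catalogue",
    "  describe --design NAME    print a design's steps and parameter schema",
    "  simulate                  write a simulation table",
    "  diagnose                  write a diagnosis table",
    "  compare                   diagnose two designs under two models",
    "",
    "options:",
    "  --design NAME    catalogue design name",
    "  --param K=V      design parameter (repeatable; JSON scalar or string)",
    "  --diagnosand D   diagnosand name (repeatable; default bias)",
    "  --sims M         number of simulation runs (default 500)",
    "  --bootstrap B    bootstrap replicates (default 100)",
    "  --seed S         integer master seed (default 1)",
    "  --config PATH    YAML/JSON configuration file",
    "  --out PATH       output file (default: standard output)",
    "  --format F       csv or json (default csv)",
    "  --verbose        chattier logging",
    sep = "\n")
}

parse_cli_args <- function(argv) {
  opts <- list(params = list(), diagnosands = character(0), verbose = FALSE)
  i <- 1
  flags1 <- c("--design", "--sims", "--bootstrap", "--seed", "--config",
              "--out", "--format")
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--verbose") {
      opts$verbose <- TRUE
    } else if (a == "--param") {
      kv <- argv[i + 1]; i <- i + 1
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) stop_config("--param expects key=value, got '", kv, "'")
      key <- substr(kv, 1, eq - 1)
      raw <- substr(kv, eq + 1, nchar(kv))
      val <- tryCatch(jsonlite::fromJSON(raw), error = function(e) raw)
      opts$params[[key]] <- val
    } else if (a == "--diagnosand") {
      opts$diagnosands <- c(opts$diagnosands, argv[i + 1]); i <- i + 1
    } else if (a %in% flags1) {
      opts[[sub("^--", "", a)]] <- argv[i + 1]; i <- i + 1
    } else {
      stop_config("unknown flag '", a, "'")
    }
    i <- i + 1
  }
  opts
}

#' Command-line entry point
#'
#' Implements the `list`, `describe`, `simulate`, `diagnose` and `compare`
#' subcommands; see [cli_usage output][parse_config()] for the flags. Log
#' lines go to standard error with timestamps; results go to `--out` or
#' standard output. Returns (rather than calls) the exit code: 0 on
#' success, 2 on a usage error, 1 on a run error, so a wrapper script can
#' `quit(status = cli_main(...))`.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    cat(cli_usage(), "\n", file = stderr())
    return(2L)
  }
  cmd <- argv[1]
  if (!cmd %in% c("list", "describe", "simulate", "diagnose", "compare")) {
    cat("unknown command '", cmd, "'\n", cli_usage(), "\n",
        sep = "", file = stderr())
    return(2L)
  }
  opts <- tryCatch(parse_cli_args(argv[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    cat(conditionMessage(opts), "\n", cli_usage(), "\n",
        sep = "", file = stderr())
    return(2L)
  }

  run <- function() {
    if (!is.null(opts$config)) {
      cfg <- parse_config(opts$config)
      opts$design <- opts$design %||% cfg$design
      opts$params <- utils::modifyList(as.list(cfg$params), opts$params)
      if (length(opts$diagnosands) == 0) opts$diagnosands <- cfg$diagnosands
      opts$sims <- opts$sims %||% cfg$sims
      opts$bootstrap <- opts$bootstrap %||% cfg$bootstrap
      opts$seed <- opts$seed %||% cfg$seed
      opts$out <- opts$out %||% cfg$out
      opts$format <- opts$format %||% cfg$format
    }
    m <- as.integer(opts$sims %||% 500)
    boot <- as.integer(opts$bootstrap %||% 100)
    seed <- as.integer(opts$seed %||% 1)
    fmt <- opts$format %||% "csv"
    diags <- if (length(opts$diagnosands)) opts$diagnosands else "bias"
    emit <- function(x) {
      if (!is.null(opts$out)) {
        write_results(x, opts$out, fmt)
        log_line("wrote ", nrow(x), " rows to ", opts$out)
      } else if (fmt == "json") {
        cat(jsonlite::toJSON(as.data.frame(x), dataframe = "rows",
                             digits = NA, na = "null", pretty = TRUE), "\n")
      } else {
        utils::write.csv(x, row.names = FALSE, na = "")
      }
    }
    switch(cmd,
      list = {
        utils::write.csv(design_catalog(), row.names = FALSE)
      },
      describe = {
        if (is.null(opts$design)) stop_config("describe needs --design")
        d <- do.call(make_design, c(list(opts$design), opts$params))
        print(d)
        cat(jsonlite::toJSON(design_schema(opts$design), auto_unbox = TRUE,
                             pretty = TRUE, null = "null"), "\n")
      },
      simulate = {
        if (is.null(opts$design)) stop_config("simulate needs --design or --config")
        d <- do.call(make_design, c(list(opts$design), opts$params))
        log_line("simulating '", opts$design, "' with m = ", m,
                 ", seed = ", seed)
        emit(simulate_design(d, m = m, seed = seed))
      },
      diagnose = {
        if (is.null(opts$design)) stop_config("diagnose needs --design or --config")
        d <- do.call(make_design, c(list(opts$design), opts$params))
        log_line("diagnosing '", opts$design, "' with m = ", m,
                 ", bootstrap = ", boot, ", seed = ", seed)
        emit(diagnose_design(d, diags, m = m, n_bootstrap = boot, seed = seed))
      },
      compare = {
        if (is.null(opts$design)) stop_config("compare needs --design")
        designs <- strsplit(opts$design, ",")[[1]]
        built <- lapply(designs, function(nm)
          do.call(make_design, c(list(nm), opts$params)))
        names(built) <- designs
        res <- compare_designs(built, diagnosand = diags[1], m = m,
                               seed = seed, n_bootstrap = boot)
        emit(res$table)
        if (!is.null(res$verdict)) log_line("verdict: ", res$verdict)
      })
    0L
  }
  code <- tryCatch(run(), dd_config_error = function(e) {
    cat(conditionMessage(e), "\n", file = stderr()); 2L
  }, error = function(e) {
    cat(conditionMessage(e), "\n", file = stderr()); 1L
  })
  code
}
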