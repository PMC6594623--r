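#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration describing one run or ensemble.
#' Recognized keys: `preset` (`"table2-main"` or `"table2-s2"`, filling
#' rates, `N` and the four reference initial conditions), `c`, `e`, `i`,
#' `N`, `rho_Rb`, `rho_Br`, `rho_Rr`, `n_reps`, `seed`, `grid_dt`, `t_max`,
#' `out`. Explicit keys override preset values. Unknown keys are rejected;
#' validation failures name the offending field.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated list of class `cvm_config` with elements `rates`
#'   ([rate_set()]), `N`, `ic` ([initial_condition()] or list of them when
#'   a preset supplies several), `n_reps`, `seed`, `grid_dt`, `t_max`,
#'   `out`, `preset`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("config must be a mapping of keys to values",
                          call. = FALSE)
  # YAML 1.1 implicit typing turns a bare `N:` key into the boolean FALSE;
  # map it back so `N: 400` works unquoted
  names(raw)[names(raw) == "FALSE"] <- "N"
  known <- c("preset", "c", "e", "i", "N", "rho_Rb", "rho_Br", "rho_Rr",
             "n_reps", "seed", "grid_dt", "t_max", "out")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(preset = NULL, ic = NULL, n_reps = raw$n_reps,
              seed = raw$seed, grid_dt = raw$grid_dt %||% 0.25,
              t_max = raw$t_max %||% Inf, out = raw$out)
  if (!is.null(raw$preset)) {
    nm <- sub("^table2-", "", raw$preset)
    if (!nm %in% c("main", "s2")) {
      stop("field `preset`: must be \"table2-main\" or \"table2-s2\"",
           call. = FALSE)
    }
    ps <- cvm_preset(nm)
    cfg$preset <- nm
    cfg$rates <- ps$rates
    cfg$N <- ps$N
    cfg$ic <- ps$ics
  }
  if (!is.null(raw$c) || !is.null(raw$e) || !is.null(raw$i)) {
    if (is.null(raw$c) || is.null(raw$e) || is.null(raw$i)) {
      stop("fields `c`, `e`, `i`: all three rates must be given together",
           call. = FALSE)
    }
    cfg$rates <- withCallingHandlers(
      rate_set(raw$c, raw$e, raw$i),
      error = function(e) stop("fields `c`/`e`/`i`: ", conditionMessage(e),
                               call. = FALSE))
  }
  if (!is.null(raw$N)) cfg$N <- raw$N
  if (!is.null(raw$rho_Rb) || !is.null(raw$rho_Br) || !is.null(raw$rho_Rr)) {
    tr <- c(raw$rho_Rb %||% 0, raw$rho_Br %||% 0, raw$rho_Rr %||% 0)
    cfg$ic <- tryCatch(
      initial_condition(tr[1L], tr[2L], tr[3L]),
      error = function(e) stop("fields `rho_Rb`/`rho_Br`/`rho_Rr`: ",
                               conditionMessage(e), call. = FALSE))
  }
  if (is.null(cfg$rates)) {
    stop("config must supply rates, either explicitly or via a preset",
         call. = FALSE)
  }
  if (!is.null(cfg$N) && (cfg$N < 1 || cfg$N != round(cfg$N))) {
    stop("field `N`: must be a positive integer", call. = FALSE)
  }
  structure(cfg, class = "cvm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a result object to disk
#'
#' Serializes ensembles, theory predictions, exact solutions, benchmark
#' tables or trajectories to JSON (full double precision) or CSV (6
#' significant digits). Every output embeds the generating parameters and
#' master seed, so any file can be regenerated bit-for-bit.
#'
#' @param result a `cvm_ensemble`, `cvm_theory`, `cvm_exact`, `cvm_table2`
#'   or `cvm_trajectory`.
#' @param path output file path.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(result, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  format <- match.arg(format, c("json", "csv"))
  payload <- results_payload(result)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  } else {
    df <- payload$table
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], signif, digits = 6L)
    meta <- payload$meta
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", names(meta), ": ",
                      vapply(meta, base::format, character(1L))), con)
    write.csv(df, con, row.names = FALSE)
  }
  invisible(path)
}

results_payload <- function(result) {
  if (inherits(result, "cvm_ensemble")) {
    p <- result$params
    list(
      kind = "ensemble",
      meta = list(N = p$N, c = p$rates$c, e = p$rates$e, i = p$rates$i,
                  rho_Rb = p$ic$rho_Rb, rho_Br = p$ic$rho_Br,
                  rho_Rr = p$ic$rho_Rr, n_reps = result$n_reps,
                  seed = p$seed),
      summary = as.list(glance(result)),
      table = result$replicates,
      gap = result$gap
    )
  } else if (inherits(result, "cvm_trajectory")) {
    p <- attr(result, "params")
    meta <- list(model = attr(result, "model"), N = p$N,
                 terminal_status = attr(result, "terminal_status"),
                 t_end = attr(result, "t_end"),
                 seed = attr(result, "seed") %||% NA)
    if (!is.null(p$rates)) {
      meta <- c(meta, list(c = p$rates$c, e = p$rates$e, i = p$rates$i))
    } else {
      meta <- c(meta, list(c = p$c))
    }
    list(kind = "trajectory", meta = meta, table = as_tibble(result))
  } else if (inherits(result, "cvm_exact")) {
    r <- attr(result, "rates")
    list(kind = "exact",
         meta = list(N = attr(result, "N"), c = r$c, e = r$e, i = r$i),
         table = as_tibble(result))
  } else if (inherits(result, "cvm_table2")) {
    list(kind = "table2",
         meta = list(preset = attr(result, "preset"), N = attr(result, "N"),
                     seed = attr(result, "seed")),
         table = as_tibble(result))
  } else if (inherits(result, "cvm_theory")) {
    list(kind = "theory", meta = list(), table = as_tibble(result))
  } else {
    stop("don't know how to serialize an object of class ",
         paste(class(result), collapse = "/"), call. = FALSE)
  }
}

#' Read back a JSON results file
#'
#' @param path a file written by [write_results()] in JSON format.
#' @return The parsed payload: a list with `kind`, `meta` and `table`
#'   (tibble), plus any extra components.
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(payload$table)) payload$table <- as_tibble(payload$table)
  if (!is.null(payload$gap)) payload$gap <- as_tibble(payload$gap)
  payload
}

#' Write a trajectory as CSV
#'
#' One row per recorded event (or grid point in sampled mode) with header
#' `t,n_Rb,n_Br,n_Rr,n_Bb`, plus a sidecar JSON (`<path>.meta.json`)
#' holding `terminal_status`, the consensus time and the seed.
#'
#' @param traj a `cvm_trajectory` from [run_cvm()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cvm_trajectory"))
  write.csv(as_tibble(traj), path, row.names = FALSE, quote = FALSE)
  meta <- list(terminal_status = attr(traj, "terminal_status"),
               T_cons = if (attr(traj, "terminal_status") %in%
                            c("absorbed_red", "absorbed_blue"))
                 attr(traj, "t_end") else NA,
               t_end = attr(traj, "t_end"),
               seed = attr(traj, "seed") %||% NA,
               n_events = attr(traj, "n_events"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
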