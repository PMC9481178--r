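#' Build and validate a run configuration
#'
#' Configurations are plain YAML (or an R list) with up to four blocks:
#' `model` (overrides for [kai_params()]), `thermo` (either `case: A-D` or
#' explicit `rules`/energies for [kai_thermo()]), `protocol` (a name from the
#' protocol drivers plus its options), and `run`
#' (`duration_h`, `warmup_h`, `record_stride_h`, `seed`, `n_replicates`).
#' Unknown keys are rejected with the offending path; defaults reproduce the
#' standard condition (N = 1000, T0 = 30 C, monomer ratio AT:BT:CT = 1:3:3).
#'
#' @param x Path to a YAML file, or a named list (empty list = all defaults).
#' @return A list of class `kai_config` with elements `params`, `thermo`,
#'   `protocol`, `run`.
#' @export
kai_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a file path or a list",
                          call. = FALSE)
  allowed <- c("model", "thermo", "protocol", "run")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config block(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)

  model <- cfg$model %||% list()
  # YAML 1.1 resolves a bare key `N` to boolean FALSE; undo that
  names(model)[names(model) == "FALSE"] <- "N"
  known_model <- names(formals(kai_params))
  known_model <- setdiff(known_model, "...")
  bad <- setdiff(names(model), known_model)
  if (length(bad)) stop("unknown model key(s): model.",
                        paste(bad, collapse = ", model."), call. = FALSE)
  params <- do.call(kai_params, model)

  th <- cfg$thermo %||% list()
  known_th <- c("case", names(formals(kai_thermo)))
  bad <- setdiff(names(th), known_th)
  if (length(bad)) stop("unknown thermo key(s): thermo.",
                        paste(bad, collapse = ", thermo."), call. = FALSE)
  thermo <- if (!is.null(th$case)) {
    extra <- th[setdiff(names(th), "case")]
    do.call(kai_case, c(list(name = th$case), extra))
  } else {
    do.call(kai_thermo, th)
  }

  run_defaults <- list(duration_h = 480, warmup_h = 100,
                       record_stride_h = 0.1, seed = 1, n_replicates = 1)
  run <- utils::modifyList(run_defaults, cfg$run %||% list())
  bad <- setdiff(names(run), names(run_defaults))
  if (length(bad)) stop("unknown run key(s): run.",
                        paste(bad, collapse = ", run."), call. = FALSE)

  protocol <- cfg$protocol %||% list(name = "simulate")

  structure(list(params = params, thermo = thermo, protocol = protocol,
                 run = run),
            class = "kai_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as delimited text
#'
#' Tab-separated values preceded by commented header lines naming the
#' columns, their units, and the run metadata (seed, stride, window).
#'
#' @param traj A `kai_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# kaiabc trajectory",
    "# columns: t[h] D_mean[-] X_mean[-] q_mean[-] qr[ADP/(CI*h)] xA[count/V] xB[count/V]",
    paste0("# seed: ", attr(traj, "seed") %||% NA,
           "  record_stride_h: ", attr(traj, "record_stride"),
           "  qr_window_h: ", attr(traj, "qr_window"))
  ), con)
  df <- as.data.frame(traj)
  # full-precision text so the round trip is exact
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path File path.
#' @return A tibble with the trajectory columns.
#' @export
read_trajectory <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#"))
}

#' Write an analysis summary as JSON
#'
#' @param x A `kai_summary`, scan tibble, or any list/data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  if (inherits(x, "kai_summary")) x <- unclass(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
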