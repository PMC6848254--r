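#' Load a network / protocol / condition configuration file
#'
#' Reads a YAML (or JSON) configuration and resolves it against the
#' standard parameter set, so an empty file yields the pure defaults.
#' Recognized top-level blocks:
#'
#' * `network`: either `preset: single` / `preset: two_node` with optional
#'   `w21`, `w12`, `w_EX1`, `w_IX1`, or explicit matrices `W_EE`, `W_IE`,
#'   `W_EI`, `W_II` (row-major lists) plus optional `W_EX`, `W_IX`, `B`,
#'   `H_e`, `tau_e`, `H_i`, `tau_i`.
#' * `protocol`: `type: step` (`onset`, `offset`, `amplitude`, `ramp`),
#'   `type: train` (`soa`, `stim_duration`, `n_stim`, `onset0`) or
#'   `type: sequence` (`reg_spans`, `rand_spans` as lists of pairs).
#' * `condition`: one of `I`, `II`, `III`, `IV`.
#' * `solver`: `dt`, `settle`.
#'
#' @param path configuration file.
#' @return list with `config` (a [network_config()], condition already
#'   applied), `stimuli` (a stimulus set or `NULL`), `adaptation`,
#'   `condition`, `solver` (list with `dt`, `settle`) and `raw` (the
#'   parsed file).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("network", "protocol", "condition", "solver"))
  if (length(bad))
    stop("unknown config block(s): ", paste(bad, collapse = ", "))

  nw <- raw$network
  cfg <- if (is.null(nw) || identical(nw$preset, "single")) {
    default_node_config()
  } else if (identical(nw$preset, "two_node")) {
    two_node_config(w21 = unlist(nw$w21) %||% rep(0, 4),
                    w12 = unlist(nw$w12) %||% rep(0, 4),
                    w_EX1 = nw$w_EX1 %||% 44, w_IX1 = nw$w_IX1 %||% 22)
  } else {
    as_mat <- function(x, nm) {
      if (is.null(x)) stop("network.", nm, " is required for explicit networks")
      m <- do.call(rbind, lapply(x, unlist))
      m
    }
    network_config(W_EE = as_mat(nw$W_EE, "W_EE"),
                   W_IE = as_mat(nw$W_IE, "W_IE"),
                   W_EI = as_mat(nw$W_EI, "W_EI"),
                   W_II = as_mat(nw$W_II, "W_II"),
                   W_EX = if (is.null(nw$W_EX)) NULL else
                     do.call(rbind, lapply(nw$W_EX, unlist)),
                   W_IX = if (is.null(nw$W_IX)) NULL else
                     do.call(rbind, lapply(nw$W_IX, unlist)),
                   B = nw$B %||% 550,
                   H_e = nw$H_e %||% 3.25, tau_e = nw$tau_e %||% 0.010,
                   H_i = nw$H_i %||% 22, tau_i = nw$tau_i %||% 0.020)
  }

  pr <- raw$protocol
  stimuli <- if (is.null(pr)) NULL else switch(
    pr$type %||% stop("protocol.type is required"),
    step = step_stimulus(pr$onset %||% 0, pr$offset %||% 2,
                         pr$amplitude %||% 1.5, pr$ramp %||% 0.010),
    train = periodic_train(pr$soa, pr$stim_duration %||% 0.050, pr$n_stim,
                           onset0 = pr$onset0 %||% 0,
                           amplitude = pr$amplitude %||% 1.5),
    sequence = sequence_pair(lapply(pr$reg_spans, unlist),
                             lapply(pr$rand_spans, unlist)),
    stop("unknown protocol type: ", pr$type))

  cond_label <- raw$condition %||% "I"
  applied <- apply_condition(cfg, cond_label)
  solver <- list(dt = raw$solver$dt %||% 5e-4,
                 settle = raw$solver$settle %||% 2)
  if (solver$dt <= 0) stop("solver.dt must be positive")
  list(config = applied$config, stimuli = stimuli,
       adaptation = applied$adaptation, condition = cond_label,
       solver = solver, raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run manifest for reproducibility
#'
#' Captures the configuration hash, solver settings and software version
#' that produced a set of outputs; every writer embeds it.
#'
#' @param config any serializable configuration object.
#' @param solver list of solver settings.
#' @return list with `config_md5`, `solver`, `package_version`, `r_version`.
#' @export
run_manifest <- function(config, solver = list(dt = 5e-4, settle = 2)) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  list(config_md5 = unname(tools::md5sum(tf)),
       solver = solver,
       package_version = as.character(utils::packageVersion("devmass")),
       r_version = as.character(getRversion()))
}

#' Write simulation / scan outputs with an embedded manifest
#'
#' Supported objects: a `"simulation_result"` (tidy long trajectory CSV),
#' a `"scan_result"` (one row per grid point with the label and metrics),
#' a contingency table (9 x 9 percentages) or any data.frame.  Formats:
#' `csv` (the manifest is written alongside as `<path>.manifest.json`) and
#' `jsonl` (one JSON object per row, first line = manifest).
#'
#' @param x object to write.
#' @param path output file.
#' @param format `"csv"` or `"jsonl"`.
#' @param manifest optional [run_manifest()]; generated from `x` otherwise.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "jsonl"),
                          manifest = NULL) {
  format <- match.arg(format)
  df <- if (inherits(x, "simulation_result")) {
    trajectory_table(x)
  } else if (inherits(x, "scan_result")) {
    data.frame(x$grid, label = as.character(x$labels), x$metrics,
               check.names = FALSE)
  } else if (is.table(x) || (is.matrix(x) && !is.null(dimnames(x)))) {
    as.data.frame(as.table(x), responseName = "percent")
  } else {
    as.data.frame(x)
  }
  if (is.null(manifest))
    manifest <- run_manifest(list(class = class(x)[1], n = nrow(df)))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(as.character(jsonlite::toJSON(
      c(list(manifest = TRUE), manifest), auto_unbox = TRUE, digits = NA)), con)
    for (i in seq_len(nrow(df)))
      writeLines(as.character(jsonlite::toJSON(as.list(df[i, ]),
                                               auto_unbox = TRUE,
                                               digits = NA)), con)
  }
  invisible(path)
}
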