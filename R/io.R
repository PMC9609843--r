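# Config and trajectory file I/O.
#
# Experiment files use a flat TOML-style dialect: `key = value` pairs,
# `[section]` headers, numeric lists as `[1, 2, 3]`, `#` comments. Numbers
# are serialized with 17 significant digits so that parse -> write -> parse
# round-trips bit-exactly.

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "nan" else sprintf("%.17g", v)
  }, "")
}

parse_value <- function(txt) {
  txt <- trimws(txt)
  if (startsWith(txt, "[")) {
    inner <- sub("\\]\\s*$", "", sub("^\\[", "", txt))
    if (trimws(inner) == "") return(numeric(0))
    return(as.numeric(trimws(strsplit(inner, ",")[[1]])))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  txt
}

#' Read a flat TOML-style config file
#'
#' @param path file path.
#' @return A named list; keys inside `[section]` headers become nested
#'   lists under the section name.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("cannot parse config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- parse_value(kv[2])
    if (is.null(section)) out[[key]] <- val
    else out[[section]][[key]] <- val
  }
  out
}

serialize_value <- function(v) {
  if (is.character(v)) sprintf('"%s"', v)
  else if (is.logical(v)) tolower(as.character(v))
  else if (length(v) > 1L) paste0("[", paste(fmt_num(v), collapse = ", "), "]")
  else fmt_num(v)
}

#' Write a flat TOML-style config file
#'
#' Numbers are written with 17 significant digits; [read_config()] of the
#' result reproduces the input exactly.
#'
#' @param config named list (scalars, numeric vectors, or one level of
#'   named-list sections).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  sections <- character(0)
  for (key in names(config)) {
    v <- config[[key]]
    if (is.list(v)) { sections <- c(sections, key); next }
    lines <- c(lines, paste(key, "=", serialize_value(v)))
  }
  for (key in sections) {
    lines <- c(lines, "", paste0("[", key, "]"))
    for (k2 in names(config[[key]]))
      lines <- c(lines, paste(k2, "=", serialize_value(config[[key]][[k2]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a patient model to a config file
#'
#' Writes `C0, p1, p2, p3, Ts` and, optionally, explicit `[A]`, `[B]`,
#' `[C]`, `[D]` sections (row-major numeric lists). Round-trips bit-exactly
#' through [read_patient_model()].
#'
#' @param params a [patient_params()] object.
#' @param path output path.
#' @param ss optional `ss_model` whose matrices are embedded.
#' @return `path`, invisibly.
#' @export
write_patient_model <- function(params, path, ss = NULL) {
  stopifnot(inherits(params, "patient_params"))
  cfg <- list(C0 = params$C0, p1 = params$p1, p2 = params$p2,
              p3 = params$p3, Ts = params$Ts)
  if (!is.null(ss)) {
    stopifnot(inherits(ss, "ss_model"))
    cfg$A <- list(rows = as.numeric(t(ss$A)))
    cfg$B <- list(rows = as.numeric(ss$B))
    cfg$C <- list(rows = as.numeric(ss$C))
    cfg$D <- list(rows = ss$D)
    cfg$domain <- ss$domain
  }
  write_config(cfg, path)
}

#' Import a patient model from a config file
#'
#' @param path file written by [write_patient_model()] (or hand-edited in
#'   the same dialect).
#' @return A list with `params` ([patient_params()]) and `ss` (an
#'   `ss_model`, or `NULL` if no matrices were embedded).
#' @export
read_patient_model <- function(path) {
  cfg <- read_config(path)
  params <- patient_params(C0 = cfg$C0, p1 = cfg$p1, p2 = cfg$p2,
                           p3 = cfg$p3, Ts = cfg$Ts)
  ss <- NULL
  if (!is.null(cfg$A)) {
    ss <- new_ss(A = matrix(cfg$A$rows, 3, 3, byrow = TRUE),
                 B = cfg$B$rows, C = cfg$C$rows, D = cfg$D$rows,
                 domain = if (!is.null(cfg$domain)) cfg$domain else "continuous",
                 Ts = if (identical(cfg$domain, "discrete")) cfg$Ts else NA_real_)
  }
  list(params = params, ss = ss)
}

#' Write a trajectory CSV
#'
#' Header `time_s,glucose_mg_dl,control_u,sliding_s,disturbance`; floats at
#' 10 significant digits; the `sliding_s` column is empty for non-SMC runs.
#'
#' @param traj a `glyco_trajectory` (or compatible data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  traj_cols(traj)
  f <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))
  lines <- c("time_s,glucose_mg_dl,control_u,sliding_s,disturbance",
             paste(f(traj$time_s), f(traj$glucose_mg_dl), f(traj$control_u),
                   f(traj$sliding_s), f(traj$disturbance), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return A data.frame with the five trajectory columns.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Write a controller comparison report CSV
#'
#' One row per controller with all performance metrics plus the config
#' fingerprint.
#'
#' @param report a `controller_comparison` from [compare_controllers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "controller_comparison"))
  rep2 <- report
  rep2$config_fingerprint <- attr(report, "fingerprint")
  num <- vapply(rep2, is.numeric, TRUE)
  for (j in which(num)) rep2[[j]] <- ifelse(is.na(rep2[[j]]), "",
                                            sprintf("%.10g", rep2[[j]]))
  utils::write.csv(rep2, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
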