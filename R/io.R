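# Flat key = value parameter files (a TOML subset: comments with '#',
# optional [section] headers, numeric scalars). Keys are exactly the
# parameter names, so the parameter table documents the file format. No
# installed R package reads TOML, and the dialect is flat, so the parser
# lives here.

.parse_flat_toml <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("parameter file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  out <- list(values = numeric(0), sections = character(0))
  section <- ""
  vals <- numeric(0)
  secs <- character(0)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) {
      rlang::abort(paste0("parse error at line ", i, " of ", path, ": '",
                          lines[i], "'"))
    }
    val <- suppressWarnings(as.numeric(m[3]))
    if (is.na(val)) {
      rlang::abort(paste0("non-numeric value at line ", i, " of ", path,
                          ": '", m[3], "'"))
    }
    vals[m[2]] <- val
    secs[m[2]] <- section
  }
  list(values = vals, sections = secs)
}

#' Read a parameter file
#'
#' Reads a flat `key = value` parameter file whose keys are the model
#' parameter names. Unknown keys are rejected by name; missing keys are an
#' error unless `allow_defaults` is set, in which case they are filled from
#' the published defaults.
#'
#' @param path file to read.
#' @param allow_defaults fill missing parameters from the defaults.
#' @return An `"eb_parameters"` vector.
#' @export
read_parameters <- function(path, allow_defaults = FALSE) {
  parsed <- .parse_flat_toml(path)
  vals <- parsed$values[parsed$sections %in% c("", "parameters")]
  unknown <- setdiff(names(vals), names(.param_defaults))
  if (length(unknown)) {
    rlang::abort(paste0("unknown parameter key(s) in ", path, ": ",
                        paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(names(.param_defaults), names(vals))
  if (length(missing) && !allow_defaults) {
    rlang::abort(paste0("missing parameter key(s) in ", path, ": ",
                        paste(missing, collapse = ", "),
                        " (use allow_defaults to fill them)"))
  }
  p <- .param_defaults
  p[names(vals)] <- vals
  validate_parameters(p)
}

#' Write a parameter file
#'
#' Emits every parameter as `key = value`, one per line; `write_parameters`
#' then `read_parameters` round-trips exactly.
#'
#' @param p an [model_parameters()] set.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  lines <- c("# energy-balance model parameters (m.p.c., 1/min, bp, aa)",
             sprintf("%s = %.17g", names(unclass(p)), as.numeric(p)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration problem file
#'
#' Same flat dialect as [read_parameters()], with a `[calibration]` section
#' holding `free` targets and weight: keys `target_a_wt`, `target_L_wt`,
#' `target_S_wt`, `reg_weight`, and `free_<name> = 1` markers selecting the
#' free parameters. Parameter keys outside the section override the base
#' set.
#'
#' @param path file to read.
#' @return An [calibration_problem()].
#' @export
read_calibration_problem <- function(path) {
  parsed <- .parse_flat_toml(path)
  pvals <- parsed$values[parsed$sections %in% c("", "parameters")]
  base <- do.call(model_parameters, as.list(pvals))
  cal <- parsed$values[parsed$sections == "calibration"]
  free <- sub("^free_", "", names(cal)[grepl("^free_", names(cal)) &
                                         cal != 0])
  if (!length(free)) free <- .free_params
  tg <- c(a_wt = unname(cal["target_a_wt"]),
          L_wt = unname(cal["target_L_wt"]),
          S_wt = unname(cal["target_S_wt"]))
  tg <- tg[!is.na(tg)]
  targets <- c(a_wt = base[["a_wt"]], L_wt = base[["L_wt"]],
               S_wt = base[["S_wt"]])
  targets[names(tg)] <- tg
  w <- if ("reg_weight" %in% names(cal)) cal[["reg_weight"]] else 1e-4
  calibration_problem(free = free, targets = targets, base = base,
                      reg_weight = w)
}
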