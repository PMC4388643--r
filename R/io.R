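# Delimited-text I/O. Every file is plain text with an optional commented
# header block ('# key: value' lines) followed by a column header row.
# Delimiter is auto-detected among comma and tab. Canonical units are
# enforced at this boundary: time s, power ucal/s, volume uL, conc uM.

#' @keywords internal
read_header_block <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- !nzchar(trimws(lines))
  body_start <- which(!is_comment & !is_blank)
  if (length(body_start) == 0L)
    stop(sprintf("'%s': no data rows found", path), call. = FALSE)
  meta <- list()
  for (ln in lines[seq_len(body_start[1L] - 1L)][is_comment[seq_len(body_start[1L] - 1L)]]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
  }
  header <- lines[body_start[1L]]
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(text = lines[!is_comment & !is_blank], sep = delim,
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  list(meta = meta, data = tab)
}

#' @keywords internal
require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop(sprintf("'%s': missing column(s) %s (found: %s)", path,
                 paste(sQuote(missing), collapse = ", "),
                 paste(sQuote(names(tab)), collapse = ", ")), call. = FALSE)
}

#' Read a thermogram file
#'
#' Reads a delimited text thermogram with columns `time_s` and
#' `power_ucal_per_s` and a commented header block. The header must carry a
#' `# unit:` line declaring the units of both columns, e.g.
#' `# unit: time=s, power=ucal/s`; times in minutes (`time=min`) are
#' converted to seconds on load, any other unit is rejected. Optional header
#' keys: `temperature_C`, `label`.
#'
#' @param path file path.
#' @return a validated [thermogram()].
#' @export
read_thermogram <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  hb <- read_header_block(path)
  if (is.null(hb$meta$unit))
    stop(sprintf("'%s': mandatory '# unit:' header line is absent", path), call. = FALSE)
  require_columns(hb$data, c("time_s", "power_ucal_per_s"), path)
  units <- parse_unit_decl(hb$meta$unit, path)
  time <- hb$data$time_s
  if (units[["time"]] == "min") time <- time * 60
  power <- hb$data$power_ucal_per_s
  d <- diff(time)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("'%s': time not strictly increasing at data row %d (t = %g)",
                 path, i + 1L, time[i + 1L]), call. = FALSE)
  }
  thermogram(time = time, power = power,
             temperature = if (!is.null(hb$meta$temperature_C))
               as.numeric(hb$meta$temperature_C) else NA_real_,
             label = if (!is.null(hb$meta$label)) hb$meta$label else "")
}

#' @keywords internal
parse_unit_decl <- function(decl, path) {
  parts <- strsplit(decl, "[,;]\\s*")[[1L]]
  units <- c(time = "s", power = "ucal/s")
  for (p in parts) {
    kv <- strsplit(trimws(p), "\\s*=\\s*")[[1L]]
    if (length(kv) == 2L) units[[kv[1L]]] <- kv[2L]
  }
  if (!units[["time"]] %in% c("s", "min"))
    stop(sprintf("'%s': unsupported time unit '%s' (use s or min)", path,
                 units[["time"]]), call. = FALSE)
  if (units[["power"]] != "ucal/s")
    stop(sprintf("'%s': unsupported power unit '%s' (use ucal/s)", path,
                 units[["power"]]), call. = FALSE)
  units
}

#' Write a thermogram file
#'
#' Writes canonical-unit delimited text readable by [read_thermogram()].
#' Numeric fields are written at full precision (17 significant digits), so a
#' read -> write -> read round trip is bit-exact.
#'
#' @param tg a [thermogram()].
#' @param path output file path.
#' @param delim `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_thermogram <- function(tg, path, delim = ",") {
  stopifnot(inherits(tg, "thermogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# unit: time=s, power=ucal/s",
               sprintf("# temperature_C: %s", tg$temperature),
               sprintf("# label: %s", tg$label)), con)
  if (length(tg$processing_log))
    writeLines(sprintf("# processing: %s", paste(tg$processing_log, collapse = " | ")), con)
  writeLines(paste("time_s", "power_ucal_per_s", sep = delim), con)
  writeLines(paste(format(tg$time, digits = 17, trim = TRUE, scientific = FALSE),
                   format(tg$power, digits = 17, trim = TRUE),
                   sep = delim), con)
  invisible(path)
}

#' Read an injection schedule file
#'
#' Delimited text with columns `time_s`, `volume_uL`, `syringe_conc_uM`.
#' An optional `# syringe_capacity_uL:` header overrides the 40 uL default.
#'
#' @param path file path.
#' @return a validated [injection_schedule()].
#' @export
read_injection_schedule <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  hb <- tryCatch(read_header_block(path),
                 error = function(e) stop(sprintf("'%s': no injection events", path),
                                          call. = FALSE))
  require_columns(hb$data, c("time_s", "volume_uL", "syringe_conc_uM"), path)
  if (nrow(hb$data) == 0L) stop(sprintf("'%s': no injection events", path), call. = FALSE)
  cap <- if (!is.null(hb$meta$syringe_capacity_uL))
    as.numeric(hb$meta$syringe_capacity_uL) else 40
  injection_schedule(time = hb$data$time_s, volume = hb$data$volume_uL,
                     syringe_conc = hb$data$syringe_conc_uM,
                     syringe_capacity = cap)
}

#' Write an injection schedule file
#'
#' @param schedule an [injection_schedule()].
#' @param path output file path.
#' @param delim `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_injection_schedule <- function(schedule, path, delim = ",") {
  stopifnot(inherits(schedule, "injection_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# syringe_capacity_uL: %g", attr(schedule, "syringe_capacity")), con)
  writeLines(paste("time_s", "volume_uL", "syringe_conc_uM", sep = delim), con)
  writeLines(paste(format(schedule$time_s, digits = 17, trim = TRUE, scientific = FALSE),
                   format(schedule$volume_uL, digits = 17, trim = TRUE),
                   format(schedule$syringe_conc_uM, digits = 17, trim = TRUE),
                   sep = delim), con)
  invisible(path)
}

#' Packaged injection protocols
#'
#' Returns one of the two iTC-200 titration protocols shipped with the
#' package: `"multi_lsa"`, 30 injections of 1 uL of 1 mM lignosulfonic acid
#' with 60 s spacing (the multiple-injection rate experiment), or
#' `"single_lsa"`, 2 injections of 5 uL of 0.1 mM lignosulfonic acid with
#' 1000 s spacing (the single-injection enthalpy experiment). Injection
#' times are offset by `t0`, the pre-injection equilibration.
#'
#' @param name `"multi_lsa"` or `"single_lsa"`.
#' @param t0 time of the first injection in s (default 300, after thermal
#'   equilibration; the instrument equilibrates within 250 s).
#' @return an [injection_schedule()].
#' @export
#' @examples
#' nrow(itc_protocol("multi_lsa"))
itc_protocol <- function(name = c("multi_lsa", "single_lsa"), t0 = 300) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_schedule.csv"),
                      package = "itckin", mustWork = TRUE)
  sch <- read_injection_schedule(path)
  injection_schedule(time = sch$time_s + t0, volume = sch$volume_uL,
                     syringe_conc = sch$syringe_conc_uM,
                     syringe_capacity = attr(sch, "syringe_capacity"))
}

#' Read a run configuration file
#'
#' YAML configuration holding the cell, assay, and instrument blocks plus a
#' seed. Recognised blocks: `cell` (volume_uL, enzyme_uM, buffer, MW_g_mol),
#' `assay` (wavelength_nm, extinction_M_cm, path_length_cm, reaction_volume_mL,
#' enzyme_mass_mg, pH, temperature_C), `instrument` (tau_s,
#' sample_interval_s), `seed`.
#'
#' @param path YAML file path.
#' @return a list with elements `cell` ([cell_config()]), `assay`
#'   ([assay_config()] or NULL), `instrument` (list), `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  cell <- if (!is.null(raw$cell))
    cell_config(volume = raw$cell$volume_uL %||% 200,
                E0 = raw$cell$enzyme_uM %||% 0,
                buffer = raw$cell$buffer %||% "",
                MW = raw$cell$MW_g_mol)
  else cell_config()
  assay <- if (!is.null(raw$assay))
    assay_config(wavelength = raw$assay$wavelength_nm,
                 extinction = raw$assay$extinction_M_cm,
                 path_length = raw$assay$path_length_cm %||% 1,
                 reaction_volume = raw$assay$reaction_volume_mL,
                 enzyme_mass = raw$assay$enzyme_mass_mg,
                 pH = raw$assay$pH %||% NA_real_,
                 temperature = raw$assay$temperature_C %||% NA_real_)
  else NULL
  list(cell = cell, assay = assay,
       instrument = raw$instrument %||% list(tau_s = 6, sample_interval_s = 5),
       seed = raw$seed)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an absorbance trace file
#'
#' Delimited text with columns `time_s` and `absorbance_AU`; header keys
#' `substrate_uM` (required) and optionally `wavelength_nm`,
#' `extinction_M_cm`, `path_length_cm`.
#'
#' @param path file path.
#' @param assay an [assay_config()]; if NULL it is built from header keys.
#' @return an [absorbance_trace()].
#' @export
read_absorbance_trace <- function(path, assay = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  hb <- read_header_block(path)
  require_columns(hb$data, c("time_s", "absorbance_AU"), path)
  if (is.null(hb$meta$substrate_uM))
    stop(sprintf("'%s': header key 'substrate_uM' is required", path), call. = FALSE)
  if (is.null(assay)) {
    if (is.null(hb$meta$extinction_M_cm))
      stop(sprintf("'%s': supply 'assay' or an 'extinction_M_cm' header key", path),
           call. = FALSE)
    assay <- assay_config(
      wavelength = as.numeric(hb$meta$wavelength_nm %||% 420),
      extinction = as.numeric(hb$meta$extinction_M_cm),
      path_length = as.numeric(hb$meta$path_length_cm %||% 1))
  }
  absorbance_trace(time = hb$data$time_s, absorbance = hb$data$absorbance_AU,
                   substrate_conc = as.numeric(hb$meta$substrate_uM),
                   assay = assay)
}
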