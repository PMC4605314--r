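# Readers and writers for the package's plain-text interchange formats:
# traces ('#' key=value metadata header + two columns), force-extension
# point sets, JSON records for fits, rates and landscapes, and experiment
# manifests. Writers emit 12 significant digits so every round trip is
# lossless to formatting precision.

.fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Write / read a constant-force trace
#'
#' Traces are delimited text: `#`-prefixed `key=value` metadata lines
#' (`force_pN`, `conc_nM`, plus anything in the trace's `meta`), a header,
#' and two tab-separated columns `time_s`, `dx_nm_per_bp`.
#'
#' @param trace a [threading_trace()].
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [threading_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "threading_trace"))
  meta <- c(list(force_pN = attr(trace, "force"),
                 conc_nM = attr(trace, "concentration")),
            attr(trace, "meta"))
  hdr <- sprintf("# %s=%s", names(meta),
                 vapply(meta, function(v)
                   if (is.numeric(v)) .fmt_num(v) else as.character(v), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "time_s\tdx_nm_per_bp"), con)
  writeLines(paste(.fmt_num(trace$time), .fmt_num(trace$dx), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  metal <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", metal)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- as.list(vals)
  names(meta) <- keys
  num <- suppressWarnings(as.numeric(vals))
  meta[!is.na(num)] <- num[!is.na(num)]
  d <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                         sep = "\t")
  force <- meta$force_pN; conc <- meta$conc_nM
  if (is.null(force) || is.null(conc))
    stop("trace file lacks force_pN / conc_nM metadata: ", path, call. = FALSE)
  meta$force_pN <- NULL; meta$conc_nM <- NULL
  threading_trace(d$time_s, d$dx_nm_per_bp, force, conc, meta = meta)
}

#' Write / read force-extension point sets
#'
#' Two tab-separated columns `force_pN`, `extension_nm_per_bp`, with
#' `#` comment lines permitted.
#'
#' @param points data frame with columns `force` and `extension`.
#' @param path file path.
#' @param comment optional comment line(s) written at the top.
#' @return `write_force_extension` returns `path` invisibly;
#'   `read_force_extension` returns a data frame with columns `force`,
#'   `extension`.
#' @export
write_force_extension <- function(points, path, comment = NULL) {
  stopifnot(all(c("force", "extension") %in% names(points)))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines("force_pN\textension_nm_per_bp", con)
  writeLines(paste(.fmt_num(points$force), .fmt_num(points$extension),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_force_extension
#' @export
read_force_extension <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  data.frame(force = d$force_pN, extension = d$extension_nm_per_bp)
}

#' Read a simulated experiment directory
#'
#' Loads every trace listed in the `manifest.json` of a directory written by
#' [simulate_experiment()] (or all `trace_*.tsv` files when no manifest is
#' present). Unreadable traces are skipped with a warning.
#'
#' @param dir directory path.
#' @return list with `traces` (list of [threading_trace()]) and `manifest`
#'   (data frame or `NULL`).
#' @export
read_experiment <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  man_path <- file.path(dir, "manifest.json")
  manifest <- NULL
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    manifest <- man$conditions
    files <- file.path(dir, manifest$file)
  } else {
    files <- list.files(dir, pattern = "^trace_.*\\.tsv$", full.names = TRUE)
  }
  if (!length(files)) stop("no trace files in ", dir, call. = FALSE)
  traces <- list()
  for (f in files) {
    tr <- try(read_trace(f), silent = TRUE)
    if (inherits(tr, "try-error")) {
      warning("skipping unreadable trace: ", f, call. = FALSE)
      next
    }
    traces[[length(traces) + 1L]] <- tr
  }
  list(traces = traces, manifest = manifest)
}

#' JSON serialisation of fits and parameter records
#'
#' `write_wlc_fit_json` records a WLC fit (estimates, uncertainties,
#' residual rms, number of points). `write_rates_json` / `read_rates_json`
#' round-trip an [elementary_rates()] object; `write_bell_json` /
#' `read_bell_json` a [bell_params()] object.
#'
#' @param fit a `"wlc_fit"`.
#' @param path file path.
#' @return writers return `path` invisibly; readers the reconstructed
#'   object.
#' @export
write_wlc_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "wlc_fit"))
  jsonlite::write_json(
    list(params = as.list(coef(fit)), uncertainties = as.list(fit$se),
         residual_rms = fit$residual_rms, n_points = fit$n,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wlc_fit_json
#' @param rates an [elementary_rates()].
#' @export
write_rates_json <- function(rates, path) {
  stopifnot(inherits(rates, "elementary_rates"))
  jsonlite::write_json(
    list(k1 = rates$k1, k_m1 = rates$k_m1, k2 = rates$k2, k_m2 = rates$k_m2,
         force = rates$force, se = as.list(rates$se)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wlc_fit_json
#' @export
read_rates_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  elementary_rates(x$k1, x$k_m1, x$k2, x$k_m2,
                   force = if (is.null(x$force)) NA_real_ else x$force,
                   se = if (length(x$se)) unlist(x$se))
}

#' @rdname write_wlc_fit_json
#' @param bp a [bell_params()].
#' @export
write_bell_json <- function(bp, path) {
  stopifnot(inherits(bp, "bell_params"))
  jsonlite::write_json(
    list(k0 = bp$k0, x_dagger = bp$x_dagger, se = as.list(bp$se)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wlc_fit_json
#' @export
read_bell_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bell_params(x$k0, x$x_dagger, se = if (length(x$se)) unlist(x$se))
}

#' Export a free-energy landscape
#'
#' Writes the five (label, elongation, energy) states as tab-separated text
#' or JSON (including the concentration and attempt-rate conventions).
#'
#' @param landscape an `"energy_landscape"`.
#' @param path file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path, format = c("tsv", "json")) {
  stopifnot(inherits(landscape, "energy_landscape"))
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# concentration_nM=%s attempt_rate_per_s=%s mono_convention=%s",
                       .fmt_num(attr(landscape, "concentration")),
                       .fmt_num(attr(landscape, "attempt_rate")),
                       attr(landscape, "mono_convention")), con)
    writeLines("label\telongation_nm\tenergy_kBT", con)
    writeLines(paste(landscape$label, .fmt_num(landscape$elongation),
                     .fmt_num(landscape$energy), sep = "\t"), con)
  } else {
    jsonlite::write_json(
      list(concentration_nM = attr(landscape, "concentration"),
           attempt_rate_per_s = attr(landscape, "attempt_rate"),
           mono_convention = attr(landscape, "mono_convention"),
           states = as.data.frame(landscape)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
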