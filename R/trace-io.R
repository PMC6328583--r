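#' Write a raw trace to a delimited text file
#'
#' The trace format is TSV with a `#`-prefixed key/value header carrying the
#' format version, chamber id, sample rate and the full transducer/geometry
#' calibration block, followed by the columns `time`, `flux`,
#' `stim_current`, `tag`. The format is deliberately plain text so that any
#' record can be inspected and asserted on directly.
#'
#' @param trace A `myo_trace` tibble (see [simulate_run()]).
#' @param path Output file path.
#' @param extra Named character vector of additional header keys (preserved
#'   on round trip).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, extra = NULL) {
  tr <- attr(trace, "transducer")
  geom <- attr(trace, "geometry")
  if (is.null(tr) || is.null(attr(trace, "sample_rate"))) {
    abort_format("trace is missing calibration metadata")
  }
  hdr <- c(
    format = "myoslice-trace v1",
    chamber_id = as.character(attr(trace, "chamber_id") %||% 1),
    sample_rate = format(attr(trace, "sample_rate"), digits = 15),
    spring_constant = format(tr$spring_constant, digits = 15),
    sensitivity = format(tr$sensitivity, digits = 15),
    baseline_flux = format(tr$baseline_flux, digits = 15),
    resolution = format(tr$resolution, digits = 15),
    length = format(geom$length %||% 5, digits = 15),
    width = format(geom$width %||% 5, digits = 15),
    thickness = format(geom$thickness %||% 0.3, digits = 15)
  )
  if (!is.null(extra)) hdr <- c(hdr, extra)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), unname(hdr)), con)
  writeLines(paste(c("time", "flux", "stim_current", "tag"),
                   collapse = "\t"), con)
  body <- sprintf("%.6f\t%.15e\t%g\t%s", trace$time, trace$flux,
                  trace$stim_current, trace$tag)
  writeLines(body, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a raw trace file
#'
#' Inverse of [write_trace()]; validates that the calibration block is
#' complete and that sample times are strictly increasing, and restores the
#' transducer/geometry attributes. Unknown header keys are preserved in the
#' `header` attribute.
#'
#' @param path Trace file path.
#' @return A `myo_trace` tibble.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  hdr_lines <- lines[is_hdr]
  kv <- regmatches(hdr_lines, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr_lines))
  keys <- vapply(kv, function(m) m[2], character(1))
  vals <- vapply(kv, function(m) m[3], character(1))
  header <- setNames(vals, keys)

  required <- c("sample_rate", "spring_constant", "sensitivity",
                "baseline_flux")
  missing <- setdiff(required, keys)
  if (length(missing)) {
    abort_format(sprintf("trace header is missing calibration keys: %s",
                         paste(missing, collapse = ", ")))
  }

  body <- lines[!is_hdr]
  cn <- strsplit(body[1], "\t")[[1]]
  df <- read.delim(text = paste(body[-1], collapse = "\n"), header = FALSE,
                   col.names = cn,
                   colClasses = c("numeric", "numeric", "numeric",
                                  "character"))
  df$tag[is.na(df$tag)] <- ""
  if (is.unsorted(df$time, strictly = TRUE)) {
    abort_format("trace sample times must be strictly increasing")
  }
  out <- as_tibble(df)
  attr(out, "transducer") <- spring_transducer(
    spring_constant = as.numeric(header["spring_constant"]),
    sensitivity = as.numeric(header["sensitivity"]),
    baseline_flux = as.numeric(header["baseline_flux"]),
    resolution = as.numeric(header["resolution"] %|na|% 0.5)
  )
  attr(out, "sample_rate") <- as.numeric(header["sample_rate"])
  attr(out, "chamber_id") <- as.integer(header["chamber_id"] %|na|% 1)
  if (all(c("length", "width", "thickness") %in% keys)) {
    attr(out, "geometry") <- slice_geometry(
      as.numeric(header["length"]), as.numeric(header["width"]),
      as.numeric(header["thickness"]))
  }
  attr(out, "header") <- header
  class(out) <- c("myo_trace", class(out))
  out
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Read or write a run configuration
#'
#' Run configurations are stored as YAML mirroring the [run_config()]
#' fields, plus optional `tissue` and `protocol` blocks whose entries
#' override the corresponding constructor defaults.
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a list with elements `config`
#'   ([run_config()]), `tissue` ([tissue_params()]) and `protocol`
#'   ([paired_pulse_protocol()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(run_config, y$run %||% list())
  tfields <- y$tissue %||% list()
  if (!is.null(tfields$geometry)) {
    tfields$geometry <- do.call(slice_geometry, tfields$geometry)
  }
  tis <- do.call(tissue_params, tfields)
  proto <- do.call(paired_pulse_protocol, y$protocol %||% list())
  list(config = cfg, tissue = tis, protocol = proto)
}

#' @rdname read_run_config
#' @param run,tissue,protocol Field lists (only the overridden entries need
#'   to be given).
#' @export
write_run_config <- function(path, run = list(), tissue = list(),
                             protocol = list()) {
  yaml::write_yaml(list(run = run, tissue = tissue, protocol = protocol),
                   path)
  invisible(path)
}
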