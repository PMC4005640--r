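# File formats: photon-stream CSV with the alternation scheme in header
# comments, long-format trajectory CSV, and a JSON results bundle. All floats
# are serialized at full precision so identical runs produce byte-identical
# outputs.

.photon_magic <- "#smfret-photons v1"

#' Write / read a photon stream
#'
#' Photon streams are stored as CSV (`t_us,detector` with integer microsecond
#' timestamps) preceded by `#`-prefixed header lines carrying the alternation
#' scheme, so a write/read round trip is lossless.
#'
#' @param stream a [photon_stream()].
#' @param path file path.
#' @return `write_photons` returns `path` invisibly; `read_photons` returns a
#'   [photon_stream()].
#' @export
write_photons <- function(stream, path) {
  .assert(inherits(stream, "photon_stream"), "stream must be a photon_stream")
  sch <- stream$scheme
  hdr <- c(.photon_magic,
           sprintf("#period_us=%.9g", sch$period_us),
           sprintf("#dex_window=%.9g,%.9g", sch$dex_window[1], sch$dex_window[2]),
           sprintf("#aex_window=%.9g,%.9g", sch$aex_window[1], sch$aex_window[2]),
           "t_us,detector")
  body <- sprintf("%.0f,%s", stream$timestamps, stream$detectors)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_photons
#' @export
read_photons <- function(path) {
  .assert(file.exists(path), "file '%s' does not exist", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_attr <- function(key, default) {
    m <- grep(sprintf("^#%s=", key), hdr, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(strsplit(sub(sprintf("^#%s=", key), "", m[1]), ",")[[1]])
  }
  def <- alternation_scheme()
  scheme <- alternation_scheme(
    period_us = get_attr("period_us", def$period_us)[1],
    dex_window = get_attr("dex_window", def$dex_window),
    aex_window = get_attr("aex_window", def$aex_window))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body)) body <- body[-1]  # column header row
  if (!length(body)) {
    warning(sprintf("'%s' contains no photons; returning an empty stream", path))
    return(photon_stream(numeric(0), character(0), scheme))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("parse error in '%s': malformed record at data row %d", path, bad[1]),
         call. = FALSE)
  }
  t_us <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  det <- vapply(parts, `[[`, character(1), 2L)
  if (anyNA(t_us)) {
    stop(sprintf("parse error in '%s': non-numeric timestamp at data row %d",
                 path, which(is.na(t_us))[1]), call. = FALSE)
  }
  d <- diff(t_us)
  if (length(d) && any(d <= 0)) {
    stop(sprintf("parse error in '%s': timestamps not strictly increasing at data row %d",
                 path, which(d <= 0)[1] + 1L), call. = FALSE)
  }
  if (!all(det %in% c("donor", "acceptor"))) {
    stop(sprintf("parse error in '%s': unknown detector label '%s' at data row %d",
                 path, det[!det %in% c("donor", "acceptor")][1],
                 which(!det %in% c("donor", "acceptor"))[1]), call. = FALSE)
  }
  photon_stream(t_us, det, scheme)
}

#' Write / read TIRF trajectories
#'
#' Long-format CSV with columns `molecule_id`, `frame`, `I_donor`,
#' `I_acceptor` (one or many molecules per file).
#'
#' @param trajs a [fret_trajectory()] or list of them.
#' @param path file path.
#' @param frame_period_ms frame period recorded for trajectories read back.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns a list of [fret_trajectory()].
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "fret_trajectory")) trajs <- list(trajs)
  df <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(molecule_id = tr$molecule_id, frame = seq_along(tr$I_d),
               I_donor = tr$I_d, I_acceptor = tr$I_a)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path, frame_period_ms = 100) {
  .assert(file.exists(path), "file '%s' does not exist", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "I_donor", "I_acceptor")
  if (!"molecule_id" %in% names(df)) df$molecule_id <- "mol1"
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  lapply(split(df, df$molecule_id), function(dd) {
    dd <- dd[order(dd$frame), ]
    fret_trajectory(dd$I_donor, dd$I_acceptor, frame_period_ms,
                    molecule_id = dd$molecule_id[1])
  })
}

#' Run configuration
#'
#' Flat named list of the parameters governing an analysis run; serialized
#' verbatim into every results bundle so runs are self-describing and
#' reproducible.
#'
#' @param seed integer seed.
#' @param ... further named scalar parameters.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = NULL, ...) {
  cfg <- c(list(seed = seed), list(...))
  structure(cfg, class = "run_config")
}

#' Write / read a results bundle
#'
#' A results bundle is a versioned JSON document containing per-stage
#' outputs plus the exact configuration used. Floats are serialized at full
#' precision; re-running with identical config and inputs reproduces
#' byte-identical output.
#'
#' @param results named list of stage outputs (data.frames become records).
#' @param config a [run_config()] (or plain named list).
#' @param path output JSON path.
#' @return `write_results` returns `path` invisibly; `read_results` returns
#'   the parsed bundle list.
#' @export
write_results <- function(results, config = run_config(), path) {
  bundle <- list(
    schema = "smfret-results/1",
    package_version = as.character(utils::packageVersion("smfret")),
    config = unclass(config),
    results = results)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  .assert(file.exists(path), "file '%s' does not exist", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
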