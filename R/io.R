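#' Read and write the package's tabular formats
#'
#' Trajectories travel as tidy TSV (`time_days`, `population`, `count`,
#' `replicate`, `condition`, `seeding_ratio`); copy-number series as a
#' BED-like segments TSV (`chromosome`, `start`, `end`, `copy_number`,
#' `sample_id`; 0-based half-open coordinates) plus a samples manifest TSV
#' (`sample_id`, `day`, `purity`, `marker_value`). Fits are serialized as
#' JSON.
#'
#' @param x object to write.
#' @param path,segments_path,manifest_path file paths.
#' @name costar_io
NULL

#' @rdname costar_io
#' @export
write_trajectory <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname costar_io
#' @export
read_trajectory <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname costar_io
#' @export
write_cn_series <- function(x, segments_path, manifest_path) {
  utils::write.table(x$segments, segments_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(segments_path, manifest_path))
}

#' @rdname costar_io
#' @export
read_cn_series <- function(segments_path, manifest_path) {
  out <- list(
    segments = utils::read.table(segments_path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE),
    manifest = utils::read.table(manifest_path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
  class(out) <- "cn_series"
  out
}

# JSON serialisation for fit objects: numbers at full precision, scalars
# unboxed, deterministic key order.
write_fit_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Validate input files against the package's schemas
#'
#' Per-file structural checks: required columns and types, non-negative
#' counts, 0-based half-open segment sanity (start < end, no overlaps
#' within a sample), purities in (0, 1], strictly increasing sampling
#' days. Warnings and fatal errors are distinguished in the report.
#'
#' @param paths character vector of file paths.
#' @param schemas character vector (recycled) of schema names:
#'   `"trajectory"`, `"segments"` or `"manifest"`.
#' @return `data.frame` with columns `file`, `schema`, `level`
#'   (`"ok"`, `"warning"`, `"fatal"`), `message`.
#' @export
validate_inputs <- function(paths, schemas) {
  schemas <- rep_len(schemas, length(paths))
  rows <- list()
  note <- function(file, schema, level, message) {
    rows[[length(rows) + 1L]] <<- data.frame(file = file, schema = schema,
                                             level = level,
                                             message = message)
  }
  for (i in seq_along(paths)) {
    p <- paths[i]; sc <- schemas[i]
    if (!file.exists(p)) {
      note(p, sc, "fatal", "file not readable")
      next
    }
    d <- tryCatch(utils::read.table(p, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE),
                  error = function(e) NULL)
    if (is.null(d)) {
      note(p, sc, "fatal", "could not parse as TSV")
      next
    }
    req <- switch(sc,
                  trajectory = c("time_days", "population", "count"),
                  segments = c("chromosome", "start", "end", "copy_number",
                               "sample_id"),
                  manifest = c("sample_id", "day", "purity"),
                  stop("unknown schema: ", sc))
    missing_cols <- setdiff(req, names(d))
    if (length(missing_cols)) {
      note(p, sc, "fatal",
           paste("missing columns:", paste(missing_cols, collapse = ", ")))
      next
    }
    ok <- TRUE
    if (sc == "trajectory") {
      if (any(!is.finite(d$count)) || any(d$count < 0)) {
        note(p, sc, "fatal", "counts must be finite and >= 0"); ok <- FALSE
      }
      if (!all(d$population %in% c("sensitive", "resistant"))) {
        note(p, sc, "warning", "unexpected population labels")
      }
    } else if (sc == "segments") {
      if (any(d$start >= d$end)) {
        note(p, sc, "fatal", "segments must satisfy start < end"); ok <- FALSE
      } else {
        for (sid in unique(d$sample_id)) {
          ds <- d[d$sample_id == sid, ]
          for (chr in unique(ds$chromosome)) {
            dc <- ds[ds$chromosome == chr, ]
            dc <- dc[order(dc$start), ]
            if (nrow(dc) > 1 && any(dc$start[-1] < dc$end[-nrow(dc)])) {
              note(p, sc, "fatal",
                   sprintf("overlapping segments in sample %s (%s)", sid, chr))
              ok <- FALSE
            }
          }
        }
      }
    } else if (sc == "manifest") {
      if (any(d$purity <= 0 | d$purity > 1)) {
        note(p, sc, "fatal", "purity must be in (0, 1]"); ok <- FALSE
      }
      dd <- d$day[order(d$day)]
      if (anyDuplicated(d$day)) {
        note(p, sc, "fatal", "duplicate sampling days"); ok <- FALSE
      } else if (is.unsorted(d$day)) {
        note(p, sc, "fatal", "sampling days are not monotone increasing")
        ok <- FALSE
      }
    }
    if (ok) note(p, sc, "ok", "valid")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
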