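#' Write analysis tables as TSV + JSON
#'
#' Each table is written both as a TSV (one file per table, full \code{\%.17g}
#' precision so numeric round-trips are bit-exact) and into one combined JSON
#' report. \code{read_report} reverses the operation.
#'
#' @param tables non-empty named list of data.frames (occupancy tables,
#'   force-response profiles, per-frame series...)
#' @param path output directory; created if needed
#' @return invisibly, the paths written.
#' @export
write_report <- function(tables, path) {
  if (!is.list(tables) || length(tables) == 0L)
    stop("tables must be a non-empty named list", call. = FALSE)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    stop("every table must be named", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    out <- file.path(path, paste0(nm, ".tsv"))
    fmt <- tab
    for (j in seq_along(fmt))
      if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]]))
        fmt[[j]] <- sprintf("%.17g", fmt[[j]])
    utils::write.table(fmt, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, out)
  }
  jpath <- file.path(path, "report.json")
  jsonlite::write_json(tables, jpath, dataframe = "columns", digits = NA,
                       na = "null")
  invisible(c(paths, jpath))
}

#' @rdname write_report
#' @param template optional named list of data.frames whose column types guide
#'   parsing (numeric columns read as numeric); by default types are inferred.
#' @return \code{read_report}: named list of data.frames.
#' @export
read_report <- function(path, template = NULL) {
  files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0L) stop("no .tsv tables under ", path, call. = FALSE)
  out <- list()
  for (f in files) {
    nm <- sub("\\.tsv$", "", basename(f))
    tab <- utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!is.null(template) && nm %in% names(template)) {
      ref <- template[[nm]]
      for (j in intersect(names(ref), names(tab))) {
        if (is.numeric(ref[[j]])) tab[[j]] <- as.numeric(tab[[j]])
        if (is.integer(ref[[j]])) tab[[j]] <- as.integer(tab[[j]])
      }
    }
    out[[nm]] <- tab
  }
  out
}

#' Published equilibrium H-bond occupancy table
#'
#' Loads the packaged table of the twelve key interface hydrogen bonds of the
#' equilibrated DNAM-1/CD155 complex, with mean occupancy (fraction of frames
#' the bond survives) and replicate spread for the wild-type complex and for
#' the D2-deleted (Delta-D2) construct. The K190-E71 pair involves a DNAM-1
#' D2 residue and therefore has occupancy exactly zero in Delta-D2.
#'
#' @return data.frame with columns \code{no}, \code{dnam1_residue},
#'   \code{cd155_residue}, \code{wt_occupancy}, \code{wt_sd},
#'   \code{dd2_occupancy}, \code{dd2_sd}.
#' @export
equilibrium_occupancy_table <- function() {
  path <- system.file("extdata", "equilibrium_hbond_occupancy.tsv",
                      package = "mechbond")
  if (!nzchar(path))
    stop("packaged occupancy table not found; is mechbond installed?",
         call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
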