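.plateCsvColumns <- c(.wellColumns, "time_min", "od600", "rfp")

fmtNum <- function(x, digits = 15) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "g"), x))
}

#' Write a plate run as long-format CSV
#'
#' One row per well and time point with columns well_id, construct,
#' iptg_mM, arabinose_pct, substrate, replicate, time_min, od600, rfp.
#' Numbers are formatted deterministically, so identical runs produce
#' byte-identical files. When the plate carries generator metadata (as
#' plates from [generatePlate()] do), a YAML sidecar
#' \code{<path>.yaml} records every generator parameter and the seed.
#'
#' @param plate a [PlateTimeSeries-class].
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @seealso [readPlateCsv()]
#' @export
writePlateCsv <- function(plate, path) {
  stopifnot(is(plate, "PlateTimeSeries"))
  wells <- wellInfo(plate)
  tg <- timeGrid(plate)
  od <- odMatrix(plate)
  rfp <- rfpMatrix(plate)
  nT <- length(tg)
  long <- data.frame(
    well_id = rep(wells$well_id, each = nT),
    construct = rep(wells$construct, each = nT),
    iptg_mM = fmtNum(rep(wells$iptg_mM, each = nT)),
    arabinose_pct = fmtNum(rep(wells$arabinose_pct, each = nT)),
    substrate = rep(wells$substrate, each = nT),
    replicate = rep(wells$replicate, each = nT),
    time_min = fmtNum(rep(tg, times = nrow(wells))),
    od600 = fmtNum(as.vector(od)),
    rfp = fmtNum(as.vector(rfp)))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  meta <- S4Vectors::metadata(plate)
  if (!is.null(meta$generator))
    yaml::write_yaml(meta$generator, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a plate run from long-format CSV
#'
#' Inverse of [writePlateCsv()]: validates the schema, checks that every
#' well shares one uniform time grid, and rebuilds the
#' [PlateTimeSeries-class]. A YAML sidecar \code{<path>.yaml}, if
#' present, is restored into the object metadata.
#'
#' @param path CSV path.
#' @return A [PlateTimeSeries-class].
#' @export
readPlateCsv <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse plate CSV: ", conditionMessage(e),
                        call. = FALSE))
  if (nrow(df) == 0) stop("plate CSV is empty")
  miss <- setdiff(.plateCsvColumns, colnames(df))
  if (length(miss))
    stop("plate CSV lacks columns: ", paste(miss, collapse = ", "))
  wellIds <- unique(df$well_id)
  ref <- sort(unique(df$time_min))
  checkTimeGrid(ref)
  mats <- lapply(wellIds, function(w) {
    g <- df[df$well_id == w, ]
    g <- g[order(g$time_min), ]
    if (length(g$time_min) != length(ref) || any(g$time_min != ref))
      stop(sprintf("ragged time grid: well '%s' does not match the %d",
                   w, length(ref)),
           "-point grid shared by the plate")
    g
  })
  od <- sapply(mats, function(g) g$od600)
  rfp <- sapply(mats, function(g) g$rfp)
  wells <- do.call(rbind, lapply(mats, function(g)
    g[1, .wellColumns, drop = FALSE]))
  rownames(wells) <- NULL
  wells$substrate <- as.logical(wells$substrate)
  wells$replicate <- as.integer(wells$replicate)
  meta <- list()
  side <- paste0(path, ".yaml")
  if (file.exists(side)) meta$generator <- yaml::read_yaml(side)
  PlateTimeSeries(ref, od, rfp, wells, metadata = meta)
}

#' Write an analysis results table as CSV
#'
#' Deterministic column order and fixed-precision floats (10 significant
#' digits), so reruns on the same inputs are byte-identical. An empty
#' result set produces a header-only file.
#'
#' @param results data.frame (e.g. from [identifyPlate()] or
#'   [plateReadouts()]).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeResultsCsv <- function(results, path) {
  out <- results
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmtNum(out[[j]], digits = 10)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
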