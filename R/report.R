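# CSV reporting: descriptor tables, the full QSPR report bundle, and the
# agreement report that regenerates the published tables from bundled data
# and flags every cell that differs from the printed value beyond its
# printed precision.

.write_report_csv <- function(d, path, force = FALSE, meta = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (file.exists(path) && !force)
    stop("refusing to overwrite ", path, " (use force = TRUE)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# topoQSPR %s | %s",
    as.character(utils::packageVersion("topoQSPR")),
    if (is.null(meta)) "report" else meta), con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a report or input CSV
#'
#' Reads the CSV dialect used throughout the package: header row, empty
#' field = missing, optional `#` comment lines (run metadata) before the
#' header. Round-trips every CSV the package writes.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readReportCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  na.strings = "")
}

#' Descriptor table for a set of molecules
#'
#' Computes all nine indices for each input molecule. Inputs may be
#' [MolecularGraph-class] or [EdgePartition-class] objects (a named list),
#' or paths to edge-list files (named by file basename).
#'
#' @param molecules named list of graphs/partitions, or character vector of
#'   edge-list file paths.
#' @param roundDigits NULL for full precision, or decimals for half-up
#'   presentation rounding.
#' @param file optional CSV output path.
#' @param force overwrite an existing file.
#' @return data.frame with column `name` plus the nine index columns in
#'   canonical order; written to `file` when given.
#' @export
indicesReport <- function(molecules, roundDigits = NULL, file = NULL,
                          force = FALSE) {
  if (length(molecules) == 0L) stop("no input molecules given")
  if (is.character(molecules)) {
    paths <- molecules
    molecules <- lapply(paths, readEdgeList)
    names(molecules) <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (is.null(names(molecules)) || any(!nzchar(names(molecules))))
    stop("molecules must be named")
  rows <- lapply(names(molecules), function(nm) {
    x <- molecules[[nm]]
    p <- if (is(x, "MolecularGraph")) edgePartition(x)
         else if (is(x, "EdgePartition")) x
         else stop("unsupported molecule object for '", nm, "'")
    vals <- computeAllIndices(p)
    if (!is.null(roundDigits)) vals <- roundHalfUp(vals, roundDigits)
    cbind(data.frame(name = nm), as.data.frame(as.list(vals)))
  })
  out <- do.call(rbind, rows)
  if (!is.null(file))
    .write_report_csv(out, file, force = force, meta = "descriptor table")
  out
}

#' Write the full QSPR report bundle
#'
#' Produces every table of the published analysis from a descriptor table
#' and a property table: nine per-index parameter tables
#' (`table_params_<index>.csv`), the correlation, standard-error and r^2
#' matrices (`table_correlation.csv`, `table_se.csv`, `table_r2.csv`), and
#' one actual-vs-predicted table per property
#' (`table_pred_<property>.csv`).
#'
#' @param ti descriptor data.frame (`name` + nine index columns).
#' @param props property data.frame (`name` + property columns).
#' @param outDir output directory, created if absent.
#' @param properties property columns to model.
#' @param coefDigits coefficient rounding for the prediction tables
#'   (default 3, the published convention).
#' @param force overwrite existing files.
#' @return invisibly, a character vector of the files written (17 for the
#'   default five properties).
#' @export
qsprReport <- function(ti, props, outDir,
                       properties = .modeled_properties, coefDigits = 3,
                       force = FALSE) {
  d <- merge(ti, props, by = "name", sort = FALSE)
  for (pr in properties) {
    if (sum(stats::complete.cases(d[[indexNames()[1L]]], d[[pr]])) < 3L)
      stop("insufficient data after join for property '", pr, "'")
  }
  written <- character()
  for (ix in indexNames()) {
    f <- file.path(outDir, sprintf("table_params_%s.csv", ix))
    .write_report_csv(regressionTable(ti, props, ix, properties), f,
      force = force, meta = sprintf("regression parameters, index %s", ix))
    written <- c(written, f)
  }
  mats <- list(correlation = correlationTable(ti, props, properties),
               se = seTable(ti, props, properties),
               r2 = r2Table(ti, props, properties))
  for (nm in names(mats)) {
    f <- file.path(outDir, sprintf("table_%s.csv", nm))
    m <- as.data.frame(mats[[nm]])
    .write_report_csv(cbind(index = rownames(mats[[nm]]), m), f,
      force = force, meta = sprintf("%s matrix (indices x properties)", nm))
    written <- c(written, f)
  }
  for (pr in properties) {
    f <- file.path(outDir, sprintf("table_pred_%s.csv", pr))
    .write_report_csv(predictionTable(ti, props, pr, coefDigits), f,
      force = force, meta = sprintf("actual vs predicted, property %s", pr))
    written <- c(written, f)
  }
  invisible(written)
}

# decimals printed in a numeric string ("101.327" -> 3, "78" -> 0)
.printed_decimals <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}

# TRUE when `value` rounds to the printed string at its own precision
.matches_printed <- function(value, printed) {
  dp <- .printed_decimals(printed)
  mapply(function(v, p, d) {
    isTRUE(all.equal(roundHalfUp(v, d), as.numeric(p), tolerance = 1e-9))
  }, value, printed, dp)
}

#' Regenerate the published tables and report agreement
#'
#' Recomputes, from the bundled descriptor and property tables, every
#' statistical quantity of the published analysis, writes the full report
#' bundle plus the descriptor rows for the two worked partitions, and emits
#' an agreement report (`agreement_report.csv`) comparing each recomputed
#' statistic with its printed value at the printed precision. Cells
#' involving a quantity in [knownDiscrepancies()] are cross-referenced to
#' that ledger.
#'
#' @param outDir output directory.
#' @param variant property-table variant, see [loadPropertyTable()].
#' @param force overwrite existing files.
#' @return invisibly, the agreement report data.frame (also written to
#'   `agreement_report.csv`): columns table, index, property, quantity,
#'   printed, computed, match, ledgered.
#' @export
reproducePublishedTables <- function(outDir, variant = "table2", force = FALSE) {
  ti <- loadTiTable()
  props <- loadPropertyTable(variant)
  qsprReport(ti, props, outDir, force = force)
  indicesReport(loadWorkedPartitions(), roundDigits = NULL,
    file = file.path(outDir, "worked_descriptors.csv"), force = force)

  pub <- .loadPublishedStats()
  ledgered_props <- c(polarity = "monobenzone polarity",
    refractivity = "azathioprine refractivity",
    molar_volume = "fluticasone molar volume")

  rows <- list()
  fits <- fitAllModels(ti, props)
  for (i in seq_len(nrow(pub$params))) {
    row <- pub$params[i, ]
    f <- fits[[row$index]][[row$property]]
    comp <- c(A = f@intercept, b = f@slope, r = f@r, r2 = f@r2, F = f@fstat,
              p = f@pvalue)
    for (q in names(comp)) {
      rows[[length(rows) + 1L]] <- data.frame(
        table = "stat_params", index = row$index, property = row$property,
        quantity = q, printed = row[[q]],
        computed = comp[[q]],
        match = .matches_printed(comp[[q]], row[[q]]),
        ledgered = row$property %in% names(ledgered_props))
    }
  }
  for (tab in c("correlation", "se", "r2")) {
    stat <- c(correlation = "r", se = "se", r2 = "r2")[[tab]]
    m <- .fit_matrix(fits, stat)
    pubm <- pub[[tab]]
    for (i in seq_len(nrow(pubm))) for (pr in .modeled_properties) {
      comp <- m[pubm$index[i], pr]
      rows[[length(rows) + 1L]] <- data.frame(
        table = tab, index = pubm$index[i], property = pr, quantity = stat,
        printed = pubm[i, pr], computed = comp,
        match = .matches_printed(comp, pubm[i, pr]),
        ledgered = pr %in% names(ledgered_props) ||
          (tab == "correlation" && pubm$index[i] == "H" && pr == "polarity"))
    }
  }
  # worked partitions vs printed descriptor rows (2-decimal convention)
  worked <- loadWorkedPartitions()
  display <- c(psoralen = "Psoralen", azathioprine = "Azathioprine")
  for (drug in names(worked)) {
    vals <- computeAllIndices(worked[[drug]])
    printed_row <- ti[ti$name == display[[drug]], indexNames()]
    for (ix in indexNames()) {
      ledg <- (drug == "azathioprine" && ix %in% c("GA", "ABC")) ||
              (drug == "psoralen" && ix == "RA")
      rows[[length(rows) + 1L]] <- data.frame(
        table = "descriptors", index = ix, property = NA_character_,
        quantity = drug, printed = format(printed_row[[ix]]),
        computed = vals[[ix]],
        match = .matches_printed(vals[[ix]], format(printed_row[[ix]])),
        ledgered = ledg)
    }
  }
  report <- do.call(rbind, rows)
  .write_report_csv(report, file.path(outDir, "agreement_report.csv"),
    force = force,
    meta = sprintf("agreement with published tables; variant=%s", variant))
  invisible(report)
}
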