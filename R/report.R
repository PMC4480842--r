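#' Write a decomposition report to JSON or TSV
#'
#' Serializes the stable and regional population tables (name, weight,
#' membership fraction, coordinates), the mode, the unmixed and
#' prior-discarded flags, and the minimax error.  Numeric values are
#' written with 6 decimal places; [read_report()] restores an equal
#' report at that precision.
#'
#' @param result a `readmix_report` (from [run_readmix()]).
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "readmix_report"))
  r6 <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = 6)
    df
  }
  stable <- r6(result$stable)
  regional <- r6(result$regional)
  if (format == "json") {
    obj <- list(mode = result$mode,
                unmixed = result$unmixed,
                prior_discarded = result$prior_discarded,
                minimax_error = round(result$minimax_error, 6),
                stable = stable, regional = regional)
    ok <- tryCatch({
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                          conditionMessage(ok))
  } else {
    con <- tryCatch(file(path, "w"), error = function(e) {
      stop("cannot write report to ", path, ": ", conditionMessage(e))
    })
    on.exit(close(con))
    writeLines(c(sprintf("# mode=%s", result$mode),
                 sprintf("# unmixed=%s", result$unmixed),
                 sprintf("# prior_discarded=%s", result$prior_discarded),
                 sprintf("# minimax_error=%.6f", result$minimax_error)), con)
    stable$section <- if (nrow(stable)) "stable" else character(0)
    names(regional)[names(regional) == "mean_weight"] <- "weight"
    regional$section <- if (nrow(regional)) "regional" else character(0)
    tab <- rbind(stable, regional)
    tab <- tab[, c("section", "population", "weight", "membership",
                   "lat", "lon"), drop = FALSE]
    utils::write.table(format(tab, digits = 15), con, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a decomposition report written by [write_report()]
#'
#' @param path file path.
#' @param format `"json"`, `"tsv"`, or `"auto"` (from the extension).
#' @return a `readmix_report` (without the underlying solution list,
#'   which is not serialized).
#' @export
read_report <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv"
              else "json"
  }
  empty <- function(wcol) {
    stats::setNames(
      data.frame(character(0), numeric(0), numeric(0), numeric(0),
                 numeric(0), stringsAsFactors = FALSE),
      c("population", wcol, "membership", "lat", "lon"))
  }
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    stable <- if (length(obj$stable)) as.data.frame(obj$stable)
              else empty("weight")
    regional <- if (length(obj$regional)) as.data.frame(obj$regional)
                else empty("mean_weight")
    out <- list(stable = stable, regional = regional,
                mode = obj$mode, prior_discarded = obj$prior_discarded,
                unmixed = obj$unmixed,
                minimax_error = obj$minimax_error,
                solutions = NULL, K = NA_integer_)
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "=", fixed = TRUE))
    meta <- stats::setNames(kv[, 2], kv[, 1])
    tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    stable <- tab[tab$section == "stable",
                  c("population", "weight", "membership", "lat", "lon")]
    rownames(stable) <- NULL
    regional <- tab[tab$section == "regional",
                    c("population", "weight", "membership", "lat", "lon")]
    names(regional)[2] <- "mean_weight"
    rownames(regional) <- NULL
    if (nrow(stable) == 0L) stable <- empty("weight")
    if (nrow(regional) == 0L) regional <- empty("mean_weight")
    out <- list(stable = stable, regional = regional,
                mode = unname(meta["mode"]),
                prior_discarded = as.logical(meta["prior_discarded"]),
                unmixed = as.logical(meta["unmixed"]),
                minimax_error = as.numeric(meta["minimax_error"]),
                solutions = NULL, K = NA_integer_)
  }
  structure(out, class = "readmix_report")
}
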