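#' Validate a raw vector as admixture proportions
#'
#' An admixture vector holds K nonnegative proportions that sum to one,
#' i.e. a point on the standard (K-1)-simplex.  Published admixture
#' tables are usually rounded, so vectors whose sum deviates from 1 by
#' at most `tol` are renormalized to sum exactly to 1; larger deviations
#' and negative entries are rejected.
#'
#' @param v numeric vector of length >= 2, finite entries.
#' @param tol maximum tolerated deviation of `sum(v)` from 1 before
#'   renormalization (default 0.01, accommodating tables rounded to 2-3
#'   decimal places).
#' @return the validated vector, renormalized to sum exactly to 1.
#' @examples
#' validate_simplex(c(0.201, 0.801))  # divided by 1.002
#' @export
validate_simplex <- function(v, tol = 0.01) {
  if (!is.numeric(v) || length(v) < 2L) {
    stop("admixture vector must be numeric with at least 2 components")
  }
  if (any(!is.finite(v))) {
    stop("admixture vector contains non-finite values")
  }
  if (any(v < 0)) {
    stop("admixture vector contains negative proportions")
  }
  s <- sum(v)
  if (abs(s - 1) > tol) {
    stop(sprintf("admixture proportions sum to %.6g, outside 1 +/- %g", s, tol))
  }
  # renormalization must be a fixed point: vectors already summing to 1
  # at machine precision are returned unchanged, so repeated validation
  # (e.g. read -> write -> read) is idempotent
  if (abs(s - 1) <= 1e-12) v else v / s
}

normalize_longitude <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Construct a reference panel
#'
#' A reference panel holds N modern populations, each with a name,
#' geographic coordinates (decimal degrees, WGS84), a K-component
#' admixture vector, and optionally per-component variances and the
#' number of genotyped individuals the population mean was computed
#' from.
#'
#' @param population character vector of unique population names.
#' @param lat,lon numeric coordinates; latitude in \[-90, 90\], longitude
#'   normalized into (-180, 180\].
#' @param Q N x K matrix of admixture proportions; each row is validated
#'   with [validate_simplex()].
#' @param V optional N x K matrix of per-component variances (>= 0).
#' @param sample_n optional integer vector of per-population sample sizes.
#' @param group optional character vector of ancestry-group labels, used
#'   by the synthetic benchmark panels.
#' @return an object of class `readmix_panel`: a list with elements
#'   `population`, `lat`, `lon`, `Q`, `V`, `sample_n`, `group`, `K`, `N`.
#' @export
readmix_panel <- function(population, lat, lon, Q, V = NULL,
                          sample_n = NULL, group = NULL) {
  Q <- as.matrix(Q)
  N <- nrow(Q)
  K <- ncol(Q)
  if (K < 2L) stop("panel must have K >= 2 admixture components")
  if (N < 1L) stop("panel must contain at least one population")
  population <- as.character(population)
  if (length(population) != N) stop("population names do not match Q rows")
  if (anyDuplicated(population)) {
    stop("duplicate population names: ",
         paste(unique(population[duplicated(population)]), collapse = ", "))
  }
  if (length(lat) != N || length(lon) != N) {
    stop("coordinate vectors do not match the number of populations")
  }
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  lon <- normalize_longitude(as.numeric(lon))
  for (i in seq_len(N)) {
    Q[i, ] <- tryCatch(validate_simplex(Q[i, ]),
                       error = function(e) {
                         stop(sprintf("population '%s' (row %d): %s",
                                      population[i], i, conditionMessage(e)),
                              call. = FALSE)
                       })
  }
  if (!is.null(V)) {
    V <- as.matrix(V)
    if (!all(dim(V) == dim(Q))) stop("variance matrix V must be N x K")
    if (any(V < 0)) stop("negative variances are not allowed")
  }
  if (!is.null(sample_n)) {
    sample_n <- as.integer(sample_n)
    if (length(sample_n) != N || any(sample_n < 1L, na.rm = TRUE)) {
      stop("sample_n must contain positive integers, one per population")
    }
  }
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != N) stop("group labels must match the number of populations")
  }
  dimnames(Q) <- list(population, NULL)
  if (!is.null(V)) dimnames(V) <- list(population, NULL)
  structure(list(population = population,
                 lat = as.numeric(lat), lon = lon,
                 Q = Q, V = V, sample_n = sample_n, group = group,
                 K = K, N = N),
            class = "readmix_panel")
}

#' @export
print.readmix_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d populations, K = %d components\n", x$N, x$K))
  cat(sprintf("  variances: %s; sample sizes: %s; groups: %s\n",
              if (is.null(x$V)) "absent" else "present",
              if (is.null(x$sample_n)) "absent" else "present",
              if (is.null(x$group)) "absent" else "present"))
  cat("  populations: ", paste(head(x$population, 8L), collapse = ", "),
      if (x$N > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

panel_index <- function(panel, names) {
  idx <- match(names, panel$population)
  if (anyNA(idx)) {
    stop("unknown population name(s): ",
         paste(names[is.na(idx)], collapse = ", "))
  }
  idx
}

infer_dialect <- function(path, dialect) {
  if (dialect != "auto") return(dialect)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
}

#' Read a reference panel from CSV or TSV
#'
#' The file must have a header row with columns `population`, `lat`,
#' `lon` and the admixture components `c1..cK`; optional columns are the
#' per-component variances `v1..vK`, the per-population sample size `n`,
#' and an ancestry-group label `group`.  Rows whose components sum to
#' within 0.01 of 1 are renormalized to sum exactly to 1.
#'
#' @param path file path.
#' @param dialect `"csv"`, `"tsv"`, or `"auto"` (default; inferred from
#'   the file extension).
#' @return a [readmix_panel()].
#' @export
read_panel <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- infer_dialect(path, match.arg(dialect))
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.table(path, header = TRUE,
                          sep = if (dialect == "csv") "," else "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("population", "lat", "lon")
  if (!all(req %in% names(df))) {
    stop("panel header must contain columns: ", paste(req, collapse = ", "))
  }
  K <- 0L
  while (sprintf("c%d", K + 1L) %in% names(df)) K <- K + 1L
  if (K < 2L) stop("panel must contain component columns c1..cK with K >= 2")
  ccols <- sprintf("c%d", seq_len(K))
  vcols <- sprintf("v%d", seq_len(K))
  V <- if (all(vcols %in% names(df))) as.matrix(df[, vcols]) else NULL
  sample_n <- if ("n" %in% names(df)) df$n else NULL
  group <- if ("group" %in% names(df)) df$group else NULL
  readmix_panel(df$population, df$lat, df$lon, as.matrix(df[, ccols]),
                V = V, sample_n = sample_n, group = group)
}

#' Write a reference panel to CSV or TSV
#'
#' Inverse of [read_panel()]; `read_panel(write_panel(p, f))` reproduces
#' `p` up to numeric formatting.
#'
#' @inheritParams read_panel
#' @param panel a [readmix_panel()].
#' @export
write_panel <- function(panel, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- infer_dialect(path, match.arg(dialect))
  df <- data.frame(population = panel$population,
                   lat = panel$lat, lon = panel$lon,
                   check.names = FALSE, stringsAsFactors = FALSE)
  Q <- panel$Q
  colnames(Q) <- sprintf("c%d", seq_len(panel$K))
  df <- cbind(df, Q)
  if (!is.null(panel$V)) {
    V <- panel$V
    colnames(V) <- sprintf("v%d", seq_len(panel$K))
    df <- cbind(df, V)
  }
  if (!is.null(panel$sample_n)) df$n <- panel$sample_n
  if (!is.null(panel$group)) df$group <- panel$group
  # 17 significant digits: doubles survive the text round trip exactly,
  # so read -> write -> read is idempotent at the byte level
  isnum <- vapply(df, is.double, logical(1))
  df[isnum] <- lapply(df[isnum], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ADMIXTURE-style Q matrix
#'
#' Plain whitespace-separated numeric matrix, one individual per line,
#' K columns, no header — the format written by ADMIXTURE in supervised
#' mode.  Every row is validated as admixture proportions.
#'
#' @param path file path.
#' @return numeric matrix with one validated admixture vector per row.
#' @export
read_q_matrix <- function(path) {
  if (!file.exists(path)) stop("Q matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("Q matrix file is empty")
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  if (length(unique(len)) != 1L) {
    stop(sprintf("ragged Q matrix: line %d has %d fields, expected %d",
                 which(len != len[1L])[1L], len[len != len[1L]][1L], len[1L]))
  }
  Q <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              nrow = length(lines), byrow = TRUE)
  if (anyNA(Q)) stop("non-numeric entry in Q matrix")
  for (i in seq_len(nrow(Q))) {
    Q[i, ] <- tryCatch(validate_simplex(Q[i, ]),
                       error = function(e) {
                         stop(sprintf("Q matrix line %d: %s", i,
                                      conditionMessage(e)), call. = FALSE)
                       })
  }
  Q
}
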