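#' Read optimizer settings from an INI-style file
#'
#' Accepts `key = value` lines (section headers in square brackets and
#' `;`/`#` comments are ignored) whose keys mirror the [de_config()]
#' arguments: `NP`, `S_const`, `crossover_p`, `G_max`, `M`,
#' `recombination`, `substitution_period`, `substitution_count`, `seed`,
#' `workers`.  Unknown keys raise an error; absent keys keep their
#' defaults.
#'
#' @param path INI file path.
#' @param base a [de_config()] supplying defaults.
#' @return a [de_config()].
#' @export
read_de_config <- function(path, base = de_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  if (length(lines) == 0L) return(base)
  parts <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed config line: ", lines[lengths(parts) != 2L][1L])
  }
  keys <- trimws(vapply(parts, `[`, character(1), 1L))
  vals <- trimws(vapply(parts, `[`, character(1), 2L))
  numeric_keys <- c("NP", "S_const", "crossover_p", "G_max", "M",
                    "substitution_period", "substitution_count", "seed",
                    "workers")
  known <- c(numeric_keys, "recombination")
  if (any(!keys %in% known)) {
    stop("unknown config key(s): ",
         paste(setdiff(keys, known), collapse = ", "))
  }
  args <- unclass(base)
  for (i in seq_along(keys)) {
    args[[keys[i]]] <- if (keys[i] %in% numeric_keys) as.numeric(vals[i])
                       else vals[i]
  }
  do.call(de_config, args)
}
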