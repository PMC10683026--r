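## Export of MD-engine configuration fragments (GROMACS .mdp dialect) for
## the steering and adaptive-bias stages, plus a parser so every export
## round-trips through its own reader.

#' Per-condition adaptive-bias defaults
#'
#' Returns the packaged adaptive-weight-histogram (AWH) parameter set for
#' a simulation condition: shared settings (cover diameter 0.4 nm, energy
#' cutoff 120 kJ/mol, 10 steps per sample, 10 samples per update, growth
#' factor 2.0, CV ranges 0.4-1.3 nm and 0.3-1.0 nm) plus the per-condition
#' force constants and diffusion coefficients from the packaged defaults
#' table.
#'
#' @param condition one of the packaged conditions (default "apo"); see
#'   `awhConditions()`.
#' @return named character vector of .mdp keys and values.
#' @export
awhDefaults <- function(condition = "apo") {
  tab <- utils::read.delim(
    system.file("extdata", "awh_parameters.tsv", package = "CoevCV"),
    stringsAsFactors = FALSE, colClasses = "character")
  row <- tab[tab$condition == condition, , drop = FALSE]
  if (!nrow(row))
    stop("unknown condition '", condition, "'; see awhConditions()")
  c("awh" = "yes",
    "awh-nstsample" = "10",
    "awh-nsamples-update" = "10",
    "awh-nbias" = "1",
    "awh1-error-init" = "5",
    "awh1-energy-cutoff" = "120",
    "awh1-growth-factor" = "2.0",
    "awh1-ndim" = "2",
    "awh1-dim1-coord-provider" = "pull",
    "awh1-dim1-start" = "0.4",
    "awh1-dim1-end" = "1.3",
    "awh1-dim1-cover-diameter" = "0.4",
    "awh1-dim1-force-constant" = row$cv1_force_constant,
    "awh1-dim1-diffusion" = row$cv1_diffusion,
    "awh1-dim2-coord-provider" = "pull",
    "awh1-dim2-start" = "0.3",
    "awh1-dim2-end" = "1.0",
    "awh1-dim2-cover-diameter" = "0.4",
    "awh1-dim2-force-constant" = row$cv2_force_constant,
    "awh1-dim2-diffusion" = row$cv2_diffusion)
}

#' @rdname awhDefaults
#' @export
awhConditions <- function() {
  tab <- utils::read.delim(
    system.file("extdata", "awh_parameters.tsv", package = "CoevCV"),
    stringsAsFactors = FALSE)
  tab$condition
}

.formatNum <- function(x) format(x, trim = TRUE, scientific = FALSE)

#' Export an MD-engine configuration fragment
#'
#' Serialises a [PullCoordinateSet-class] and/or an AWH parameter set into
#' a GROMACS .mdp-style key/value fragment. Each cluster becomes one
#' umbrella pull coordinate whose force constant is the per-contact force
#' constant times the number of member pairs; pair lists and weights are
#' carried in companion keys. The output is canonical: parsing it with
#' [parseMdConfig()] and re-exporting reproduces the text byte for byte.
#'
#' @param pullSet optional [PullCoordinateSet-class].
#' @param awh optional named character vector as from [awhDefaults()].
#' @param dialect only "gromacs" is supported.
#' @return character scalar, the configuration text.
#' @export
exportMdConfig <- function(pullSet = NULL, awh = NULL,
                           dialect = "gromacs") {
  if (!identical(dialect, "gromacs"))
    stop("unknown dialect '", dialect, "'")
  kv <- character(0)
  if (!is.null(pullSet)) {
    stopifnot(is(pullSet, "PullCoordinateSet"))
    n <- length(pullSet@clusters)
    kv <- c(kv, "pull" = "yes", "pull-ncoords" = .formatNum(n))
    for (k in seq_len(n)) {
      cl <- pullSet@clusters[[k]]
      p <- sprintf("pull-coord%d", k)
      kv <- c(kv, stats::setNames(c(
        "umbrella", "transformation-distance",
        .formatNum(pullSet@forceConstant * nrow(cl)),
        .formatNum(pullSet@target),
        paste(sprintf("%d:%d", cl$resnoI, cl$resnoJ), collapse = ","),
        paste(.formatNum(round(cl$weight, 6)), collapse = ",")),
        paste0(p, c("-type", "-geometry", "-k", "-init",
                    "-pairs", "-weights"))))
    }
  }
  if (!is.null(awh)) kv <- c(kv, awh)
  paste0(paste(names(kv), unname(kv), sep = " = ", collapse = "\n"), "\n")
}

#' Parse an .mdp-style configuration fragment
#'
#' @param text configuration text as produced by [exportMdConfig()] (or
#'   any `key = value` .mdp fragment; comments and blank lines ignored).
#' @return named character vector of keys and values.
#' @export
parseMdConfig <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(m) != 2L
  if (any(bad)) stop("unparseable line(s): ",
                     paste(lines[bad], collapse = "; "))
  stats::setNames(trimws(vapply(m, `[`, "", 2L)),
                  trimws(vapply(m, `[`, "", 1L)))
}

#' Re-export a parsed configuration
#'
#' `exportMdConfig()` emits canonical `key = value` lines, so
#' `reexportMdConfig(parseMdConfig(x))` is byte-identical to `x` for any
#' export of this package.
#'
#' @param kv named character vector from [parseMdConfig()].
#' @return character scalar.
#' @export
reexportMdConfig <- function(kv) {
  paste0(paste(names(kv), unname(kv), sep = " = ", collapse = "\n"), "\n")
}
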