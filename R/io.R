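# Configuration parsing and deterministic tabular output.

#' Parse a run configuration from YAML (or a list)
#'
#' Recognised keys: `n`, `b`, `d`, `M`, `alpha`, `kind`
#' (`"fecundity"`/`"survival"`), `cost`, `seed`, `out`, `grid` (a list of
#' axis vectors). A landscape is given either explicitly via `b` (and
#' optionally `d`) or through the monotonic family via `M`, `alpha`, `kind`.
#' Defaults: `d` all zero, `cost` `"costless"`. All violations are collected
#' and reported together.
#'
#' @param source Path to a YAML file, or a named list of the same keys.
#' @return Object of class `"run_config"`: the validated, default-filled
#'   list.
#' @export
parse_config <- function(source) {
  cfg <- if (is.character(source)) {
    if (!file.exists(source)) stop("config file not found: ", source)
    yaml::read_yaml(source)
  } else if (is.list(source)) source
  else stop("source must be a file path or a list")
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; undo that
  names(cfg)[names(cfg) == "FALSE"] <- "n"
  known <- c("n", "b", "d", "M", "alpha", "kind", "cost", "seed", "out", "grid")
  errs <- character(0)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    errs <- c(errs, paste("unknown keys:", paste(unknown, collapse = ", ")))
  if (is.null(cfg$n)) errs <- c(errs, "key 'n' is required")
  else if (length(cfg$n) != 1 || cfg$n < 2 || cfg$n != round(cfg$n))
    errs <- c(errs, "'n' must be an integer >= 2")
  cfg$cost <- tryCatch(match_cost(cfg$cost %||% "costless"),
                       error = function(e) {
                         errs <<- c(errs, conditionMessage(e)); NULL
                       })
  has_b <- !is.null(cfg$b)
  has_mono <- !is.null(cfg$M) || !is.null(cfg$alpha)
  if (has_b && has_mono)
    errs <- c(errs, "give either an explicit 'b' or a monotonic (M, alpha) spec, not both")
  if (has_b && !is.null(cfg$n) && length(cfg$b) != cfg$n - 1)
    errs <- c(errs, paste0("'b' has length ", length(cfg$b),
                           " but n = ", cfg$n, " requires length ", cfg$n - 1))
  if (!is.null(cfg$d) && has_b && length(cfg$d) != length(cfg$b))
    errs <- c(errs, paste0("'d' has length ", length(cfg$d),
                           " but 'b' has length ", length(cfg$b)))
  if (has_mono) {
    if (is.null(cfg$M) || is.null(cfg$alpha))
      errs <- c(errs, "a monotonic spec needs both 'M' and 'alpha'")
    cfg$kind <- cfg$kind %||% "fecundity"
    if (!cfg$kind %in% c("fecundity", "survival"))
      errs <- c(errs, "'kind' must be \"fecundity\" or \"survival\"")
  }
  if (!has_b && !has_mono)
    errs <- c(errs, "no landscape: give 'b' (and optionally 'd') or 'M' and 'alpha'")
  if (length(errs) > 0)
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  if (has_b && is.null(cfg$d)) cfg$d <- rep(0, length(cfg$b))
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the fitness landscape described by a run configuration
#'
#' @param config A `"run_config"` from [parse_config()].
#' @return A `"fitness_landscape"`.
#' @export
config_landscape <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$b)) {
    fitness_landscape(b = config$b, d = config$d)
  } else {
    monotonic_landscape(config$n, M = config$M, alpha = config$alpha,
                        kind = config$kind)
  }
}

#' Write a data frame as a deterministic TSV
#'
#' Column order is preserved, numeric values are formatted with 12
#' significant digits (`%.12g`), and the file is newline-terminated, so two
#' runs producing the same data produce byte-identical files.
#'
#' @param records A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  fmt_col <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.12g", x) else as.character(x)
  }
  body <- vapply(records, fmt_col, character(nrow(records)))
  lines <- c(paste(names(records), collapse = "\t"),
             if (nrow(records) > 0)
               apply(matrix(body, nrow = nrow(records)), 1, paste, collapse = "\t"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("no such table: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Dump a projection matrix as a labelled TSV
#'
#' @param A Projection matrix (rows/columns labelled by group size).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(A, path) {
  df <- as.data.frame(A)
  names(df) <- paste0("size_", seq_len(ncol(A)))
  df <- cbind(data.frame(size = seq_len(nrow(A))), df)
  write_table(df, path)
}

#' Derive a per-task seed from a global seed
#'
#' A counter-based derivation so that adding tasks does not perturb the
#' random streams of existing ones. Results stay below 2^31.
#'
#' @param seed Global integer seed.
#' @param index Task counter (non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 8191) %% 2147483629)
}
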