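#' Read a wide-format longitudinal dataset from CSV
#'
#' Expects a header of \code{"y{i}_t{j}"} names, occasion-major with
#' indicators varying fastest, one subject per row, no missing cells.
#' Indicator and occasion counts are inferred from the header. A dataset
#' with fewer than five occasions loads with a warning: a two-phase
#' piecewise growth model is not identified on it.
#'
#' @param path CSV file path.
#' @return A \code{"pgm_data"} matrix; see [simulate_pgm()].
#' @export
read_pgm_data <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  layout <- parse_layout(colnames(df))
  y <- as.matrix(df)
  if (!is.numeric(y))
    stop("non-numeric values in ", path, call. = FALSE)
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)[1, ]
    stop("missing cell at row ", bad[1], ", column ",
         colnames(y)[bad[2]], " of ", path, call. = FALSE)
  }
  if (layout$n_occasions < 5L)
    warning("only ", layout$n_occasions, " occasions: at least five are ",
            "needed to identify a two-phase piecewise growth model",
            call. = FALSE)
  structure(y, n_indicators = layout$n_indicators,
            n_occasions = layout$n_occasions,
            class = c("pgm_data", "matrix", "array"))
}

#' Write a wide-format longitudinal dataset to CSV
#'
#' One subject per row under the \code{"y{i}_t{j}"} header. Optionally
#' writes a JSON sidecar (same path with extension \code{.meta.json})
#' recording the generating-cell metadata.
#'
#' @param data A \code{"pgm_data"} matrix.
#' @param path Output CSV path.
#' @param metadata Optional named list (e.g. cell, seed, population truth)
#'   for the sidecar; omitted when \code{NULL}.
#' @return \code{path}, invisibly.
#' @export
write_pgm_data <- function(data, path, metadata = NULL) {
  parse_layout(colnames(data))
  utils::write.csv(as.data.frame(unclass(data)), path, row.names = FALSE)
  if (!is.null(metadata)) {
    side <- sub("\\.csv$", "", path)
    jsonlite::write_json(metadata, paste0(side, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read and validate a study configuration file
#'
#' YAML or JSON (by extension). Recognised top-level keys: \code{design}
#' (\code{time_codes}, \code{knot}), \code{generating} (\code{growth_means},
#' \code{growth_vars}, \code{n_indicators}, \code{target_rel}),
#' \code{study} (\code{sample_sizes}, \code{os_levels}, \code{models},
#' \code{n_replications}, \code{base_seed}). Unknown keys are rejected so
#' typos fail before any computation. All keys are optional; defaults are
#' the package defaults.
#'
#' @param path Config file path.
#' @return Named list of arguments ready for [run_study()], plus
#'   \code{generating} and \code{design} objects.
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg)) cfg <- list()
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      stop("unknown key(s) in ", where, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_keys(cfg, c("design", "generating", "study"), "config")
  check_keys(cfg$design, c("time_codes", "knot"), "design block")
  check_keys(cfg$generating,
             c("growth_means", "growth_vars", "n_indicators", "target_rel"),
             "generating block")
  check_keys(cfg$study,
             c("sample_sizes", "os_levels", "models", "n_replications",
               "base_seed"),
             "study block")
  des <- pgm_design(
    time_codes = cfg$design$time_codes %||% 0:6,
    knot = cfg$design$knot %||% 3)
  gen <- generating_design(
    design = des,
    growth = growth_parameters(
      cfg$generating$growth_means %||% c(10, 2, 1),
      cfg$generating$growth_vars %||% c(1, 0.25, 0.25)),
    n_indicators = cfg$generating$n_indicators %||% 2,
    target_rel = cfg$generating$target_rel %||% 0.8)
  list(design = des,
       generating = gen,
       n = cfg$study$sample_sizes %||% c(100, 250, 500),
       os_levels = cfg$study$os_levels %||% c(0, 0.10, 0.25, 0.40),
       models = cfg$study$models %||% c("si", "mi"),
       n_replications = cfg$study$n_replications %||% 200,
       base_seed = cfg$study$base_seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# display convention for bias tables: magnitudes below 0.001 print as
# "<0.001"; raw values are kept in the JSON log
format_bias <- function(x, digits = 3) {
  out <- formatC(x, digits = digits, format = "f")
  out[abs(x) < 0.001] <- "<0.001"
  out
}

#' Write study results to disk
#'
#' Emits \code{table1_growth_bias.csv} (rows: growth parameters) and
#' \code{table2_reliability_bias.csv} (rows: occasions), one column per
#' (model, situational-effect level, n) cell, plus \code{study_log.json}
#' with raw full-precision values, configuration, seeds and convergence
#' counts. In the display tables, bias magnitudes below 0.001 are rendered
#' \code{"<0.001"}; the JSON log keeps the raw numbers.
#'
#' @param study A [run_study()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(study, out_dir) {
  stopifnot(inherits(study, "pgm_study"))
  if (length(study$cells) == 0L)
    stop("empty study results; nothing to write", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  widen <- function(tab, rowvar) {
    tab <- tab[order(tab$model, tab$os, tab$n), ]
    cols <- sprintf("%s_os%s_n%d", tab$model, format(tab$os, trim = TRUE),
                    tab$n)
    rows <- unique(tab[[rowvar]])
    out <- data.frame(row = rows)
    names(out) <- rowvar
    for (cl in unique(cols)) {
      sub <- tab[cols == cl, ]
      out[[cl]] <- format_bias(sub$bias[match(rows, sub[[rowvar]])])
    }
    out
  }
  f_growth <- file.path(out_dir, "table1_growth_bias.csv")
  f_rel <- file.path(out_dir, "table2_reliability_bias.csv")
  f_log <- file.path(out_dir, "study_log.json")
  utils::write.csv(widen(study$growth_table, "parameter"), f_growth,
                   row.names = FALSE)
  utils::write.csv(widen(study$reliability_table, "occasion"), f_rel,
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = study$config,
         growth_bias = study$growth_table,
         reliability_bias = study$reliability_table,
         convergence = data.frame(
           cell = names(study$cells),
           n_converged = vapply(study$cells, `[[`, 0, "n_converged"),
           n_replications = vapply(study$cells, `[[`, 0, "n_replications"))),
    f_log, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(c(f_growth, f_rel, f_log))
}
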