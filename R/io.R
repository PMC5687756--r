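## Tidy long-format CSV is the single interchange format. Column names are
## fixed and match the record types; statuses are the lowercase literals
## "living" / "dead".

reading_cols <- c("site", "transect", "section", "observer", "reading",
                  "count_probably_living", "count_possibly_living",
                  "count_dead")
oyster_cols <- c("oyster_id", "field_status", "video_status")
truth_cols <- c("site", "transect", "section", "true_living", "true_dead")

check_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

check_counts <- function(df, cols, path, integer_only = FALSE) {
  for (col in cols) {
    v <- df[[col]]
    bad <- !is.finite(v) | v < 0 | (integer_only & v != round(v))
    if (any(bad))
      stop(sprintf("invalid %s in %s at row %d (%s)", col, path,
                   which(bad)[1], format(v[which(bad)[1]])),
           call. = FALSE)
  }
  invisible(df)
}

#' Read and write the package's CSV interchange tables
#'
#' Validating readers/writers for the three record types: reading records
#' (one row per site/transect/section/observer/reading with the three
#' status-category counts), matched oyster records (field and video status
#' per individually relocated oyster) and section truth (field census per
#' section). Validation failures name the offending column and row.
#'
#' @param path CSV file path.
#' @return The validated data.frame.
#' @export
read_readings <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, reading_cols, path)
  check_counts(df, c("site", "transect", "section", "observer", "reading"),
               path, integer_only = TRUE)
  check_counts(df, c("count_probably_living", "count_possibly_living",
                     "count_dead"), path)
  df
}

#' @rdname read_readings
#' @export
read_oysters <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, oyster_cols, path)
  for (col in c("field_status", "video_status")) {
    bad <- !(df[[col]] %in% c("living", "dead"))
    if (any(bad))
      stop(sprintf("unknown status in %s at row %d (%s)", path,
                   which(bad)[1], df[[col]][which(bad)[1]]), call. = FALSE)
  }
  df
}

#' @rdname read_readings
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, truth_cols, path)
  check_counts(df, truth_cols, path, integer_only = TRUE)
  if (!is.null(df$vegetation_cover) &&
      any(df$vegetation_cover < 0 | df$vegetation_cover > 1, na.rm = TRUE))
    stop("vegetation_cover outside [0, 1] in ", path, call. = FALSE)
  df
}

#' @rdname read_readings
#' @param df The table to write.
#' @export
write_survey_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply a user-supplied column mapping to an imported table
#'
#' Spreadsheet exports of survey data rarely use this package's column
#' names; `mapping` renames them (`c(oyster_id = "ID", field_status =
#' "Field", ...)`, package name = source name) before the usual
#' validation. [read_oysters_xlsx()] combines this with a `readxl` import
#' of a worksheet.
#'
#' @param df Imported data.frame.
#' @param mapping Named character vector: names are package column names,
#'   values the source columns.
#' @param type One of `"oysters"`, `"readings"`, `"truth"`.
#' @return Validated data.frame in package layout.
#' @export
apply_column_mapping <- function(df, mapping,
                                 type = c("oysters", "readings", "truth")) {
  type <- match.arg(type)
  miss <- setdiff(unname(mapping), names(df))
  if (length(miss))
    stop("mapped column(s) absent from source: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- df[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(out, tmp, row.names = FALSE)
  switch(type, oysters = read_oysters(tmp), readings = read_readings(tmp),
         truth = read_truth(tmp))
}

#' @rdname apply_column_mapping
#' @param path XLSX file path.
#' @param sheet Worksheet name or index.
#' @export
read_oysters_xlsx <- function(path, mapping, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("package 'readxl' is required for XLSX import", call. = FALSE)
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  apply_column_mapping(df, mapping, "oysters")
}

#' Read a run configuration from YAML
#'
#' The YAML may contain `design:`, `generator:` and `precision:` blocks
#' (fields matching the arguments of [survey_design()],
#' [generator_config()] and [scenario_grid()]), plus `seed` and
#' `out_dir`. Missing fields fall back to package defaults; a top-level
#' `seed` overrides the generator's.
#'
#' @param path YAML file path.
#' @return A list with `design`, `config`, `precision`, `out_dir`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  design <- do.call(survey_design, raw$design %||% list())
  gen <- raw$generator %||% list()
  if (!is.null(gen$vc)) gen$vc <- as_variance_components(gen$vc)
  if (!is.null(gen$dead_vc)) gen$dead_vc <- as_variance_components(gen$dead_vc)
  if (!is.null(raw$seed)) gen$seed <- raw$seed
  config <- do.call(generator_config, gen)
  list(design = design, config = config,
       precision = raw$precision %||% list(),
       out_dir = raw$out_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-survey analysis pipeline
#'
#' Executes simulate -> classification validation -> variance-component
#' fit -> precision prediction on one synthetic survey, writing each
#' stage's CSV plus a combined text report into `out_dir`. The generator
#' runs in mechanistic mode for truth/readings/matched oysters and the
#' variance-component stage analyses the merged living counts.
#'
#' @param run A list as returned by [read_run_config()], or a path to a
#'   YAML config.
#' @return Invisibly, a list with `truth`, `readings`, `oysters`,
#'   `metrics`, `anova`, `vc`, `grid` and the output paths.
#' @export
run_pipeline <- function(run) {
  if (is.character(run)) run <- read_run_config(run)
  design <- run$design
  config <- run$config
  if (config$mode != "mechanistic")
    config$mode <- "mechanistic"
  dir.create(run$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(run$out_dir, f)
  stage <- function(name, expr) {
    message("[", name, "] running")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- stage("simulate", generate_field_truth(design, config))
  video <- stage("simulate", generate_video_observations(truth, design,
                                                         config))
  write_survey_csv(truth$sections, p("section_truth.csv"))
  write_survey_csv(video$readings, p("readings.csv"))
  write_survey_csv(video$oysters, p("oysters.csv"))

  metrics <- stage("validate-classification",
                   classification_metrics(build_confusion(video$oysters)))
  comparison <- stage("validate-abundance",
                      build_comparison(video$readings, truth$sections))
  write_survey_csv(comparison, p("section_comparison.csv"))

  tab <- stage("fit-vc", suppressWarnings(
    fit_variance_components(video$readings, design)))
  vc <- attr(tab, "vc")
  write_survey_csv(as.data.frame(tab), p("variance_components.csv"))

  prec <- run$precision
  grid <- stage("precision", scenario_grid(
    vc, prec$a_range %||% 1:10, prec$b_range %||% c(1, 5),
    prec$c_range %||% 1:2, prec$n_range %||% 1:2, design))
  write_survey_csv(grid, p("precision_grid.csv"))

  report <- p("report.txt")
  sink(report); on.exit(sink(), add = TRUE)
  cat("Towed-video survey pipeline report\n\n")
  print(design); cat("\n"); print(metrics); cat("\n")
  cat(sprintf("living recovery (merged): %.3f\n",
              recovery_rate(comparison, "living")))
  print(tab); cat("\n"); print(vc)
  sink(); on.exit()

  invisible(list(truth = truth, readings = video$readings,
                 oysters = video$oysters, metrics = metrics,
                 comparison = comparison, anova = tab, vc = vc,
                 grid = grid, report = report, out_dir = run$out_dir))
}
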