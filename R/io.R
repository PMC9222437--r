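# Tabular IO. One dialect everywhere: UTF-8 TSV, '.' decimal, header row.

.schemas <- list(
  subjects = list(
    required = c("subject_id", "opn1lw_hap"),
    numeric = c("al_mm", "cc_d", "percent_l", "observed_ser_d",
                "calculated_ser"),
    logical = c("european", "cv_normal", "surgery", "single_opn1lw",
                "opn1mw_mvvva_only")),
  assay = list(
    required = c("haplotype", "replicate", "auc_a", "auc_t"),
    numeric = c("replicate", "auc_a", "auc_t"),
    logical = character()),
  trajectories = list(
    required = c("subject_id", "eye", "arm", "period", "day", "al_mm"),
    numeric = c("period", "day", "al_mm"),
    logical = character()),
  haplotype_summary = list(
    required = c("haplotype", "n", "median_ser_os", "mean_ser_os"),
    numeric = c("n", "median_ser_os", "mean_ser_os", "pct_exon3_skipping",
                "split_halves_rank"),
    logical = character())
)

#' Read and validate a tab-separated analysis table
#'
#' Reads a UTF-8 TSV with a header row and validates it against one of the
#' package's named schemas: required columns must be present, and numeric
#' and logical columns must parse, with unparseable values reported by
#' file line number. An empty table (header only) is returned with a
#' warning.
#'
#' @param path Path to a TSV file.
#' @param schema One of `"subjects"`, `"assay"`, `"trajectories"`,
#'   `"haplotype_summary"`.
#' @return The validated data frame.
#' @export
read_table <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sc <- .schemas[[schema]]
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character")
  missing_cols <- setdiff(sc$required, names(df))
  if (length(missing_cols)) {
    stop("schema '", schema, "': missing required column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty table (header only): ", path, call. = FALSE)
  }
  errs <- character()
  for (col in intersect(sc$numeric, names(df))) {
    raw <- df[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad)) {
      errs <- c(errs, sprintf("line %d: column '%s' value '%s' is not numeric",
                              bad + 1L, col, raw[bad]))
    }
    df[[col]] <- num
  }
  for (col in intersect(sc$logical, names(df))) {
    raw <- toupper(df[[col]])
    lg <- rep(NA, length(raw))
    lg[raw %in% c("TRUE", "T", "1", "YES")] <- TRUE
    lg[raw %in% c("FALSE", "F", "0", "NO")] <- FALSE
    bad <- which(is.na(lg) & !is.na(df[[col]]))
    if (length(bad)) {
      errs <- c(errs, sprintf("line %d: column '%s' value '%s' is not logical",
                              bad + 1L, col, df[[col]][bad]))
    }
    df[[col]] <- lg
  }
  if (length(errs)) {
    stop("validation errors in ", path, " (schema '", schema, "'):\n  ",
         paste(utils::head(errs, 10), collapse = "\n  "),
         if (length(errs) > 10) "\n  ...", call. = FALSE)
  }
  df
}

#' Read a subject table, averaging replicate biometry columns
#'
#' Accepts either pre-averaged `al_mm`/`cc_d` columns, or per-visit
#' replicates: `al_read_*` columns (up to 20 axial-length readings per
#' eye, averaged on load) and the two keratometry read-outs
#' `cc_method1_d`/`cc_method2_d` (averaged into `cc_d`).
#'
#' @param path Path to a subjects TSV.
#' @return Validated subject data frame with `al_mm` and `cc_d` filled in.
#' @export
read_subject_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                           nrows = 1)
  al_reads <- grep("^al_read_", names(raw), value = TRUE)
  df <- read_table(path, "subjects")
  if (!"al_mm" %in% names(df) && length(al_reads)) {
    reads <- df[al_reads]
    reads[] <- lapply(reads, function(x) suppressWarnings(as.numeric(x)))
    df$al_mm <- rowMeans(reads, na.rm = TRUE)
  }
  if (!"cc_d" %in% names(df) &&
      all(c("cc_method1_d", "cc_method2_d") %in% names(df))) {
    df$cc_d <- (suppressWarnings(as.numeric(df$cc_method1_d)) +
                suppressWarnings(as.numeric(df$cc_method2_d))) / 2
  }
  df
}

#' Write a JSON analysis report
#'
#' Serializes a module result (or any list of results) to JSON together
#' with the package version and the seed used, so a run is reproducible
#' from its own report. Classed result objects are flattened to plain
#' lists. Re-running with the same inputs and seed produces an identical
#' file.
#'
#' @param results A result object or named list of result objects.
#' @param path Output path (`.json`).
#' @param seed The seed the results were computed with (echoed).
#' @param overwrite Allow replacing an existing file (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NULL, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("output exists, not overwriting without overwrite = TRUE: ", path,
         call. = FALSE)
  }
  strip <- function(x) {
    if (is.environment(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(x, strip)
      return(unclass(x))
    }
    x
  }
  payload <- list(package = "opsinmyopia",
                  version = as.character(utils::packageVersion("opsinmyopia")),
                  seed = seed,
                  results = strip(results))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}
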