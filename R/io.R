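# Delimited-text readers and writers for soaking curves and treatment
# tables. Dialect: comma-separated, header row, decimal point, UTF-8;
# tab-separated input is accepted on read.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && grepl("\t", first[1])) "\t" else ","
}

read_delim_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = detect_sep(path),
               stringsAsFactors = FALSE, check.names = FALSE,
               encoding = "UTF-8"),
    error = function(e) stop(sprintf("malformed table %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

CURVE_COLUMNS <- c("pretreatment", "temperature_C", "time_min", "moisture_db")

#' Read soaking curves from a delimited table
#'
#' Long format with columns `pretreatment`, `temperature_C`, `time_min`,
#' `moisture_db` (dry basis, g/g); one row per sampled time point, one
#' curve per condition. Comma separation is the default and tabs are
#' accepted.
#'
#' @param path Path to the file.
#' @return Named list of [rehydration_curve()]s.
#' @export
read_curve_table <- function(path) {
  df <- read_delim_checked(path, CURVE_COLUMNS)
  if (nrow(df) == 0) {
    warning(sprintf("%s: header only, no curves", path), call. = FALSE)
    return(list())
  }
  bad <- which(!is.finite(df$time_min) | df$time_min < 0)
  if (length(bad))
    stop(sprintf("%s: invalid soaking time at row %d (time_min = %s)",
                 path, bad[1], format(df$time_min[bad[1]])), call. = FALSE)
  bad <- which(!is.finite(df$moisture_db) | df$moisture_db < 0)
  if (length(bad))
    stop(sprintf("%s: invalid moisture at row %d (moisture_db = %s)",
                 path, bad[1], format(df$moisture_db[bad[1]])), call. = FALSE)
  key <- sprintf("%s_%s", df$pretreatment, df$temperature_C)
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(idx) {
    sub <- df[idx, ][order(df$time_min[idx]), ]
    rehydration_curve(sub$time_min, sub$moisture_db,
                      pretreatment = sub$pretreatment[1],
                      temperature = sub$temperature_C[1],
                      Xw0 = sub$moisture_db[1])
  })
  out
}

#' Write soaking curves to a delimited table
#'
#' @param curves A list of [rehydration_curve()]s.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_curve_table <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(pretreatment = cv$pretreatment,
               temperature_C = cv$temperature,
               time_min = cv$times,
               moisture_db = cv$moistures)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

TREATMENT_COLUMNS <- c("pretreatment", "temperature_C", "mass_fresh_g",
                       "mass_dried_g", "mass_rehydrated_g",
                       "L_mm", "W_mm", "T_mm", "Lstar", "astar", "bstar",
                       "total_sugar_g_per_100g", "ascorbic_acid_mg_per_100g",
                       "sensory_score")

#' Read a treatment-property table
#'
#' One row per (pretreatment, temperature) condition with the measured
#' masses, kernel dimensions, CIELAB color, total sugar, ascorbic acid and
#' sensory score. See [generate_treatment_table()] for the column layout.
#'
#' @param path Path to the file.
#' @return A data frame of treatment records.
#' @export
read_treatment_table <- function(path) {
  df <- read_delim_checked(path, TREATMENT_COLUMNS)
  if (nrow(df) == 0) {
    warning(sprintf("%s: header only, no treatments", path), call. = FALSE)
    return(df)
  }
  for (col in c("mass_fresh_g", "mass_dried_g", "mass_rehydrated_g",
                "L_mm", "W_mm", "T_mm")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad))
      stop(sprintf("%s: non-positive %s at row %d", path, col, bad[1]),
           call. = FALSE)
  }
  df
}

#' Write a treatment-property table
#'
#' @param treatments Data frame of treatment records.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_treatment_table <- function(treatments, path) {
  write.csv(treatments, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
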