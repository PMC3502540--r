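# Packaged fixtures: the 22-h dose-response table and the FCS/ELISA
# percent-change time courses, transcribed verbatim (signs and deviation
# columns preserved; any unicode minus normalized to ASCII on load).

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "acthfcs")
  if (path == "") {
    stop(errorCondition(sprintf("packaged fixture '%s' not found", file),
                        class = c("acthfcs_io_error", "acthfcs_error")))
  }
  path
}

normalize_minus <- function(df) {
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      df[[j]] <- as.numeric(gsub("−", "-", df[[j]]))
    }
  }
  df
}

#' Load the 22-h dose-response records
#'
#' Seven rows of CRH/cortisol dose combinations applied to AtT-20 anterior
#' pituitary cells for 22 h, with cell density and measured extracellular
#' ACTH (nM, with Student-t deviations).
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Data frame with columns `crh_nM`, `cortisol_nM`, `cells_per_ml`,
#'   `cells_dev`, `acth_nM`, `acth_dev`.
#' @export
load_table1 <- function(path = fixture_path("table1_dose_response.csv")) {
  df <- normalize_minus(read.csv(path, colClasses = "character",
                                 fileEncoding = "UTF-8"))
  stopifnot(all(df$acth_nM > 0), all(df$crh_nM >= 0), all(df$cortisol_nM >= 0))
  df
}

#' Load the FCS/ELISA percent-change time courses
#'
#' Sixteen rows covering the basal, 10 nM CRH and 10 nM CRH + 100 nM
#' cortisol arms: FCS percent change of extracellular ACTH versus t = 0 with
#' Student-t deviations, plus the matching ELISA control columns (validation
#' only; the ELISA assay itself is out of scope).
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return Data frame with columns `arm`, `time_min`, `fcs_pct`, `fcs_dev`,
#'   `elisa_pct`, `elisa_dev`.
#' @export
load_table2 <- function(path = fixture_path("table2_time_course.csv")) {
  df <- read.csv(path, colClasses = c(arm = "character"),
                 fileEncoding = "UTF-8")
  num <- setdiff(names(df), "arm")
  for (j in num) {
    if (is.character(df[[j]])) df[[j]] <- as.numeric(gsub("−", "-", df[[j]]))
  }
  stopifnot(all(df$time_min >= 0), all(df$fcs_dev > 0), all(df$elisa_dev > 0))
  df
}

#' MD5 checksums of the packaged fixture tables
#'
#' Used by the integrity tests to pin the transcribed values.
#'
#' @return Named character vector of MD5 sums.
#' @export
fixture_checksums <- function() {
  files <- c(table1 = fixture_path("table1_dose_response.csv"),
             table2 = fixture_path("table2_time_course.csv"))
  sums <- tools::md5sum(files)
  names(sums) <- names(files)
  sums
}
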