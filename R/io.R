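# Readers/writers and run configuration.  Files carry ISO calendar dates;
# the monotone season-day axis is internal only.

check_columns <- function(df, need, file) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("schema error in %s: missing column(s) %s", file,
          paste(miss, collapse = ", "))
}

#' Read and validate an image-score table
#'
#' @param path CSV with columns subcolony, site_id, season, date (ISO),
#'   time (minutes since midnight), count (0/1/2).
#' @return validated data.frame.
#' @export
read_image_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subcolony", "site_id", "season", "date", "time",
                      "count"), path)
  bad <- which(!(df$count %in% 0:2))
  if (length(bad))
    stopf("data error in %s: count outside {0,1,2} at row %d (column 'count')",
          path, bad[1])
  df$date <- as.Date(df$date)
  if (anyNA(df$date))
    stopf("data error in %s: unparseable date (column 'date')", path)
  df
}

#' Read and validate a site table
#' @param path CSV with columns site_id, subcolony, quality, n_attempts.
#' @return validated data.frame.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site_id", "subcolony", "quality"), path)
  bad <- which(df$quality < 0 | df$quality > 1)
  if (length(bad))
    stopf("data error in %s: quality outside [0,1] at row %d (column 'quality')",
          path, bad[1])
  df
}

#' Read and validate a breeding table
#' @param path CSV with columns site_id, season, lay_date, success.
#' @return validated data.frame.
#' @export
read_breeding <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("site_id", "season", "lay_date", "success"), path)
  bad <- which(!is.na(df$success) & !(df$success %in% 0:1))
  if (length(bad))
    stopf("data error in %s: success outside {0,1} at row %d (column 'success')",
          path, bad[1])
  df
}

#' Write a synthetic colony to CSV + JSON
#'
#' Emits \code{image_scores.csv}, \code{sites.csv}, \code{breeding.csv} and
#' \code{truth.json} (the ground truth echo) into a directory.
#'
#' @param colony a \code{cw_colony}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_colony <- function(colony, dir) {
  stopifnot(inherits(colony, "cw_colony"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(colony$image_scores, file.path(dir, "image_scores.csv"),
            row.names = FALSE)
  write.csv(colony$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  write.csv(colony$breeding, file.path(dir, "breeding.csv"),
            row.names = FALSE)
  truth <- colony$truth
  truth$gap_spec <- as.data.frame(truth$gap_spec)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a run configuration file
#'
#' YAML with either a \code{simulate:} block (fields of
#' \code{\link{simulation_truth}}) or an \code{inputs:} block
#' (\code{image_scores}, \code{sites}, \code{breeding} paths), plus
#' optional \code{presence_filters}, \code{mcmc:} (chains, iterations,
#' burn_in, thin, profile), \code{seed} and \code{output_dir}.  Exactly one
#' of simulate/inputs must be present.
#'
#' @param path YAML file.
#' @return a validated run-config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$simulate) == is.null(cfg$inputs))
    stopf("configuration error: supply exactly one of 'simulate' or 'inputs'")
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  if (is.null(cfg$presence_filters)) cfg$presence_filters <- "any"
  if (is.null(cfg$output_dir)) cfg$output_dir <- "colonywatch_run"
  cfg
}
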