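# Pipeline driver: simulate (or read) -> metrics -> mixed models -> path
# analysis, with a manifest recording configuration, row counts, warnings
# and completed stages.

#' Run the full analysis pipeline
#'
#' Executes the stages in order, writing each stage's outputs under
#' \code{output_dir} and a \code{manifest.json} describing the run.  Any
#' stage failure still writes the manifest with the completed stages.  All
#' randomness flows from the root seed via named per-stage substreams, so a
#' repeated run is byte-identical.
#'
#' @param config run-config list (see \code{\link{read_run_config}}), or a
#'   path to a YAML config file.
#' @return the manifest (invisibly), with stage outputs attached as the
#'   \code{results} attribute.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("colonywatch")),
                   config = config[setdiff(names(config), "truth_object")],
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   stages = list(), warnings = list(), counts = list())
  results <- list()
  finish <- function() {
    manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    attr(manifest, "results") <- results
    invisible(manifest)
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- "failed"
      manifest$warnings[[name]] <<- conditionMessage(e)
      finish()
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- "ok"
    res
  }

  ## stage: data (simulate or read)
  dat <- stage("data", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- substream_seed(config$seed, "simulate-root")
      truth <- do.call(simulation_truth, args)
      colony <- simulate_colony(truth)
      write_colony(colony, file.path(out_dir, "synthetic"))
      list(scores = colony$image_scores, sites = colony$sites,
           breeding = colony$breeding, gaps = truth$gap_spec,
           survey_log = colony$survey_log)
    } else {
      list(scores = read_image_scores(config$inputs$image_scores),
           sites = read_sites(config$inputs$sites),
           breeding = read_breeding(config$inputs$breeding),
           gaps = NULL, survey_log = NULL)
    }
  })
  manifest$counts$image_scores <- nrow(dat$scores)
  manifest$counts$sites <- nrow(dat$sites)
  manifest$counts$breeding <- nrow(dat$breeding)

  ## stage: metrics (per requested presence filter)
  metrics_list <- stage("metrics", {
    ml <- lapply(config$presence_filters, function(fl)
      compute_metrics(dat$scores, declared_gaps = dat$gaps,
                      presence_filter = fl))
    names(ml) <- config$presence_filters
    all_m <- do.call(rbind, ml)
    write.csv(all_m, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    cs <- colony_summaries(dat$scores)
    write.csv(cs$daily, file.path(out_dir, "daily_summary.csv"),
              row.names = FALSE)
    write.csv(cs$hourly, file.path(out_dir, "hourly_summary.csv"),
              row.names = FALSE)
    ml
  })
  manifest$counts$site_seasons <- nrow(metrics_list[[1]])
  manifest$warnings$never_occupied <-
    attr(metrics_list[[1]], "n_never_occupied")

  ## stage: mixed models
  glmm_res <- stage("glmm", {
    hyps <- config$hypotheses
    if (is.null(hyps)) hyps <- c("assoc1", "assoc2", "1", "2a", "2b")
    res <- lapply(metrics_list, function(m) {
      md <- prepare_model_data(m, dat$breeding, dat$sites)
      out <- list()
      for (h in hyps)
        out[[h]] <- tryCatch(fit_hypothesis(md, h),
                             error = function(e) conditionMessage(e))
      out
    })
    # flat AIC table across hypotheses/filters
    rows <- list()
    for (fl in names(res)) for (h in names(res[[fl]])) {
      r <- res[[fl]][[h]]
      sels <- if (h == "1" && is.list(r) && !is.null(r$return_day)) r
        else setNames(list(r), h)
      for (nm in names(sels)) {
        s <- sels[[nm]]
        if (!is.list(s) || is.null(s$table)) next
        tt <- s$table
        tt$hypothesis <- h; tt$filter <- fl
        tt$response <- if (nzchar(nm)) nm else sub(" ~.*", "", tt$label)
        tt$chosen <- tt$label == s$chosen$label
        tt$terms <- NULL
        rows[[length(rows) + 1]] <- tt
      }
    }
    if (length(rows))
      write.csv(do.call(rbind, rows), file.path(out_dir, "selection.csv"),
                row.names = FALSE)
    res
  })

  ## stage: path analysis
  path_res <- stage("pathmodel", {
    m_any <- metrics_list[["any"]]
    if (is.null(m_any)) m_any <- metrics_list[[1]]
    pd <- build_path_data(m_any, dat$breeding, dat$sites,
                          n_rows = config$path_n_rows)
    prof <- if (!is.null(config$mcmc$profile)) config$mcmc$profile else "fast"
    mc_args <- config$mcmc
    mc_args$profile <- prof
    mc_args$seed <- substream_seed(config$seed, "pathmodel")
    cfg <- do.call(mcmc_config, mc_args)
    pr <- fit_path_analysis(pd, config = cfg)
    write.csv(pr$pathways, file.path(out_dir, "pathways.csv"),
              row.names = FALSE)
    write.csv(pr$diagnostics, file.path(out_dir, "diagnostics.csv"),
              row.names = FALSE)
    pr
  })
  manifest$counts$path_rows <- length(unique(paste(
    dat$breeding$site_id, dat$breeding$season)))
  manifest$path_converged <- path_res$converged

  results <- list(metrics = metrics_list, glmm = glmm_res, path = path_res,
                  data = dat)
  finish()
}
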