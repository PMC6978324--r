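#' JSON + Markdown summary report of an MSM analysis
#'
#' Writes `<prefix>.json` and `<prefix>.md` summarizing a fitted pipeline:
#' coarse stationary probabilities (with bootstrap confidence intervals when
#' available), metastable mean first passage times, the implied-timescale
#' table and a Chapman-Kolmogorov summary.
#'
#' @param pipeline an `msm_pipeline` from [run_msm_pipeline()].
#' @param prefix output path prefix.
#' @param its optional `implied_timescales` data frame.
#' @param ck optional `ck_test` data frame.
#' @param entropy optional `entropy_profile` matrix.
#' @return invisible list of the written paths.
#' @export
msm_report <- function(pipeline, prefix, its = NULL, ck = NULL,
                       entropy = NULL) {
  stopifnot(inherits(pipeline, "msm_pipeline"))
  boot <- pipeline$bootstrap
  obj <- list(
    n_microstates = length(pipeline$msm$pi),
    lag = lag_time(pipeline$msm),
    populations = as.list(stats::setNames(pipeline$populations,
      pipeline$weights$state_names)),
    mfpt = as.list(pipeline$mfpt),
    eigenvalues = pipeline$msm$eigenvalues[seq_len(min(5,
      length(pipeline$msm$eigenvalues)))]
  )
  if (!is.null(boot)) {
    ci <- boot$intervals$coarse_pi
    obj$population_ci <- lapply(seq_len(ncol(ci)), function(j)
      list(lower = ci[1, j], upper = ci[2, j],
           sd = stats::sd(boot$coarse_pi[, j])))
    cim <- boot$intervals$mfpt
    obj$mfpt_ci <- lapply(seq_len(ncol(cim)), function(j)
      list(name = colnames(boot$mfpt)[j], lower = cim[1, j],
           upper = cim[2, j]))
  }
  if (!is.null(its)) obj$implied_timescales <- as.list(as.data.frame(its))
  if (!is.null(ck)) obj$ck_test <- as.list(as.data.frame(ck))
  if (!is.null(entropy)) obj$psi_entropy <- as.data.frame(unclass(entropy))
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  md <- c("# MSM analysis report", "",
          sprintf("- microstates: %d", obj$n_microstates),
          sprintf("- lag time: %g", obj$lag), "",
          "## Metastable state probabilities", "")
  for (j in seq_along(pipeline$populations)) {
    line <- sprintf("- %s: %.3f", pipeline$weights$state_names[j],
                    pipeline$populations[j])
    if (!is.null(boot))
      line <- sprintf("%s  [%.3f, %.3f]", line,
                      boot$intervals$coarse_pi[1, j],
                      boot$intervals$coarse_pi[2, j])
    md <- c(md, line)
  }
  md <- c(md, "", "## Mean first passage times", "",
          sprintf("- %s: %.4g", names(pipeline$mfpt), pipeline$mfpt))
  if (!is.null(its)) {
    md <- c(md, "", "## Implied timescales", "",
            paste(utils::capture.output(print.data.frame(as.data.frame(its),
                                                         digits = 4)),
                  collapse = "\n"))
  }
  if (!is.null(ck)) {
    md <- c(md, "", "## Chapman-Kolmogorov test", "",
            paste(utils::capture.output(print.data.frame(as.data.frame(ck),
                                                         digits = 4)),
                  collapse = "\n"))
  }
  md_path <- paste0(prefix, ".md")
  writeLines(md, md_path)
  invisible(list(json = json_path, md = md_path))
}

#' Write a numeric matrix as TSV
#'
#' @param M matrix (e.g. a count or transition matrix, or a distance
#'   matrix).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  utils::write.table(as.matrix(M), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
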