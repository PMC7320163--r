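#' Write pipeline results to disk
#'
#' Writes three files into `out_dir`: `distances.csv` (one row per profile
#' with source position, raw distance and kept flag), `profiles.csv`
#' (long-format aligned average profiles: profile id, offset nm, intensity)
#' and `summary.json` (fit parameters, stage counts, config echo, software
#' version). All floats carry full precision (>= 6 significant digits).
#'
#' @param result a [run_pipeline()] result (or a compatible skeleton with
#'   empty elements).
#' @param out_dir output directory, created if needed.
#' @return character vector of written file paths (the manifest), invisibly.
#' @export
write_results <- function(result, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    stop("cannot write to directory: ", out_dir)

  f_dist <- file.path(out_dir, "distances.csv")
  dd <- result$distances
  if (is.null(dd))
    dd <- data.frame(profile_id = integer(0), line_id = integer(0),
                     source_row = integer(0), source_col = integer(0),
                     distance_nm = numeric(0), kept = logical(0),
                     reason = character(0))
  utils::write.csv(format_sig(dd), f_dist, row.names = FALSE, quote = FALSE)

  f_prof <- file.path(out_dir, "profiles.csv")
  prof_rows <- list()
  add_prof <- function(id, p) {
    if (is.null(p)) return()
    prof_rows[[length(prof_rows) + 1L]] <<- data.frame(
      profile_id = id, offset_nm = p$offsets_nm, intensity = p$intensities)
  }
  for (nm in names(result$per_line_average_profiles))
    add_prof(paste0("line_", nm), result$per_line_average_profiles[[nm]])
  add_prof("image_average", result$image_average_profile)
  pf <- if (length(prof_rows)) do.call(rbind, prof_rows) else
    data.frame(profile_id = character(0), offset_nm = numeric(0),
               intensity = numeric(0))
  utils::write.csv(format_sig(pf), f_prof, row.names = FALSE, quote = FALSE)

  f_sum <- file.path(out_dir, "summary.json")
  fit <- result$fit
  summary <- list(
    fit = if (is.null(fit)) NULL else
      list(A = fit$A, c = fit$c, sigma = fit$sigma, n = fit$n,
           c_stderr = fit$c_stderr, converged = fit$converged,
           fit_window_nm = fit$fit_window_nm),
    counts = result$counts,
    config = unclass(result$config),
    version = as.character(utils::packageVersion("lineprofiler")))
  jsonlite::write_json(summary, f_sum, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(f_dist, f_prof, f_sum))
}

# full-precision formatting for CSV output
format_sig <- function(df) {
  for (k in seq_along(df))
    if (is.double(df[[k]])) df[[k]] <- formatC(df[[k]], digits = 10,
                                               format = "g")
  df
}
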