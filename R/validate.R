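#' Write a simulated helix to TIFF with a ground-truth sidecar
#'
#' Renders the validation helix and writes a two-page TIFF (page 1 axis
#' channel, page 2 central channel) plus `<out>.truth.json` recording the
#' generating parameters and crossing positions.
#'
#' @param spec a [helix_spec()].
#' @param out output TIFF path.
#' @return list with `tiff` and `truth_json` paths, invisibly.
#' @export
simulate_helix_files <- function(spec = helix_spec(), out) {
  r <- render_helix(spec)
  write_channels_tiff(list(r$axis, r$central), out)
  truth_path <- paste0(sub("\\.tiff?$", "", out), ".truth.json")
  truth <- r$truth
  truth$strand_y <- NULL  # functions are not serializable
  payload <- c(unclass(spec), truth[setdiff(names(truth), "a_nm")],
               list(a_nm = spec$a_nm))
  jsonlite::write_json(payload, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(tiff = out, truth_json = truth_path))
}

#' Reproduce the helix validation experiment
#'
#' Simulates the twisted two-strand helix, runs the full one-channel
#' pipeline on it, and compares the fitted strand distance against the
#' known ground truth. With defaults this is the canonical self-check:
#' `a = 800` nm, `b = 1/1612` per nm, pixel size 32.24 nm, and the fitted
#' center must land within `tolerance_nm` (5 nm) of the truth.
#'
#' @param a_nm,b_per_nm,pixel_size_nm,psf_sigma_nm helix parameters
#'   (see [helix_spec()]).
#' @param n_periods length of the rendered helix in twist periods.
#' @param expect_nm expected strand distance; defaults to `a_nm`.
#' @param tolerance_nm pass window half-width.
#' @param config a [pipeline_config()].
#' @param quiet suppress the summary line on stdout.
#' @return list with `c_nm`, `stderr_nm`, `expect_nm`, `pass` and the full
#'   `result`, invisibly when printing.
#' @export
validate_helix <- function(a_nm = 800, b_per_nm = 1 / 1612,
                           pixel_size_nm = 32.24, psf_sigma_nm = 40,
                           n_periods = 3, expect_nm = a_nm,
                           tolerance_nm = 5,
                           config = pipeline_config(), quiet = FALSE) {
  spec <- helix_spec(a_nm = a_nm, b_per_nm = b_per_nm,
                     length_nm = n_periods * 2 * pi / b_per_nm,
                     pixel_size_nm = pixel_size_nm,
                     psf_sigma_nm = psf_sigma_nm, seed = config$seed)
  r <- render_helix(spec)
  res <- run_pipeline(r$axis, central = NULL, config = config)
  if (is.null(res$fit) || !isTRUE(res$fit$converged))
    stop_analysis("half-norm fit did not converge on the simulated helix")
  c_nm <- res$fit$c
  pass <- abs(c_nm - expect_nm) <= tolerance_nm
  if (!quiet)
    cat(sprintf("strand_distance_nm=%.6g stderr_nm=%.6g pass=%s\n",
                c_nm, res$fit$c_stderr, tolower(pass)))
  invisible(list(c_nm = c_nm, stderr_nm = res$fit$c_stderr,
                 expect_nm = expect_nm, pass = pass, result = res))
}
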