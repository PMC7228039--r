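#' Derive a reproducible stage seed
#'
#' Fans a single user seed out into independent per-stage, per-run seeds so
#' that adding runs to one stage never perturbs the random stream of another.
#' The derived seed is a deterministic hash of `(seed, stage, run_index)`
#' kept inside the 32-bit integer range.
#'
#' @param seed Integer master seed.
#' @param stage Character stage name (e.g. `"subsample"`, `"cluster"`).
#' @param run_index Integer run index within the stage (0 for stage-level).
#' @return A single integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stage, run_index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  val <- (abs(as.double(seed)) * 48271 + h * 3967 + as.double(run_index) * 7919) %%
    2147483629
  as.integer(val)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() wrapper keeping call noise out of user-facing errors
cms_stop <- function(...) stop(..., call. = FALSE)

cms_warn <- function(...) warning(..., call. = FALSE)

# shared missing-value tokens for delimited input
MISSING_TOKENS <- c("", "NA", "NaN")

#' Write a list as pretty JSON
#'
#' Thin wrapper used for all structured-text reports (filter reports,
#' preprocessing manifests, selection and severity reports) so every report
#' is written with identical, reproducible conventions.
#'
#' @param x A list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
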