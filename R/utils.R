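`%||%` <- function(a, b) if (is.null(a)) b else a

# All diagnostics go to stderr so machine-readable output on stdout stays clean.
.LOG_LEVELS <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

cvd_log <- function(fmt, ..., level = "INFO") {
  min_level <- getOption("cvdstrat.log_level", "INFO")
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[min_level]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

# Condition class used by the CLI so usage problems map to exit code 2.
cvd_usage_error <- function(msg) {
  structure(
    class = c("cvd_usage_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

.stop_usage <- function(fmt, ...) stop(cvd_usage_error(sprintf(fmt, ...)))
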