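# Internal condition helpers. All package errors carry a subclass of
# "protonflux_error" so callers can branch on the failure mode rather than
# on message text.

pf_stop <- function(class, msg, ..., call. = FALSE) {
  stop(errorCondition(msg, ..., class = c(paste0("protonflux_", class),
                                          "protonflux_error")))
}

pf_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(paste0("protonflux_", class),
                                               "protonflux_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stopifnot_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    pf_stop("validation_error", sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
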