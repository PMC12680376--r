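#' @keywords internal
"_PACKAGE"

# Configuration errors carry a dedicated class so callers (and the CLI) can
# distinguish bad user input from internal failures.
config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("reinstatr_config_error", "error")))
}

assert_config <- function(ok, msg, ...) {
  if (!isTRUE(ok)) config_error(msg, ...)
  invisible(TRUE)
}

#' Derive a per-stage seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage (or
#' cohort replicate) gets its own stream via a fixed counter scheme, recorded
#' in run manifests. Values stay below 2^31 - 1 so they remain valid R
#' integer seeds.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stage/replicate counter.
#' @return an integer seed.
#' @export
derive_seed <- function(master, counter = 0L) {
  assert_config(is.numeric(master) && length(master) == 1L && is.finite(master),
                "master seed must be a single finite number")
  assert_config(is.numeric(counter) && counter >= 0,
                "seed counter must be non-negative")
  # affine congruential step; 2147483629 is prime < 2^31
  as.integer((abs(master) %% 2147483629 * 48271 + counter * 7919 + 1) %%
               2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# stable hash of an R object via its canonical JSON rendering
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
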