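#' Round half away from zero toward positive infinity
#'
#' Commercial ("round half up") rounding: `round_half_up(0.5) == 1`,
#' unlike [round()]'s round-half-to-even. Used for every split and infusion
#' count so dataset sizes are reproducible by hand. A tiny epsilon absorbs
#' binary floating-point representation error in products such as
#' `0.9 * 1665`, whose decimal value is an exact half.
#'
#' @param x numeric vector.
#' @return integer vector, `floor(x + 0.5)` with an epsilon guard.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.4, 1.5, 2.5))
round_half_up <- function(x) {
  as.integer(floor(x + 0.5 + 1e-9))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' library functions never clobber a user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Derive a per-stage seed from a global seed
#'
#' Deterministically maps (global seed, stage name) to a seed in
#' `[1, 2^31 - 2]` so that pipeline stages remain individually reproducible
#' when run standalone with the same global seed. Uses a MINSTD-style
#' multiplicative step plus a 31-fold string hash, all exact in doubles.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% m
  s <- ((abs(as.numeric(seed)) %% m) * 48271) %% m
  out <- (s + h) %% m
  as.integer(out + 1)
}

# stop() with sprintf formatting; call. = FALSE keeps messages user-facing
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# shared validator: character vector of unique, non-empty ids
check_ids <- function(ids, what = "image_id") {
  if (!is.character(ids) || anyNA(ids) || any(!nzchar(ids)))
    fail("%s values must be non-empty strings", what)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    fail("duplicate %s values: %s", what, paste(dup, collapse = ", "))
  invisible(ids)
}
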