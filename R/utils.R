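#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state so seeded helpers never disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-stage seed from a global one so stages can be re-run in
# isolation and still reproduce a full pipeline run. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    cohort = 101L, session = 211L, qc = 307L, partition = 401L,
    model = 503L, importance = 601L, nmi = 701L, sweep = 809L,
    generalization = 907L
  )
  off <- offsets[[stage]]
  as.integer((as.integer(seed) * 1009L + off) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mw <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_mw("'%s' must be a single non-missing number", name)
  }
  invisible(x)
}
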