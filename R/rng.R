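#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards. All randomness in the package
#' flows through this helper so that every output is a pure function of its
#' seed and parameters.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a named RNG substream seed
#'
#' Maps (master seed, stage label, index) to a reproducible integer seed.
#' Each pipeline stage (noise, placement, observer, permutation, ...) draws
#' from its own substream so that changing one stage's RNG consumption never
#' shifts another stage's draws.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @param index Optional integer distinguishing draws within a stage.
#' @return An integer seed in `[0, 2^28)`.
#' @export
substream_seed <- function(master, stage, index = 0L) {
  h <- rlang::hash(list(as.integer(master), as.character(stage), as.integer(index)))
  strtoi(substr(h, 1L, 7L), base = 16L)
}
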