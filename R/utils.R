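# Internal helpers shared across modules.

# Deterministic fan-out of one user seed into independent substreams, so each
# simulated artifact (means, size factors, counts, gene sets, graph edges, ...)
# draws from its own stream and adding a stage never perturbs another.
stream_seeds <- function(seed, n = 32L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  seed <- as.integer(abs(seed) %% .Machine$integer.max)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

abort_config <- function(msg, ...) {
  abort(msg, class = "tritrend_config_error", ...)
}

abort_stage <- function(stage, parent) {
  abort(
    paste0("pipeline stage '", stage, "' failed: ", conditionMessage(parent)),
    class = "tritrend_stage_error",
    stage = stage,
    parent = parent
  )
}

# Cohort labels are fixed by the study design.
COHORTS <- c("Young", "Old", "OAD")

COMPARISONS <- list(
  YoungVsOld  = list(name = "YoungVsOld",  reference = "Young", test = "Old"),
  OldVsOAD    = list(name = "OldVsOAD",    reference = "Old",   test = "OAD"),
  YoungVsOAD  = list(name = "YoungVsOAD",  reference = "Young", test = "OAD")
)
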