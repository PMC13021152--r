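# Seed-substream discipline: every (sample, stage) pair maps to its own seed
# derived from the master seed by a small Lehmer-style mixer, so regenerating
# a later stage never perturbs an earlier one and samples are independent.
# All arithmetic stays below 2^53, hence exact in doubles.

.STAGE <- c(pattern = 1L, tissue = 2L, holes = 3L, cells = 4L,
            markers = 5L, permutation = 6L)

.MOD <- 2147483647  # 2^31 - 1

.mix <- function(h) (h * 48271) %% .MOD

.substreamSeed <- function(seed, sample, stage) {
  h <- .mix((abs(as.double(seed)) %% (.MOD - 1)) + 1)
  h <- .mix((h + as.double(sample) * 1000003) %% .MOD)
  h <- .mix((h + as.double(stage) * 10007) %% .MOD)
  as.integer(h)
}

# Evaluate expr under a given seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(seed)
  expr
}
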