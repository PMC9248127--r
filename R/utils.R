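# Small shared helpers.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions do not perturb the
# session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# sample() without the length-1 surprise: sample1(c(7)) always returns 7.
sample_from <- function(x, size = 1L, replace = FALSE) {
  if (length(x) == 1L) return(rep(x, if (replace) size else min(size, 1L)))
  sample(x, size = size, replace = replace)
}

ocsr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "ocsr")
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop(sprintf("bundled data file '%s' not found", file))
  path
}

read_lines_clean <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
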