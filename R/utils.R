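# Internal helpers shared across modules.

# One pseudorandom stream per module call: the stream seed is derived from the
# top-level seed plus a short call tag, so adding a new generator never shifts
# the draws of existing ones. Kept well below .Machine$integer.max.
stream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 2017L
  as.integer((abs(as.integer(seed)) %% 1000000L) * 2017L + h)
}

with_stream <- function(seed, tag, code) {
  withr::with_seed(stream_seed(seed, tag), code)
}

geometric_mean <- function(x) exp(mean(log(x)))

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# Consistent value used as the pipeline/schema version in sidecar files.
pipeline_version <- function() as.character(utils::packageVersion("phenoscreen"))
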