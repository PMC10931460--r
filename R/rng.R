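# Seed management: one global seed fans out deterministically to per-stage
# seeds so each pipeline stage is independently reproducible.

#' Derive a stage seed from a global seed
#'
#' Mixes a global integer seed with a stage label into a new seed in
#' `[1, 2^31 - 2]` using multiplicative hashing, so independent pipeline
#' stages (data synthesis, cascade training, model training, ...) draw from
#' unrelated streams while staying reproducible from one number.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. `"synth"`, `"train"`).
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1, "synth")
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  s <- (as.double(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((s + h) %% 2147483645 + 1)
}

# Evaluate expr with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# He-style initialisation for conv kernels (kh,kw,Cin,Cout) and linear (out,in)
init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin, cout))
}

init_linear <- function(nout, nin) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout)
}
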