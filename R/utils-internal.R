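# Evaluate expr with a private RNG state so callers' streams are untouched.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# VAF >= frac comparison robust to binary-fraction rounding (vac/depth vs a
# decimal threshold like 0.02): compare counts, not floats.
ge_frac <- function(vac, depth, frac) {
  vac >= frac * depth - 1e-9
}
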