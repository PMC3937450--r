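# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Counter-based child seeds: deterministic in (master, index), independent of
# execution order, kept within the 32-bit integer range.
child_seed <- function(master, index) {
  if (is.null(master)) return(NULL)
  as.integer((as.double(master) * 48271 + as.double(index) * 7919) %% 2147483647)
}
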