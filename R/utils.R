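# integer percentage, rounding half away from zero (reproduces printed
# cohort percentages, e.g. 10/59 -> 16.95 -> 17, 95/118 -> 80.5 -> 81)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

pct_int <- function(k, n) as.integer(round_half_away(100 * k / n))

pct_exact <- function(k, n) round(100 * k / n, 4)

`%||%` <- function(x, y) if (is.null(x)) y else x

# deterministic RNG scope: run code under a seed without disturbing the
# caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
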