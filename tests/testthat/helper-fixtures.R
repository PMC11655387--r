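## Shared fixture builders. Everything is generated in code at test time;
## no data files.

## Small archipelago + genotypes used by several suites.
tiny_sim <- function(n_islands = 4, cells = 5, n_per_island = 15,
                     n_neutral = 150, n_adaptive = 30, fst = 0.05,
                     effect_b = 3, seed = 42, ...) {
  arch <- make_archipelago(n_islands, cells, seed = seed)
  sim <- simulate_genotypes(arch, n_per_island = n_per_island,
                            n_neutral = n_neutral, n_adaptive = n_adaptive,
                            fst = fst, effect_b = effect_b,
                            seed = seed + 1, ...)
  list(arch = arch, gm = sim$gm, truth = sim$truth)
}

## Per-individual historic climate rows for a simulated dataset.
sample_climate <- function(arch, gm, slice = c("historic", "future")) {
  slice <- match.arg(slice)
  ci <- match(gm$sample_meta$cell_id, arch$grid$cell_id)
  as.data.frame(arch[[slice]][ci, , drop = FALSE])
}

## Hand-built two-predictor turnover model with known step functions:
##   f_A jumps to 0.1 / 0.3 / 0.6 at A = 1, 2, 3
##   f_B jumps to 0.2 / 0.5       at B = 10, 20
toy_turnover_model <- function() {
  structure(
    list(
      functions = list(
        A = list(upper = c(1, 2, 3), cum = c(0.1, 0.3, 0.6),
                 range = c(0, 3)),
        B = list(upper = c(10, 20), cum = c(0.2, 0.5), range = c(0, 20))
      ),
      importance = c(A = 0.6, B = 0.5),
      r2 = NULL, n_included = 2L,
      predictors = c("A", "B"), params = NULL, model_id = "toy"
    ),
    class = "turnover_model"
  )
}
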