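`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent closed-form oracle for the fitness model, written as straight
# arithmetic so it shares no code with the package's evaluation path.
oracle_lrf <- function(M, parent = c("maternal", "paternal"),
                       ibi_override = NULL, pu_override = NULL,
                       mortality_multiplier = 1, stunting_multiplier = 1,
                       maternal_mortality = FALSE) {
  parent <- match.arg(parent)
  ibi <- if (is.null(ibi_override)) 2 + (M - 15) * 0.25 else ibi_override
  tf <- pmax(0, (35 - (M + 1)) / ibi)
  lbw <- pmin(pmax(0.9 - (M - 15) * 0.1, 0), 1)
  mr <- pmin(pmax(lbw * pmax(0.7 - (M - 15) * 0.065, 0) *
                    mortality_multiplier, 0), 1)
  mmr <- if (maternal_mortality) {
    pmin(pmax(0.485 - 0.033 * M + 0.000023 * M^3, 0), 1)
  } else 0
  lrf <- tf * (1 - mr) * (1 - mmr)
  if (parent == "paternal") {
    pu <- if (is.null(pu_override)) {
      pmin(pmax(0.05 * (M - 15), 0), 1)
    } else pu_override
    lrf <- lrf * (1 - pu)
  }
  lrf
}

# Brute-force argmax over an inclusive grid; first (lowest-age) maximum.
brute_force_argmax <- function(f, lo, hi, step) {
  grid <- lo + step * (0:floor((hi - lo) / step + 1e-9))
  grid[which.max(f(grid))]
}

# A random but valid parameter draw for property tests (seeded by caller).
random_params <- function() {
  fitness_params(
    mortality_multiplier = stats::runif(1, 0.5, 1.5),
    stunting_multiplier = sample(c(1, 3), 1),
    ibi_override = if (stats::runif(1) < 0.5) stats::runif(1, 1.5, 4),
    pu_override = if (stats::runif(1) < 0.5) stats::runif(1, 0, 0.3),
    maternal_mortality_enabled = stats::runif(1) < 0.5
  )
}
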