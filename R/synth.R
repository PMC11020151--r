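# Evaluate any supported generating model at times t.
eval_gen_model <- function(model, t) {
  if (is.numeric(model)) return(poly_eval(model, t))
  if (inherits(model, c("poly_model", "piecewise_model")))
    return(predict(model, t))
  if (is.function(model)) return(model(t))
  stop("unsupported generating model; supply coefficients, a poly_model, ",
       "a piecewise_model or a function of t")
}

#' Generate replicate fluorescence time courses
#'
#' Emulates the fluorometric recordings the analysis pipeline consumes:
#' `n_replicates` time series following a generating model (polynomial,
#' piecewise linear, or arbitrary function of time) with additive Gaussian
#' noise. `sigma = 0` reproduces the model exactly; output is bit-reproducible
#' for a fixed seed (all replicates drawn from one stream seeded once, in
#' replicate order).
#'
#' @param model generating model: ascending coefficient vector, a
#'   [poly_model()], a [ca_piecewise_model()], or `function(t)`.
#' @param times sampling grid, minutes, within `[0, 15]`.
#' @param n_replicates number of replicate traces (the recordings behind the
#'   reported means are n = 4--7).
#' @param sigma additive Gaussian noise SD, relative fluorescence units x1000.
#' @param seed integer seed.
#' @param nonnegative clamp noisy values at 0 (for probes whose fluorescence
#'   cannot be negative); clamped points are counted in attribute `n_clamped`.
#' @return list of `n_replicates` data.frames (`time`, `value`), each with a
#'   `replicate` attribute.
#' @export
gen_timeseries <- function(model, times = seq(0, 15, by = 0.5),
                           n_replicates = 4, sigma = 5, seed = 1,
                           nonnegative = FALSE) {
  stopifnot(n_replicates >= 1, sigma >= 0)
  if (any(times < 0 | times > 15))
    stop("time grid outside the 0-15 min validity window")
  base <- eval_gen_model(model, times)
  set.seed(as.integer(seed))
  n_clamped <- 0L
  out <- lapply(seq_len(n_replicates), function(i) {
    v <- base + if (sigma > 0) stats::rnorm(length(times), 0, sigma) else 0
    if (nonnegative) {
      n_clamped <<- n_clamped + sum(v < 0)
      v[v < 0] <- 0
    }
    structure(data.frame(time = times, value = v), replicate = i)
  })
  if (n_clamped > 0)
    message(n_clamped, " generated point(s) clamped at 0")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Generate a C-1193 dose--response table
#'
#' Draws `n_replicates` concentration--fluorescence curves from the Hill
#' inhibition law `F(C) = Fmax / (1 + (C/Ki)^n)` with multiplicative Gaussian
#' noise (coefficient of variation `cv`), including per replicate the
#' zero-inhibitor row that measures that replicate's Fmax. Replicate `i` draws
#' from a substream seeded deterministically as `seed + i - 1`.
#'
#' @param fmax zero-inhibitor fluorescence (relative units).
#' @param ki apparent inhibition constant, molar (default 5.5 nM, the NO
#'   dose--response parameterization).
#' @param hill_n Hill coefficient.
#' @param concentrations inhibitor concentrations, molar, all > 0; default
#'   decade series 0.001--100 uM.
#' @param n_replicates number of replicates (default 7).
#' @param cv multiplicative noise CV (0 disables noise).
#' @param seed integer seed.
#' @return data.frame with columns `concentration_M`, `F`, `replicate`,
#'   directly consumable by [estimate_ki()].
#' @export
gen_doseresponse <- function(fmax = 1000, ki = 5.5e-9, hill_n = 1,
                             concentrations = c(1e-9, 1e-8, 1e-7, 1e-6,
                                                1e-5, 1e-4),
                             n_replicates = 7, cv = 0.05, seed = 1) {
  stopifnot(fmax > 0, ki > 0, hill_n > 0, n_replicates >= 1, cv >= 0)
  if (any(concentrations <= 0))
    stop("concentrations must be positive (the zero-inhibitor Fmax row is ",
         "added automatically)")
  rows <- lapply(seq_len(n_replicates), function(i) {
    set.seed(as.integer(seed) + i - 1L)
    conc <- c(0, concentrations)
    f0 <- c(fmax, fmax / (1 + (concentrations / ki)^hill_n))
    noise <- if (cv > 0) 1 + stats::rnorm(length(conc), 0, cv) else 1
    data.frame(concentration_M = conc, F = f0 * noise, replicate = i)
  })
  do.call(rbind, rows)
}
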