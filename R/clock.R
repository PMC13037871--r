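#' Strict molecular clock model
#'
#' Describes the substitution process used by [evolve_sequences()]: a strict
#' clock with rate `rate` (substitutions per base pair per year, applied at
#' non-invariant sites), a nucleotide model (`JC69` or `TN93`) and a
#' proportion of invariant sites that never substitute.
#'
#' Under `TN93`, `kappa1` is the rate multiplier of A<->G transitions and
#' `kappa2` that of C<->T transitions, relative to transversions;
#' `base_freqs` are the stationary frequencies in the order A, C, G, T.
#' `JC69` fixes `kappa1 = kappa2 = 1` and equal base frequencies.
#'
#' The default rate is the mitochondrial dating rate used for hominin
#' strict-clock analyses, 1.57e-8 substitutions/bp/year.
#'
#' @param rate substitution rate (subs/bp/year) at non-invariant sites.
#' @param model `"TN93"` or `"JC69"`.
#' @param invariant_fraction proportion of sites that never substitute,
#'   in `[0, 1)`.
#' @param kappa1,kappa2 transition/transversion rate ratios (TN93 only).
#' @param base_freqs stationary base frequencies (A, C, G, T); must sum to 1.
#' @return An object of class `clock_model`.
#' @examples
#' clock_model(rate = 1.57e-8, model = "TN93", invariant_fraction = 0.3,
#'             kappa1 = 20, kappa2 = 40)
#' @export
clock_model <- function(rate = 1.57e-8,
                        model = c("TN93", "JC69"),
                        invariant_fraction = 0,
                        kappa1 = 1, kappa2 = 1,
                        base_freqs = rep(0.25, 4)) {
  model <- match.arg(model)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stop_invalid("'rate' must be a single non-negative number")
  if (invariant_fraction < 0 || invariant_fraction >= 1)
    stop_invalid("'invariant_fraction' must be in [0, 1)")
  if (model == "JC69") {
    kappa1 <- kappa2 <- 1
    base_freqs <- rep(0.25, 4)
  }
  if (length(base_freqs) != 4L || any(base_freqs <= 0))
    stop_invalid("'base_freqs' must be four positive probabilities")
  if (abs(sum(base_freqs) - 1) > 1e-9)
    stop_invalid("'base_freqs' must sum to 1 (within 1e-9)")
  if (kappa1 <= 0 || kappa2 <= 0)
    stop_invalid("'kappa1' and 'kappa2' must be positive")
  structure(
    list(rate = rate, model = model,
         invariant_fraction = invariant_fraction,
         kappa1 = kappa1, kappa2 = kappa2,
         base_freqs = as.numeric(base_freqs)),
    class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Strict clock: %s, rate %.3g subs/bp/year, %.0f%% invariant sites\n",
              x$model, x$rate, 100 * x$invariant_fraction))
  if (x$model == "TN93")
    cat(sprintf("  kappa1 (A<->G) = %g, kappa2 (C<->T) = %g; freqs A,C,G,T = %s\n",
                x$kappa1, x$kappa2, paste(signif(x$base_freqs, 3), collapse = ", ")))
  invisible(x)
}

# Instantaneous rate matrix (states A,C,G,T), scaled to one expected
# substitution per unit branch length at stationarity.
clock_rate_matrix <- function(clock) {
  pi <- clock$base_freqs
  # exchangeabilities: A<->G kappa1, C<->T kappa2, transversions 1
  ex <- matrix(1, 4, 4)
  ex[1, 3] <- ex[3, 1] <- clock$kappa1
  ex[2, 4] <- ex[4, 2] <- clock$kappa2
  Q <- ex * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Transition probability matrix after 'd' expected substitutions per site.
clock_pmatrix <- function(Q, d) {
  if (d <= 0) return(diag(4))
  ape::matexpo(Q * d)
}
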