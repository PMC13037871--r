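# Tip-to-root regression: temporal-signal assessment, clock-rate
# estimation and molecular age prediction for undated tips.

#' Root-to-tip path distances
#'
#' Sums branch lengths on the root-to-tip path for every tip of a rooted
#' tree, optionally divided by an alignment length to give per-bp
#' distances.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param per_bp divide by `aln_length`.
#' @param aln_length alignment length in bp (required when `per_bp`).
#' @return Named numeric vector of distances, one per tip.
#' @export
root_to_tip_distances <- function(tree, per_bp = FALSE, aln_length = NULL) {
  if (!ape::is.rooted(tree)) stop_invalid("'tree' must be rooted")
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  if (per_bp) {
    if (is.null(aln_length)) stop_invalid("'aln_length' required for per-bp distances")
    d <- d / aln_length
  }
  d
}

#' Tip-to-root temporal regression
#'
#' Ordinary least squares of root-to-tip distance on negative tip age
#' (years before present), so that the slope is the substitution rate
#' forward in time. Tips with `NA` age are treated as undated: their
#' molecular age is predicted as the age at which the fitted line
#' attains their observed distance, with a prediction interval obtained
#' by mapping the distance prediction interval through the fitted slope.
#'
#' @param distances named numeric vector of root-to-tip distances (from
#'   [root_to_tip_distances()] or per-bp sequence distances to the
#'   root).
#' @param ages named numeric vector of tip ages in years BP; `NA` marks
#'   undated tips. At least 3 dated tips with at least 2 distinct ages
#'   are required.
#' @param level prediction-interval coverage (default 0.95).
#' @return Object of class `temporal_regression`: `slope`
#'   (substitutions per unit distance per year), `intercept`,
#'   `r_squared`, `root_age_estimate`, `residuals` (dated tips),
#'   `predicted_ages` (data frame `tip`, `distance`, `age_hat`,
#'   `age_lower`, `age_upper`) and the underlying `lm` fit.
#' @examples
#' ages <- c(a = 40000, b = 60000, c = 80000, d = 100000)
#' d <- 1.57e-8 * (120000 - ages)
#' fit_temporal_regression(d, ages)$slope
#' @export
fit_temporal_regression <- function(distances, ages, level = 0.95) {
  tips <- names(distances)
  if (is.null(tips) || is.null(names(ages)))
    stop_invalid("'distances' and 'ages' must be named by tip")
  ages <- ages[tips]
  dated <- !is.na(ages)
  if (sum(dated) < 2) stop_invalid("need at least 2 dated tips")
  if (length(unique(ages[dated])) < 2)
    stop_invalid("all dated tips share one age: no temporal signal to fit")
  df <- data.frame(d = distances[dated], x = -ages[dated])
  fit <- stats::lm(d ~ x, data = df)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- summary(fit)$r.squared
  root_age <- if (slope != 0) intercept / slope else NA_real_
  predicted <- data.frame(tip = character(0), distance = numeric(0),
                          age_hat = numeric(0), age_lower = numeric(0),
                          age_upper = numeric(0))
  if (any(!dated) && slope != 0) {
    und <- tips[!dated]
    d_obs <- distances[und]
    age_hat <- (intercept - d_obs) / slope
    if (sum(dated) >= 3) {
      pi <- suppressWarnings(
        stats::predict(fit, newdata = data.frame(x = -age_hat),
                       interval = "prediction", level = level))
      hw <- (pi[, "upr"] - pi[, "lwr"]) / 2
    } else {
      hw <- rep(NA_real_, length(und))  # no residual df with 2 dated tips
    }
    predicted <- data.frame(tip = und, distance = unname(d_obs),
                            age_hat = unname(age_hat),
                            age_lower = unname(age_hat - hw / abs(slope)),
                            age_upper = unname(age_hat + hw / abs(slope)),
                            stringsAsFactors = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 root_age_estimate = root_age,
                 residuals = stats::residuals(fit),
                 predicted_ages = predicted, fit = fit, level = level),
            class = "temporal_regression")
}

#' @export
print.temporal_regression <- function(x, ...) {
  cat(sprintf("Tip-to-root regression: slope %.4g subs/unit/year, R^2 %.3f\n",
              x$slope, x$r_squared))
  cat(sprintf("  root age estimate: %.0f years BP\n", x$root_age_estimate))
  if (nrow(x$predicted_ages)) {
    cat(sprintf("  predicted ages (%d%% PI):\n", round(100 * x$level)))
    print(x$predicted_ages, row.names = FALSE)
  }
  invisible(x)
}
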