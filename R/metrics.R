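#' Model-evaluation statistics for paired observed/simulated series
#'
#' Standard agreement statistics for comparing a simulated series against
#' observations:
#' * `rrmse()` - relative root mean square error (%, 0 to +Inf, optimum 0):
#'   `100 * RMSE / mean(observed)`;
#' * `modelling_efficiency()` - Nash-Sutcliffe efficiency (-Inf to 1,
#'   optimum 1): `1 - SSE / SStot`;
#' * `crm()` - coefficient of residual mass (-Inf to +Inf, optimum 0):
#'   `(sum(observed) - sum(simulated)) / sum(observed)`; negative values
#'   flag systematic overestimation;
#' * `r_squared()` - squared Pearson correlation (0-1).
#'
#' @param observed,simulated Numeric vectors of equal nonzero length with
#'   finite values.
#' @return A single number; `evaluate_series()` returns all four as a
#'   named list.
#' @export
rrmse <- function(observed, simulated) {
  check_pairs(observed, simulated)
  m <- mean(observed)
  if (m == 0)
    stop("RRMSE undefined: mean of observations is zero", call. = FALSE)
  100 * sqrt(mean((simulated - observed)^2)) / m
}

#' @rdname rrmse
#' @export
modelling_efficiency <- function(observed, simulated) {
  check_pairs(observed, simulated)
  sstot <- sum((observed - mean(observed))^2)
  if (sstot == 0)
    stop("modelling efficiency undefined: observations have zero variance",
         call. = FALSE)
  1 - sum((simulated - observed)^2) / sstot
}

#' @rdname rrmse
#' @export
crm <- function(observed, simulated) {
  check_pairs(observed, simulated)
  so <- sum(observed)
  if (so == 0)
    stop("CRM undefined: observations sum to zero", call. = FALSE)
  (so - sum(simulated)) / so
}

#' @rdname rrmse
#' @export
r_squared <- function(observed, simulated) {
  check_pairs(observed, simulated)
  if (stats::var(observed) == 0 || stats::var(simulated) == 0)
    stop("R^2 undefined: a series has zero variance", call. = FALSE)
  stats::cor(observed, simulated)^2
}

#' @rdname rrmse
#' @export
evaluate_series <- function(observed, simulated) {
  list(rrmse = rrmse(observed, simulated),
       ef = modelling_efficiency(observed, simulated),
       crm = crm(observed, simulated),
       r_squared = r_squared(observed, simulated))
}

check_pairs <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) == 0)
    stop("'observed' and 'simulated' must have equal nonzero length",
         call. = FALSE)
  if (!all(is.finite(observed)) || !all(is.finite(simulated)))
    stop("series must contain only finite values", call. = FALSE)
  invisible(NULL)
}
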