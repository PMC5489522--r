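#' Sobol' sample-size rule
#'
#' Total number of model runs for the Saltelli design: the smallest
#' `M = 2^(q+3) * (2n + 2)` over integer `q >= 1` that strictly exceeds
#' `gamma * n`, where `n` is the number of parameters and `gamma` the
#' suggested number of runs per parameter.
#'
#' @param n_params Number of parameters (n >= 1).
#' @param gamma Suggested runs per parameter (>= 1).
#' @return Total sample size M (count of model runs).
#' @examples
#' sobol_sample_size(10, 500)  # 5632
#' @export
sobol_sample_size <- function(n_params, gamma) {
  if (n_params < 1 || gamma < 1)
    stop("'n_params' and 'gamma' must be >= 1", call. = FALSE)
  q <- 1
  repeat {
    m <- 2^(q + 3) * (2 * n_params + 2)
    if (m > gamma * n_params) return(m)
    q <- q + 1
  }
}

#' Trait-parameter distributions for sensitivity analysis
#'
#' Builds the marginal distribution set over the ten trait parameters:
#' normal marginals centred on the configured means with standard
#' deviations equal to `cv` times the mean (default 5%), truncated at
#' +/- 4 sd and at physical bounds (fractions to \[0, 1\], percentages to
#' (0, 100\], concentrations to > 0). Parameters are treated as
#' independent.
#'
#' @param params A [trait_parameters()] object supplying the means.
#' @param cv Coefficient of variation (sd / mean) of every marginal.
#' @return A data frame of class `parameter_distributions` with columns
#'   `name`, `dist`, `mean`, `sd`, `lower`, `upper` and a `trait` column
#'   mapping each parameter to its trait group (T1-T5).
#' @export
trait_distributions <- function(params = trait_parameters(), cv = 0.05) {
  nm <- names(params)
  mean <- unlist(params)
  sd <- cv * mean
  lower <- pmax(mean - 4 * sd, 1e-12)
  upper <- mean + 4 * sd
  frac <- nm %in% c("sub_dep_eff", "na_to_pan", "part_cap")
  upper[frac] <- pmin(upper[frac], 1)
  upper[nm == "rrbf_min"] <- min(upper[nm == "rrbf_min"], 100)
  trait <- c(rrbf_min = "T1", sub_dep_eff = "T1", sc_max = "T1",
             pot_c_seq = "T2", na_culm_max = "T2",
             susc_st = "T3", na_to_pan = "T3",
             part_cap = "T4",
             thresh_l = "T5", crit_l = "T5")[nm]
  structure(data.frame(name = nm, dist = "normal", mean = mean, sd = sd,
                       lower = lower, upper = upper, trait = trait,
                       row.names = NULL),
            class = c("parameter_distributions", "data.frame"))
}

#' Uniform marginal set (for benchmarks)
#'
#' @param names Parameter names.
#' @param lower,upper Bounds, recycled.
#' @return A `parameter_distributions` data frame with uniform marginals.
#' @export
uniform_distributions <- function(names, lower, upper) {
  n <- length(names)
  structure(data.frame(name = names, dist = "uniform",
                       mean = (lower + upper) / 2, sd = NA_real_,
                       lower = rep_len(lower, n), upper = rep_len(upper, n),
                       trait = NA_character_, row.names = NULL),
            class = c("parameter_distributions", "data.frame"))
}

# inverse-CDF mapping of a unit-hypercube sample onto the marginals,
# truncating normals at the configured bounds
map_quantiles <- function(u, dists) {
  x <- matrix(NA_real_, nrow = nrow(u), ncol = ncol(u),
              dimnames = list(NULL, dists$name))
  for (j in seq_len(ncol(u))) {
    if (dists$dist[j] == "uniform") {
      x[, j] <- stats::qunif(u[, j], dists$lower[j], dists$upper[j])
    } else {
      plo <- stats::pnorm(dists$lower[j], dists$mean[j], dists$sd[j])
      phi <- stats::pnorm(dists$upper[j], dists$mean[j], dists$sd[j])
      if (dists$sd[j] == 0) {
        x[, j] <- dists$mean[j]
      } else {
        x[, j] <- stats::qnorm(plo + u[, j] * (phi - plo),
                               dists$mean[j], dists$sd[j])
      }
    }
  }
  x
}

#' Saltelli cross-sampling design
#'
#' Builds the radial (Saltelli) design used to estimate Sobol' first- and
#' total-order indices. Two independent base matrices A and B of size
#' `base_n x n` are drawn from a seeded Latin hypercube and mapped through
#' the marginal inverse CDFs; the design stacks A, B, the n matrices AB_i
#' (A with column i taken from B) and the n matrices BA_i, giving
#' `base_n * (2n + 2)` rows in total - the row count of the sample-size
#' rule when `base_n = 2^(q+3)`.
#'
#' @param dists A `parameter_distributions` data frame.
#' @param base_n Base sample size N (rows of A).
#' @param seed Integer seed; the design is reproducible from it.
#' @return An object of class `saltelli_design`: list with the stacked
#'   `matrix`, `base_n`, `n`, `names` and block bookkeeping.
#' @export
saltelli_sample <- function(dists, base_n, seed) {
  n <- nrow(dists)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- lhs::randomLHS(base_n, 2 * n)
  a <- map_quantiles(u[, seq_len(n), drop = FALSE], dists)
  b <- map_quantiles(u[, n + seq_len(n), drop = FALSE], dists)
  blocks <- vector("list", 2 * n + 2)
  blocks[[1]] <- a
  blocks[[2]] <- b
  for (i in seq_len(n)) {
    ab <- a; ab[, i] <- b[, i]
    ba <- b; ba[, i] <- a[, i]
    blocks[[2 + i]] <- ab
    blocks[[2 + n + i]] <- ba
  }
  structure(list(matrix = do.call(rbind, blocks), base_n = base_n, n = n,
                 names = dists$name, dists = dists),
            class = "saltelli_design")
}

design_block <- function(design, which) {
  i0 <- (which - 1) * design$base_n
  design$matrix[i0 + seq_len(design$base_n), , drop = FALSE]
}

output_block <- function(outputs, design, which) {
  i0 <- (which - 1) * design$base_n
  outputs[i0 + seq_len(design$base_n)]
}

#' Sobol' first- and total-order indices
#'
#' Jansen-form estimators on a Saltelli design. With `yA`, `yB` the
#' outputs of the base blocks and `yAB_i`, `yBA_i` those of the radial
#' blocks, the symmetric Jansen estimators are
#' `S_i  = 1 - mean((yB - yAB_i)^2, (yA - yBA_i)^2) / (2 V)` and
#' `ST_i = mean((yA - yAB_i)^2, (yB - yBA_i)^2) / (2 V)`,
#' with V the variance of the pooled base outputs. Bootstrap confidence
#' bounds are computed by resampling base rows.
#'
#' @param outputs Numeric vector of model outputs, aligned row-for-row
#'   with `design$matrix`.
#' @param design A [saltelli_sample()] design.
#' @param n_boot Number of bootstrap resamples (0 disables the CIs).
#' @param conf Confidence level of the bootstrap interval.
#' @return An object of class `sobol_result`: data frame `indices` with
#'   columns `name`, `trait`, `first`, `total`, `first_lo`, `first_hi`,
#'   `total_lo`, `total_hi`, plus `sample_size`, `variance`,
#'   `output_mean`, `output_sd` and `degenerate` (TRUE when the output
#'   variance is zero, in which case the indices are NA).
#' @export
sobol_indices <- function(outputs, design, n_boot = 100, conf = 0.95) {
  stopifnot(inherits(design, "saltelli_design"))
  n <- design$n
  nn <- design$base_n
  if (length(outputs) != nn * (2 * n + 2))
    stop("'outputs' must align with the design rows", call. = FALSE)
  ya <- output_block(outputs, design, 1)
  yb <- output_block(outputs, design, 2)
  yab <- sapply(seq_len(n), function(i) output_block(outputs, design, 2 + i))
  yba <- sapply(seq_len(n),
                function(i) output_block(outputs, design, 2 + n + i))

  est <- function(idx) {
    a <- ya[idx]; b <- yb[idx]
    v <- stats::var(c(a, b))
    if (!is.finite(v) || v <= 0) return(list(first = rep(NA_real_, n),
                                             total = rep(NA_real_, n),
                                             v = v))
    first <- total <- numeric(n)
    for (i in seq_len(n)) {
      dab <- yab[idx, i]; dba <- yba[idx, i]
      first[i] <- 1 - (mean((b - dab)^2) + mean((a - dba)^2)) / (4 * v)
      total[i] <- (mean((a - dab)^2) + mean((b - dba)^2)) / (4 * v)
    }
    list(first = first, total = total, v = v)
  }

  full <- est(seq_len(nn))
  degenerate <- !is.finite(full$v) || full$v <= 0
  lo <- hi <- function(x) rep(NA_real_, n)
  first_ci <- total_ci <- matrix(NA_real_, 2, n)
  if (!degenerate && n_boot > 0) {
    bf <- bt <- matrix(NA_real_, n_boot, n)
    for (r in seq_len(n_boot)) {
      idx <- sample.int(nn, nn, replace = TRUE)
      e <- est(idx)
      bf[r, ] <- e$first
      bt[r, ] <- e$total
    }
    al <- (1 - conf) / 2
    first_ci <- apply(bf, 2, stats::quantile, probs = c(al, 1 - al),
                      na.rm = TRUE)
    total_ci <- apply(bt, 2, stats::quantile, probs = c(al, 1 - al),
                      na.rm = TRUE)
  }
  idxdf <- data.frame(
    name = design$names,
    trait = design$dists$trait,
    first = full$first, total = full$total,
    first_lo = first_ci[1, ], first_hi = first_ci[2, ],
    total_lo = total_ci[1, ], total_hi = total_ci[2, ],
    row.names = NULL
  )
  structure(list(indices = idxdf,
                 sample_size = length(outputs),
                 variance = full$v,
                 output_mean = mean(c(ya, yb)),
                 output_sd = stats::sd(c(ya, yb)),
                 degenerate = degenerate),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, ...) {
  cat("Sobol' sensitivity analysis (", x$sample_size, " runs)\n", sep = "")
  if (x$degenerate) {
    cat("  degenerate: output variance is zero, indices undefined\n")
  } else {
    cat(sprintf("  output mean %.2f, sd %.2f\n", x$output_mean,
                x$output_sd))
    df <- x$indices[order(-x$indices$total), ]
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-12s %-3s S=%6.3f ST=%6.3f\n", df$name[i],
                  ifelse(is.na(df$trait[i]), "", df$trait[i]),
                  df$first[i], df$total[i]))
  }
  invisible(x)
}

#' Select the ideotype from a sensitivity experiment
#'
#' The ideotype is the sampled parameter combination that achieved the
#' highest output (yield); ties are broken by the lowest row index.
#'
#' @param design A [saltelli_sample()] design (or any matrix of parameter
#'   rows).
#' @param outputs Output vector aligned with the rows.
#' @return Named numeric vector: the winning parameter row, with
#'   attributes `yield` and `row`.
#' @export
select_ideotype <- function(design, outputs) {
  m <- if (inherits(design, "saltelli_design")) design$matrix else design
  if (length(outputs) != nrow(m))
    stop("'outputs' must align with the design rows", call. = FALSE)
  if (length(outputs) == 0) stop("empty outputs", call. = FALSE)
  best <- which.max(outputs)     # which.max already takes the first tie
  out <- m[best, ]
  attr(out, "yield") <- outputs[best]
  attr(out, "row") <- best
  out
}

#' Run the full trait-sensitivity / ideotyping workflow
#'
#' Chains the sample-size rule, Saltelli sampling of the trait-parameter
#' distributions, a batch of full-season simulations under a salinity
#' scenario, Jansen estimation of the Sobol' indices on final yield, and
#' ideotype extraction.
#'
#' @param scenario A [salinity_scenario()] object.
#' @param seed Integer seed controlling weather and sampling.
#' @param gamma Suggested runs per parameter for the sample-size rule;
#'   ignored when `base_n` is given.
#' @param base_n Base sample size N (power of two). Defaults to the value
#'   implied by the sample-size rule (`M / (2n + 2)`).
#' @param season_length Days in the simulated season.
#' @param dists Trait-parameter distributions, see [trait_distributions()].
#' @param aux,host,modes Passed to [run_season()].
#' @param weather Optional weather data frame; generated from `seed` when
#'   omitted.
#' @param n_boot Bootstrap resamples for the index CIs.
#' @return A list with `sobol` (a `sobol_result`), `ideotype`, `design`,
#'   `outputs`, `weather` and `salinity`.
#' @export
run_sensitivity <- function(scenario, seed = 1, gamma = 500, base_n = NULL,
                            season_length = 130,
                            dists = trait_distributions(),
                            aux = auxiliary_constants(),
                            host = host_parameters(),
                            modes = default_modes(),
                            weather = NULL, n_boot = 100) {
  n <- nrow(dists)
  if (is.null(base_n)) {
    m <- sobol_sample_size(n, gamma)
    base_n <- m / (2 * n + 2)
  }
  design <- saltelli_sample(dists, base_n, seed)
  if (is.null(weather))
    weather <- make_weather(season_length, seed)
  salinity <- make_salinity_series(scenario, nrow(weather))
  outputs <- apply(design$matrix, 1, function(row) {
    p <- do.call(trait_parameters, as.list(row))
    run_season(weather, salinity, params = p, aux = aux, host = host,
               modes = modes, daily = FALSE)$yield
  })
  sob <- sobol_indices(outputs, design, n_boot = n_boot)
  list(sobol = sob,
       ideotype = select_ideotype(design, outputs),
       design = design, outputs = outputs,
       weather = weather, salinity = salinity)
}
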