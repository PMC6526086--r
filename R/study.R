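#' Size and power studies for the covariance goodness-of-fit tests
#'
#' Orchestrates a factorial Monte-Carlo experiment over design cells.
#' Each cell is one row of `cells` with columns `n`, `m` and (for power)
#' `delta` and `deviation`; every cell uses the standard generator
#' parameters of [sim_design()] (unit intercept/slope variances,
#' covariance \eqn{-0.5}, unit noise, the 80-point grid on
#' \eqn{[-1, 1]}) unless overridden via `...`.  For each cell, `R`
#' datasets are simulated and the requested tests run; rejection is
#' `p_value < alpha`.  Per-dataset seeds are derived from
#' `(seed, cell, replicate)`, so results are bit-identical for a fixed
#' master seed regardless of the worker count.
#'
#' For the direct test, the finite-sample RLRT reference distribution is
#' simulated once per cell — from the null model fitted to the cell's
#' first dataset — and shared across the cell's datasets; given the
#' design, that distribution does not depend on the data, so sharing it
#' avoids `R` redundant simulations.
#'
#' @param cells data frame of design cells (`n`, `m`, optionally `delta`,
#'   `deviation`).
#' @param R simulated datasets per cell.
#' @param L bootstrap replicates per dataset (bootstrap test).
#' @param alphas nominal levels for the size study.
#' @param alpha single nominal level for the power study.
#' @param tests subset of `c("bootstrap", "direct")`.
#' @param seed master seed.
#' @param workers parallel workers (forked; results identical for any
#'   value).
#' @param direct_null_draws draws for the shared RLRT reference.
#' @param H tensor-product basis dimension for the bootstrap test.
#' @param ... further arguments passed to [sim_design()] (e.g.
#'   `grid_size`, `noise_sd`, `re_cov`).
#' @return a tibble with one row per (cell, test, alpha): columns `test`,
#'   `n`, `m`, `alpha`, `deviation`, `delta`, `deviation_size`, `R`, `L`,
#'   `rate` and its Monte-Carlo standard error `se`
#'   (\eqn{\sqrt{r(1-r)/R}}).  The raw p-values are attached as
#'   `attr(result, "pvalues")`, a list indexed by cell and test.
#' @examples
#' \donttest{
#' cells <- data.frame(n = 50, m = 10)
#' run_size_study(cells, R = 5, L = 20, seed = 1)
#' }
#' @export
run_size_study <- function(cells, R = 200L, L = 200L,
                           alphas = c(0.05, 0.10),
                           tests = c("bootstrap", "direct"), seed = 1L,
                           workers = 1L, direct_null_draws = 2000L,
                           H = 10L, ...) {
  cells$delta <- 0
  cells$deviation <- "none"
  study_run(cells, R, L, alphas, tests, seed, workers, direct_null_draws,
            H, ...)
}

#' @rdname run_size_study
#' @export
run_power_study <- function(cells, R = 200L, L = 200L, alpha = 0.05,
                            tests = c("bootstrap", "direct"), seed = 1L,
                            workers = 1L, direct_null_draws = 2000L,
                            H = 10L, ...) {
  if (is.null(cells$delta) || is.null(cells$deviation)) {
    stop_covgof("power cells need `delta` and `deviation` columns",
                "covgof_config_error")
  }
  study_run(cells, R, L, alpha, tests, seed, workers, direct_null_draws,
            H, ...)
}

study_run <- function(cells, R, L, alphas, tests, seed, workers, draws,
                      H, ...) {
  tests <- match.arg(tests, c("bootstrap", "direct"), several.ok = TRUE)
  rows <- list()
  pv_archive <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    delta <- cell$delta %||% 0
    deviation <- as.character(cell$deviation %||% "none")
    make_design <- function(s) {
      sim_design(n = cell$n, m = cell$m, delta = delta,
                 deviation = deviation, seed = s, ...)
    }
    dev_size <- deviation_size(make_design(1L))

    reference <- NULL
    if ("direct" %in% tests) {
      ref_ds <- simulate_dataset(make_design(derive_seed(seed, ci, 900001L)))
      reference <- direct_null_reference(
        ref_ds, draws = draws, seed = derive_seed(seed, ci, 900002L))
    }

    one_rep <- function(r) {
      ds <- simulate_dataset(make_design(derive_seed(seed, ci, r)))
      out <- c(bootstrap = NA_real_, direct = NA_real_)
      if ("bootstrap" %in% tests) {
        out["bootstrap"] <- tryCatch(
          run_gof_test(ds, L = L, seed = derive_seed(seed, ci, r, 2L),
                       H = H)$p_value,
          error = function(e) NA_real_)
      }
      if ("direct" %in% tests) {
        out["direct"] <- tryCatch(
          run_direct_test(ds, reference = reference)$p_value,
          error = function(e) NA_real_)
      }
      out
    }
    res <- if (workers > 1L) {
      parallel::mclapply(seq_len(R), one_rep, mc.cores = workers,
                         mc.preschedule = TRUE)
    } else {
      lapply(seq_len(R), one_rep)
    }
    pmat <- do.call(rbind, res)
    pv_archive[[ci]] <- pmat
    for (test in tests) {
      pv <- pmat[, test]
      n_ok <- sum(!is.na(pv))
      if (n_ok < R) {
        warning(sprintf("cell %d, %s test: %d of %d replicates failed",
                        ci, test, R - n_ok, R))
      }
      for (a in alphas) {
        rate <- mean(pv < a, na.rm = TRUE)
        rows[[length(rows) + 1]] <- tibble::tibble(
          test = test, n = cell$n, m = cell$m, alpha = a,
          deviation = deviation, delta = delta,
          deviation_size = dev_size, R = n_ok, L = L,
          rate = rate, se = sqrt(rate * (1 - rate) / max(n_ok, 1)))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pvalues") <- pv_archive
  out
}
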