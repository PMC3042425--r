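#' Run one Monte-Carlo replicate
#'
#' Executes the full per-replicate pipeline: generate a dataset from the
#' configuration's substream; fit the restricted and expanded logistic
#' models; form each model's in-sample linear predictors; compute the
#' likelihood-ratio and Wald p-values for the new marker's coefficient;
#' and compare the two predictors' AUCs by the DeLong paired test.
#' A replicate whose fits are flagged non-converged (separation) is
#' discarded and redrawn from the next substream, up to `max_attempts`.
#'
#' @param config A [sim_config()].
#' @param centered Passed to the correlated generator.
#' @param max_attempts Redraw budget for degenerate/non-converged draws.
#' @return Named numeric vector `c(p_lrt, p_wald, p_auc)` with attribute
#'   `"discarded"` counting redrawn attempts.
#' @examples
#' run_replicate(sim_config(200, 0.5, mu = 0, mu_star = 0.5, seed = 42))
#' @export
run_replicate <- function(config, centered = FALSE, max_attempts = 100L) {
  discarded <- 0L
  cfg <- config
  for (attempt in seq_len(max_attempts)) {
    d <- generate_dataset(cfg, centered = centered)
    discarded <- discarded + attr(d, "discarded")
    fit <- fit_nested_models(d)
    if (fit$converged) {
      cmp <- delong_paired_test(fit$z_restricted, fit$z_expanded, d$y)
      out <- c(p_lrt = fit$p_lrt, p_wald = fit$p_wald, p_auc = cmp$p_value)
      attr(out, "discarded") <- discarded
      return(out)
    }
    discarded <- discarded + 1L
    # shift to a fresh substream: bump the replicate index far outside the
    # cell's normal range so redraws never collide with other replicates
    cfg <- sim_config(cfg$n, cfg$prevalence, cfg$mu, cfg$mu_star, cfg$rho,
                      seed = cfg$seed,
                      replicate_index = cfg$replicate_index + 1000000L * attempt)
  }
  stop("replicate failed to produce a converged fit after ", max_attempts,
       " attempts", call. = FALSE)
}

#' Run one cell of the simulation grid
#'
#' Repeats [run_replicate()] `replicates` times with per-replicate
#' substreams and returns empirical rejection rates (fraction of p-values
#' strictly below `alpha`) for the three tests, with binomial Monte-Carlo
#' standard errors.
#'
#' @param config A [sim_config()]; its `replicate_index` is ignored.
#' @param replicates Number of Monte-Carlo replicates (at least 100).
#' @param alpha Nominal significance level; rejection is p < alpha.
#' @param centered Passed to the correlated generator.
#' @return Object of class `"cell_result"`: list with the configuration,
#'   `replicates`, `alpha`, rejection rates `reject_lrt`, `reject_wald`,
#'   `reject_auc`, standard errors `mc_se_*`, and the `discarded` count.
#' @examples
#' run_cell(sim_config(100, 0.5, mu = 0, mu_star = 1), replicates = 100)
#' @export
run_cell <- function(config, replicates = 2000L, alpha = 0.05,
                     centered = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  replicates <- as.integer(replicates)
  if (replicates < 100L) stop("`replicates` must be at least 100", call. = FALSE)
  if (alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  p <- matrix(NA_real_, replicates, 3L,
              dimnames = list(NULL, c("p_lrt", "p_wald", "p_auc")))
  discarded <- 0L
  for (i in seq_len(replicates)) {
    cfg <- sim_config(config$n, config$prevalence, config$mu, config$mu_star,
                      config$rho, seed = config$seed,
                      replicate_index = i - 1L)
    r <- run_replicate(cfg, centered = centered)
    p[i, ] <- r
    discarded <- discarded + attr(r, "discarded")
  }
  rates <- colMeans(p < alpha)
  se <- sqrt(rates * (1 - rates) / replicates)
  structure(list(
    config = config, replicates = replicates, alpha = alpha,
    reject_lrt = unname(rates["p_lrt"]),
    reject_wald = unname(rates["p_wald"]),
    reject_auc = unname(rates["p_auc"]),
    mc_se_lrt = unname(se["p_lrt"]),
    mc_se_wald = unname(se["p_wald"]),
    mc_se_auc = unname(se["p_auc"]),
    discarded = discarded
  ), class = "cell_result")
}

#' @export
print.cell_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Cell (mu* = %g, mu = %g, rho = %g; n = %d, prevalence = %g), %d replicates:\n",
    cfg$mu_star, cfg$mu, cfg$rho, cfg$n, cfg$prevalence, x$replicates))
  cat(sprintf("  LRT  rejects %.3f (SE %.3f)\n", x$reject_lrt, x$mc_se_lrt))
  cat(sprintf("  Wald rejects %.3f (SE %.3f)\n", x$reject_wald, x$mc_se_wald))
  cat(sprintf("  AUC  rejects %.3f (SE %.3f)\n", x$reject_auc, x$mc_se_auc))
  if (x$discarded > 0)
    cat(sprintf("  %d draws discarded (degenerate or non-converged)\n",
                x$discarded))
  invisible(x)
}

#' Run the full simulation grid
#'
#' One [run_cell()] per combination of `mu_star`, `mu` and `rho`, each with
#' its own independent seed streams, so any cell can be recomputed in
#' isolation and results do not depend on execution order.
#'
#' @param n Sample size per replicate.
#' @param prevalence Outcome prevalence.
#' @param mu_list,mu_star_list,rho_list Grid values; the defaults are the
#'   full study grid (mu, mu* in 0, 0.1, 0.2, 0.3; rho in 0, 0.1, 0.3, 0.5).
#' @param replicates Replicates per cell.
#' @param alpha Nominal level.
#' @param master_seed Master seed.
#' @param centered Passed to the correlated generator.
#' @param verbose Print one line per finished cell.
#' @return Object of class `"grid_result"`: list with `cells` (list of
#'   `cell_result`, keyed `"mu_star=..;mu=..;rho=.."`) and `metadata`.
#' @export
run_grid <- function(n = 500, prevalence = 0.5,
                     mu_list = c(0, 0.1, 0.2, 0.3),
                     mu_star_list = c(0, 0.1, 0.2, 0.3),
                     rho_list = c(0, 0.1, 0.3, 0.5),
                     replicates = 2000L, alpha = 0.05, master_seed = 1L,
                     centered = FALSE, verbose = FALSE) {
  stopifnot(length(mu_list) > 0, length(mu_star_list) > 0, length(rho_list) > 0)
  cells <- list()
  for (ms in mu_star_list) for (m in mu_list) for (r in rho_list) {
    cfg <- sim_config(n, prevalence, mu = m, mu_star = ms, rho = r,
                      seed = master_seed)
    key <- sprintf("mu_star=%g;mu=%g;rho=%g", ms, m, r)
    cells[[key]] <- run_cell(cfg, replicates = replicates, alpha = alpha,
                             centered = centered)
    if (verbose) { print(cells[[key]]); utils::flush.console() }
  }
  structure(list(
    cells = cells,
    metadata = list(master_seed = master_seed, n = n, prevalence = prevalence,
                    replicates = replicates, alpha = alpha,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "grid_result")
}

#' Long-format data frame of grid results
#'
#' One row per (cell, test): columns `mu_star`, `mu`, `rho`, `test`,
#' `rejection_rate`, `mc_se`, `replicates`, `discarded`.
#'
#' @param x A `"grid_result"`.
#' @param ... Unused.
#' @export
as.data.frame.grid_result <- function(x, ...) {
  rows <- lapply(x$cells, function(cell) {
    cfg <- cell$config
    data.frame(
      mu_star = cfg$mu_star, mu = cfg$mu, rho = cfg$rho,
      test = c("LRT", "Wald", "AUC"),
      rejection_rate = c(cell$reject_lrt, cell$reject_wald, cell$reject_auc),
      mc_se = c(cell$mc_se_lrt, cell$mc_se_wald, cell$mc_se_auc),
      replicates = cell$replicates, discarded = cell$discarded
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wide rejection-rate table (rows mu*, mu, test; one column per rho)
#'
#' The layout of the published simulation table: for each (mu*, mu) block,
#' three rows (LRT, Wald, AUC) with rejection rates across the correlation
#' columns.
#'
#' @param grid A `"grid_result"`.
#' @return Data frame with columns `mu_star`, `mu`, `test`, then one
#'   `rho=...` column per correlation value.
#' @export
grid_wide_table <- function(grid) {
  long <- as.data.frame(grid)
  rhos <- sort(unique(long$rho))
  base <- unique(long[, c("mu_star", "mu", "test")])
  base$test <- factor(base$test, levels = c("LRT", "Wald", "AUC"))
  base <- base[order(base$mu_star, base$mu, base$test), ]
  base$test <- as.character(base$test)
  for (r in rhos) {
    sub <- long[long$rho == r, ]
    idx <- match(paste(base$mu_star, base$mu, base$test),
                 paste(sub$mu_star, sub$mu, sub$test))
    base[[sprintf("rho=%g", r)]] <- sub$rejection_rate[idx]
  }
  rownames(base) <- NULL
  base
}

#' @export
print.grid_result <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "Simulation grid: %d cells, n = %d, prevalence = %g, %d replicates/cell\n",
    length(x$cells), md$n, md$prevalence, md$replicates))
  print(grid_wide_table(x), digits = 3)
  invisible(x)
}

#' Write grid results to disk
#'
#' Writes the long-format CSV (`<stem>_long.csv`), the wide table
#' (`<stem>_wide.csv`) and a JSON metadata sidecar (`<stem>_meta.json`
#' with seed, parameters and discard counts).
#'
#' @param grid A `"grid_result"`.
#' @param stem Output path stem (directory must exist).
#' @return Invisibly, the three paths written.
#' @export
write_results <- function(grid, stem) {
  long_path <- paste0(stem, "_long.csv")
  wide_path <- paste0(stem, "_wide.csv")
  meta_path <- paste0(stem, "_meta.json")
  utils::write.csv(as.data.frame(grid), long_path, row.names = FALSE)
  utils::write.csv(grid_wide_table(grid), wide_path, row.names = FALSE)
  meta <- grid$metadata
  meta$total_discarded <- sum(vapply(grid$cells, `[[`, integer(1), "discarded"))
  meta$package_version <- as.character(utils::packageVersion("nestedAUC"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(long = long_path, wide = wide_path, meta = meta_path))
}
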