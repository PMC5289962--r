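#' Pan- and core-genome accumulation curves
#'
#' Adds genomes one at a time in random order; after each addition the pan
#' count is the union of OGs seen so far and the core count the
#' intersection. Means and standard deviations are taken over `n_orders`
#' uniform-random genome permutations; when `N! <= n_orders` every
#' permutation is enumerated exactly instead of sampled.
#'
#' @param pm binary pan-matrix (genomes x OGs) from [build_pan_matrix()].
#' @param n_orders number of genome orderings (default 1000).
#' @param seed RNG seed for permutation sampling.
#' @return list of class `accumulation_curves`: `curves` (data.frame `n`,
#'   `pan_mean`, `pan_sd`, `core_mean`, `core_sd`), per-order matrices
#'   `pan_orders` / `core_orders`, `exhaustive` flag.
#' @export
accumulation_curves <- function(pm, n_orders = 1000, seed = 1) {
  N <- nrow(pm)
  assert_that(N >= 2, "need at least two genomes")
  exhaustive <- factorial(N) <= n_orders
  orders <- if (exhaustive) all_permutations(N) else {
    set.seed(seed)
    t(replicate(n_orders, sample.int(N)))
  }
  storage.mode(pm) <- "integer"
  pan <- matrix(0L, nrow(orders), N)
  core <- matrix(0L, nrow(orders), N)
  for (r in seq_len(nrow(orders))) {
    seen <- pm[orders[r, 1], ]
    shared <- seen
    pan[r, 1] <- sum(seen); core[r, 1] <- sum(shared)
    for (i in seq_len(N)[-1]) {
      row <- pm[orders[r, i], ]
      seen <- seen | row
      shared <- shared & row
      pan[r, i] <- sum(seen); core[r, i] <- sum(shared)
    }
  }
  curves <- data.frame(n = seq_len(N),
                       pan_mean = colMeans(pan),
                       pan_sd = apply(pan, 2, sd),
                       core_mean = colMeans(core),
                       core_sd = apply(core, 2, sd))
  structure(list(curves = curves, pan_orders = pan, core_orders = core,
                 n_orders = nrow(orders), exhaustive = exhaustive,
                 seed = seed),
            class = "accumulation_curves")
}

all_permutations <- function(n) {
  assert_that(n <= 9, "exhaustive enumeration is limited to 9 genomes")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

#' Fit pan/core accumulation curves
#'
#' Nonlinear least squares on the mean curves: a Heaps/Tettelin-style power
#' law `y = A n^B + C` for the pan curve and an exponential decay
#' `y = A exp(B n) + C` for the core curve. The pan-genome is classified
#' open when the fitted exponent B exceeds zero by more than three standard
#' errors.
#'
#' @param curves an [accumulation_curves()] result.
#' @return list with `pan` and `core` fits (`model`, `A`, `B`, `C`, `B_se`,
#'   `rmse`, and for pan `open`).
#' @export
fit_curves <- function(curves) {
  cv <- curves$curves
  assert_that(nrow(cv) >= 4, "need at least four genomes to fit")
  pan <- fit_one(cv$n, cv$pan_mean, "power_law_pan")
  core <- fit_one(cv$n, cv$core_mean, "exponential_core")
  pan$open <- is.finite(pan$B_se) && pan$B > 3 * pan$B_se
  list(pan = pan, core = core)
}

fit_one <- function(n, y, model) {
  if (sd(y) < .Machine$double.eps^0.5) {
    return(list(model = model, A = 0, B = 0, C = y[1], B_se = NA_real_,
                rmse = 0))
  }
  df <- data.frame(n = n, y = y)
  fit <- tryCatch({
    if (model == "power_law_pan") {
      minpack.lm::nlsLM(y ~ A * n^B + C, data = df,
                        start = list(A = max(y[1], 1), B = 0.5,
                                     C = min(y) / 2),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ A * exp(B * n) + C, data = df,
                        start = list(A = max(y[1] - min(y), 1), B = -0.5,
                                     C = min(y)),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e)
    abort("curve fit (", model, ") failed: ", conditionMessage(e),
          "; residual range ", paste(range(y), collapse = "-")))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["B", "Std. Error"],
                 error = function(e) NA_real_)
  list(model = model, A = unname(cf["A"]), B = unname(cf["B"]),
       C = unname(cf["C"]), B_se = se,
       rmse = sqrt(mean(stats::residuals(fit)^2)))
}

#' Pan/core summary report
#'
#' Totals from the pan-matrix plus, when a lineage assignment is supplied,
#' per-lineage genome summaries (mean and sd of per-genome OG counts, as in
#' per-lineage genome content tables).
#'
#' @param pm binary pan-matrix.
#' @param lineages optional [assign_lineages()] result (or named vector of
#'   lineage labels).
#' @param soft_core_fraction fraction of genomes an OG must occupy to count
#'   as core (default 1 = strict core).
#' @return list of class `pan_core_report`: `total_ogs`, `core_ogs`,
#'   `genome_og_counts`, optionally `lineage_summary` (data.frame).
#' @export
report_pan_core <- function(pm, lineages = NULL, soft_core_fraction = 1.0) {
  n <- nrow(pm)
  core <- sum(colSums(pm) >= soft_core_fraction * n)
  counts <- rowSums(pm)
  out <- list(total_ogs = ncol(pm), core_ogs = core,
              soft_core_fraction = soft_core_fraction,
              genome_og_counts = counts)
  if (!is.null(lineages)) {
    labels <- if (inherits(lineages, "lineage_assignment"))
      lineages$labels else lineages
    labels <- labels[rownames(pm)]
    spl <- split(counts, labels)
    out$lineage_summary <- data.frame(
      lineage = names(spl),
      n_genomes = lengths(spl),
      mean_ogs = vapply(spl, mean, numeric(1)),
      sd_ogs = vapply(spl, function(x)
        if (length(x) > 1) sd(x) else 0, numeric(1)),
      row.names = NULL)
  }
  structure(out, class = "pan_core_report")
}

#' @export
print.pan_core_report <- function(x, ...) {
  cat("Pan-genome:", x$total_ogs, "OGs; core genome:", x$core_ogs,
      "OGs\n")
  cat("Per-genome OG counts:", paste(range(x$genome_og_counts),
                                     collapse = "-"), "(range)\n")
  if (!is.null(x$lineage_summary)) {
    cat("Per-lineage summary:\n")
    print(x$lineage_summary, digits = 4)
  }
  invisible(x)
}
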