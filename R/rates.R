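#' Net-distance pairs between modern and herbarium samples
#'
#' For modern sample i and herbarium sample j, both called against the same
#' lineage pseudo-reference c, the net distance is `D'_ij = D_ic - D_jc`
#' (signed SNP count, where `D_xc` is the number of derived alleles sample x
#' carries) and the time delta is `T'_ij = year_i - year_j`.  Because both
#' samples descend from the same founder, the expected net distance grows
#' linearly with the time delta at rate `mu * L`, regardless of how deep the
#' shared ancestry is -- this is what makes the regression a tip-dated clock.
#'
#' @param v a [variant_table()]
#' @param meta `sample_meta`; samples without a year are skipped with a
#'   warning
#' @param class restrict to sites of one annotation class (default all)
#' @return data.frame of class `net_distance_pairs` with columns `modern`,
#'   `herbarium`, `D_ic`, `D_jc`, `Dprime`, `Tprime`, `callable_i`,
#'   `callable_j`
#' @export
net_distance_pairs <- function(v, meta, class = NULL) {
  m <- meta[match(colnames(v$calls), meta$sample_id), ]
  if (anyNA(m$year)) {
    warning("skipping ", sum(is.na(m$year)), " sample(s) without a year")
  }
  if (!is.null(class)) {
    keep <- v$sites$class %in% class
    v <- v
    v$calls <- v$calls[keep, , drop = FALSE]
    v$sites <- v$sites[keep, , drop = FALSE]
  }
  dc <- derived_counts(v)
  cc <- callable_counts(v)
  mod <- which(m$era == "modern" & !is.na(m$year))
  her <- which(m$era == "herbarium" & !is.na(m$year))
  if (!length(mod) || !length(her))
    stop("need at least one modern and one herbarium sample")
  grid <- expand.grid(i = mod, j = her)
  ## missingness correction: rescale each sample's derived count to the full
  ## site set via its callable-site fraction, so era-specific missingness
  ## (herbarium specimens are patchier) does not deflate the slope
  S <- n_sites(v)
  adj <- if (S == 0) rep(0, length(dc)) else
    ifelse(cc > 0, dc * S / cc, NA_real_)
  out <- data.frame(
    modern = m$sample_id[grid$i], herbarium = m$sample_id[grid$j],
    D_ic = dc[grid$i], D_jc = dc[grid$j],
    Dprime = adj[grid$i] - adj[grid$j],
    Tprime = m$year[grid$i] - m$year[grid$j],
    callable_i = cc[grid$i], callable_j = cc[grid$j],
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("net_distance_pairs", "data.frame")
  out
}

#' Fit a substitution rate by net-distance regression
#'
#' Ordinary least squares of `D' = a + b T'` over all modern-herbarium pairs;
#' the slope b is the number of substitutions accumulating per year
#' genome-wide, and `rate = b / accessible_bp` is the per-site rate.  Because
#' pairs sharing a sample are not independent, the 95% confidence interval is
#' a percentile bootstrap over pairs (resampled with replacement), which
#' mitigates -- but does not fully remove -- the anti-conservativeness of the
#' analytical interval.  A sample-level bootstrap is available as an
#' alternative resampling unit.
#'
#' @param pairs a `net_distance_pairs` data.frame
#' @param accessible_bp callable genome size used to scale the slope
#' @param n_boot bootstrap replicates (default 1000)
#' @param seed RNG seed for the bootstrap
#' @param boot_unit `"pair"` (default) or `"sample"` (resample modern and
#'   herbarium sample sets and keep their induced pairs)
#' @return a `rate_estimate`: list with `rate`, `ci_low`, `ci_high`,
#'   `intercept`, `slope`, `n_boot`, `accessible_bp`, `method`, `unit`
#' @export
fit_rate <- function(pairs, accessible_bp, n_boot = 1000L, seed = 1L,
                     boot_unit = c("pair", "sample")) {
  boot_unit <- match.arg(boot_unit)
  stopifnot(accessible_bp > 0)
  if (length(unique(pairs$Tprime)) < 2)
    stop("no variance in time deltas; slope undefined")
  ols <- function(x, y) {
    xm <- mean(x); ym <- mean(y)
    b <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
    c(a = ym - b * xm, b = b)
  }
  fit <- ols(pairs$Tprime, pairs$Dprime)
  set.seed(seed)
  slopes <- rep(NA_real_, n_boot)
  if (boot_unit == "pair") {
    n <- nrow(pairs)
    for (r in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      x <- pairs$Tprime[idx]
      if (length(unique(x)) < 2) next
      slopes[r] <- ols(x, pairs$Dprime[idx])[["b"]]
    }
  } else {
    mods <- unique(pairs$modern); hers <- unique(pairs$herbarium)
    for (r in seq_len(n_boot)) {
      sm <- sample(mods, length(mods), replace = TRUE)
      sh <- sample(hers, length(hers), replace = TRUE)
      idx <- unlist(lapply(sm, function(mi)
        which(pairs$modern == mi & pairs$herbarium %in% sh)))
      x <- pairs$Tprime[idx]
      if (length(unique(x)) < 2) next
      slopes[r] <- ols(x, pairs$Dprime[idx])[["b"]]
    }
  }
  qs <- quantile(slopes, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  rate_estimate(rate = fit[["b"]] / accessible_bp,
                ci = qs / accessible_bp,
                intercept = fit[["a"]], slope = fit[["b"]],
                n_boot = n_boot, accessible_bp = accessible_bp,
                method = "net_distance", unit = "site^-1 year^-1")
}

rate_estimate <- function(rate, ci, intercept = NA, slope = NA, n_boot = 0,
                          accessible_bp = NA, method, unit) {
  structure(list(rate = unname(rate), ci_low = min(ci), ci_high = max(ci),
                 intercept = unname(intercept), slope = unname(slope),
                 n_boot = n_boot, accessible_bp = accessible_bp,
                 method = method, unit = unit),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s rate: %.3g %s (95%% CI %.3g-%.3g, %d bootstraps)\n",
              x$method, x$rate, x$unit, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Annotation-stratified substitution rates
#'
#' Runs the net-distance regression separately on each annotation class,
#' scaling by that class's accessible length.
#'
#' @param v a [variant_table()] whose `accessible_length` carries per-class bp
#' @param meta `sample_meta`
#' @param classes classes to stratify over (default: those with accessible
#'   length recorded)
#' @inheritParams fit_rate
#' @return named list of `rate_estimate`s
#' @export
stratify_rates <- function(v, meta, classes = NULL, n_boot = 1000L,
                           seed = 1L) {
  acc <- v$accessible_length
  if (is.null(classes))
    classes <- setdiff(names(acc)[acc > 0], "total")
  out <- list()
  for (cl in classes) {
    if (is.na(acc[cl]) || acc[cl] <= 0) {
      warning("class ", cl, " has no accessible length; skipped")
      next
    }
    pr <- net_distance_pairs(v, meta, class = cl)
    out[[cl]] <- fit_rate(pr, acc[[cl]], n_boot = n_boot, seed = seed)
  }
  out
}

#' Rescale a yearly rate to a per-generation rate
#'
#' Seed banks delay reproduction, so the mean generation interval exceeds one
#' year even in an annual plant; multiplying the yearly rate by the mean
#' generation time (default 1.3 years) expresses it per generation, making it
#' comparable with laboratory mutation-accumulation rates.
#'
#' @param r a `rate_estimate` in site^-1 year^-1
#' @param generation_time_years mean generation interval
#' @return a `rate_estimate` in site^-1 generation^-1
#' @export
per_generation_rate <- function(r, generation_time_years = 1.3) {
  stopifnot(generation_time_years > 0)
  rate_estimate(rate = r$rate * generation_time_years,
                ci = c(r$ci_low, r$ci_high) * generation_time_years,
                intercept = r$intercept, slope = r$slope, n_boot = r$n_boot,
                accessible_bp = r$accessible_bp, method = r$method,
                unit = "site^-1 generation^-1")
}

#' Date the most recent common ancestor of the lineage
#'
#' With a per-site, per-year substitution rate `mu`, the expected per-site
#' distance between two samples is twice the time back to their common
#' ancestor: solving `d = 2 L mu` gives the TMRCA depth `L` in years, and
#' subtracting it from the mean collection year dates the founding.
#'
#' @param mean_pairwise_d_per_site mean pairwise distance per accessible site
#' @param mu substitution rate, site^-1 year^-1 (> 0)
#' @param mean_collection_year average collection year of the samples used
#' @return list with `L_years` and `root_year`
#' @export
estimate_tmrca <- function(mean_pairwise_d_per_site, mu,
                           mean_collection_year) {
  if (mu <= 0) stop("mu must be positive")
  if (mean_pairwise_d_per_site < 0) stop("distance must be nonnegative")
  L <- mean_pairwise_d_per_site / (2 * mu)
  list(L_years = L, root_year = mean_collection_year - L)
}

#' Mean pairwise per-site distance of a sample set
#'
#' Average over all unordered sample pairs of the missing-data-corrected SNP
#' distance divided by the accessible genome length; the `d` that enters
#' [estimate_tmrca()].
#'
#' @param pd a `pairwise_distances` object
#' @param accessible_bp callable genome size
#' @param samples optional sample ids to restrict to (e.g. modern only)
#' @export
mean_pairwise_distance <- function(pd, accessible_bp, samples = NULL) {
  d <- pd$d; cal <- pd$callable
  if (!is.null(samples)) {
    k <- match(samples, colnames(d))
    d <- d[k, k]; cal <- cal[k, k]
  }
  ut <- upper.tri(d)
  S <- max(diag(cal))
  corr <- d[ut] * ifelse(cal[ut] > 0, S / cal[ut], NA)
  mean(corr, na.rm = TRUE) / accessible_bp
}

#' Mutation rate from mutation-accumulation lines
#'
#' Pooled estimator `rate = sum(counts) / sum(generations * callable_bp)`.
#' The 95% CI is a line-level bootstrap t-interval (point estimate +/-
#' t[n-1] x bootstrap standard error): with the typical dozen MA lines a
#' percentile interval is noticeably anticonservative, while the t-interval
#' holds close to nominal coverage.  With a single line the bootstrap
#' degenerates and an exact Poisson interval is used instead.
#'
#' @param counts per-line mutation counts
#' @param generations per-line generation numbers (recycled if scalar)
#' @param callable_bp per-line callable bp (recycled if scalar)
#' @param n_boot bootstrap replicates
#' @param seed RNG seed
#' @return a `rate_estimate` in site^-1 generation^-1
#' @export
ma_mutation_rate <- function(counts, generations, callable_bp,
                             n_boot = 1000L, seed = 1L) {
  n <- length(counts)
  generations <- rep_len(generations, n)
  callable_bp <- rep_len(callable_bp, n)
  stopifnot(all(counts >= 0), all(generations > 0), all(callable_bp > 0))
  expo <- generations * callable_bp
  rate <- sum(counts) / sum(expo)
  if (n == 1) {
    x <- counts[1]
    ci <- c(if (x == 0) 0 else stats::qgamma(0.025, x),
            stats::qgamma(0.975, x + 1)) / expo[1]
  } else {
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(r) {
      idx <- sample.int(n, n, replace = TRUE)
      sum(counts[idx]) / sum(expo[idx])
    }, numeric(1))
    half <- stats::qt(0.975, n - 1) * stats::sd(boot)
    ci <- c(max(0, rate - half), rate + half)
  }
  rate_estimate(rate = rate, ci = ci, n_boot = if (n == 1) 0L else n_boot,
                accessible_bp = sum(callable_bp), method = "ma_lines",
                unit = "site^-1 generation^-1")
}
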