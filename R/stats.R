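#' Repeated-measures BMD table
#'
#' Per-cell BMD across knees and repeated measurements (cells x knees x
#' repeats), the input of the reliability/reproducibility evaluation. `NA`
#' marks cells missing for a knee/repeat; such cells are excluded listwise
#' (per cell) before analysis.
#'
#' @param values 3D numeric array: cells x knees x repeats (mg/cc).
#' @param cell_ids optional identifiers for the first dimension.
#' @return An object of class `repeated_measures`.
#' @export
repeated_measures <- function(values, cell_ids = NULL) {
  values <- as.array(values)
  d <- dim(values)
  if (length(d) != 3L) stop("values must be a cells x knees x repeats array")
  if (d[3] < 2L) stop("at least 2 repeats are required")
  if (d[2] < 2L) stop("at least 2 knees are required")
  if (!is.null(cell_ids) && length(cell_ids) != d[1])
    stop("cell_ids length must match the number of cells")
  structure(list(values = values, cell_ids = cell_ids %||% seq_len(d[1]),
                 n_cells = d[1], n_knees = d[2], n_repeats = d[3]),
            class = "repeated_measures")
}

#' @export
print.repeated_measures <- function(x, ...) {
  cat(sprintf("repeated_measures: %d cells x %d knees x %d repeats\n",
              x$n_cells, x$n_knees, x$n_repeats))
  invisible(x)
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Single-measurement absolute-agreement ICC from the two-way ANOVA mean
#' squares of an `n` knees x `k` repeats matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`,
#' where MSR, MSC and MSE are the rows (knees), columns (repeats) and residual
#' mean squares.
#'
#' @param cell_values n x k numeric matrix (no missing entries).
#' @return the ICC, or `NA` when the total variance is zero (degenerate cell).
#' @export
icc_two_way_random <- function(cell_values) {
  y <- as.matrix(cell_values)
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2) stop("ICC needs >= 2 knees and >= 2 repeats")
  if (anyNA(y)) stop("ICC input must have no missing entries")
  m <- mean(y)
  if (sum((y - m)^2) < 1e-24 * max(1, m^2)) return(NA_real_)
  ri <- rowMeans(y); cj <- colMeans(y)
  msr <- k * sum((ri - m)^2) / (n - 1)
  msc <- n * sum((cj - m)^2) / (k - 1)
  mse <- sum((y - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + m)^2) /
    ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300) return(NA_real_)
  (msr - mse) / denom
}

#' Classify an ICC value
#'
#' Poor (< 0.5), moderate (0.5 to < 0.75), good (0.75 to < 0.9), excellent
#' (>= 0.9; the 0.9 boundary is assigned to excellent).
#' @param icc numeric vector of finite ICC values (`NA` passes through).
#' @return character vector of classes.
#' @export
classify_icc <- function(icc) {
  out <- rep(NA_character_, length(icc))
  ok <- !is.na(icc)
  out[ok & icc < 0.5] <- "poor"
  out[ok & icc >= 0.5 & icc < 0.75] <- "moderate"
  out[ok & icc >= 0.75 & icc < 0.9] <- "good"
  out[ok & icc >= 0.9] <- "excellent"
  out
}

#' Root-mean-square precision error (RMSSD)
#'
#' Per-knee sample standard deviation across repeats (denominator `k - 1`),
#' then the root mean square across knees: `sqrt(mean(SD_i^2))`. In mg/cc.
#' @param cell_values n x k numeric matrix (no missing entries).
#' @return the RMSSD.
#' @export
rmssd <- function(cell_values) {
  y <- as.matrix(cell_values)
  if (ncol(y) < 2) stop("RMSSD needs >= 2 repeats")
  if (anyNA(y)) stop("RMSSD input must have no missing entries")
  sds <- apply(y, 1, sd)
  sqrt(mean(sds^2))
}

#' Paired comparison of per-cell metrics between two settings
#'
#' Two-sided Wilcoxon signed-rank test with the normal approximation: zero
#' differences are dropped, tied absolute differences get average ranks (with
#' the tie correction in the variance), and no continuity correction is
#' applied. `exact = TRUE` instead evaluates the exact null distribution of
#' the signed-rank statistic for the observed (possibly tied) ranks. The
#' effect size is `r = |z| / sqrt(N)` with `N` the number of non-zero pairs.
#'
#' @param map_a_cells,map_b_cells equal-length paired metric vectors (cells in
#'   the same order); pairs with a missing value are dropped.
#' @param n_comparisons Bonferroni multiplier (default 3: the three pairwise
#'   setting comparisons); `p_adjusted = min(1, n_comparisons * p_raw)`.
#' @param exact use the exact permutation null of the rank sum.
#' @return list with `z`, `p_raw`, `p_adjusted`, `effect_size`, `n`.
#' @export
compare_settings <- function(map_a_cells, map_b_cells, n_comparisons = 3,
                             exact = FALSE) {
  a <- as.numeric(map_a_cells); b <- as.numeric(map_b_cells)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(z = 0, p_raw = 1, p_adjusted = 1, effect_size = 0, n = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0)
    return(list(z = 0, p_raw = 1, p_adjusted = 1, effect_size = 0, n = n))
  z <- (W - mu) / sqrt(sigma2)
  if (exact) {
    p <- exact_signed_rank_p(r, W)
  } else {
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(z = z, p_raw = p, p_adjusted = min(1, n_comparisons * p),
       effect_size = abs(z) / sqrt(n), n = n)
}

# exact two-sided p for the signed-rank statistic given the (tied) ranks:
# enumerates the 2^n equiprobable sign patterns by convolution over doubled
# ranks (integers even with average ranks .5)
exact_signed_rank_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  dist <- numeric(total + 1)          # index = value of 2W, offset +1
  dist[1] <- 1
  for (v in r2) {
    shifted <- c(rep(0, v), dist[seq_len(total + 1 - v)])
    dist <- 0.5 * dist + 0.5 * shifted
  }
  w2 <- as.integer(round(2 * W))
  mu2 <- total / 2
  dev <- abs(w2 - mu2)
  vals <- 0:total
  min(1, sum(dist[abs(vals - mu2) >= dev - 1e-9]))
}

#' Evaluate reliability and reproducibility across experimental settings
#'
#' Computes per-cell ICC(2,1) and RMSSD for each setting, summarizes them as
#' median and quartiles over cells, reports the fraction of cells with
#' excellent reliability, and compares settings pairwise with Wilcoxon
#' signed-rank tests (Bonferroni-adjusted over the number of pairs).
#'
#' Cells with a missing value in any knee/repeat of a setting are excluded
#' from that setting's per-cell statistics (complete case per cell); cells
#' with zero total variance are flagged degenerate and excluded from the
#' summaries.
#'
#' @param settings named list of [repeated_measures()] (or cells x knees x
#'   repeats arrays) with identical cell sets.
#' @param n_comparisons Bonferroni multiplier; defaults to the number of
#'   setting pairs.
#' @param exact passed to [compare_settings()].
#' @return list with `per_cell` (data.frame: icc, icc_class, rmssd per
#'   setting), `summary` (per setting: medians, quartiles, pct_excellent),
#'   `comparisons` (per pair and metric: z, p_raw, p_adjusted, effect_size).
#' @export
evaluate_settings <- function(settings, n_comparisons = NULL, exact = FALSE) {
  if (is.null(names(settings)) || any(!nzchar(names(settings))))
    names(settings) <- paste0("setting", seq_along(settings))
  rms <- lapply(settings, function(s) {
    if (inherits(s, "repeated_measures")) s else repeated_measures(s)
  })
  ncells <- unique(vapply(rms, `[[`, numeric(1), "n_cells"))
  if (length(ncells) != 1)
    stop("all settings must share the same cell grid (cell counts differ)")
  ids <- rms[[1]]$cell_ids
  for (s in rms) if (!identical(s$cell_ids, ids))
    stop("all settings must share the same cell grid (cell ids differ)")
  per_cell <- data.frame(cell = ids)
  for (nm in names(rms)) {
    v <- rms[[nm]]$values
    icc <- numeric(ncells); rms_v <- numeric(ncells)
    for (c in seq_len(ncells)) {
      y <- v[c, , , drop = TRUE]
      if (anyNA(y)) {
        icc[c] <- NA_real_; rms_v[c] <- NA_real_
      } else {
        icc[c] <- icc_two_way_random(y)
        rms_v[c] <- rmssd(y)
      }
    }
    per_cell[[paste0("icc_", nm)]] <- icc
    per_cell[[paste0("icc_class_", nm)]] <- classify_icc(icc)
    per_cell[[paste0("rmssd_", nm)]] <- rms_v
  }
  q3 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  }
  summary_tab <- do.call(rbind, lapply(names(rms), function(nm) {
    icc <- per_cell[[paste0("icc_", nm)]]
    rv <- per_cell[[paste0("rmssd_", nm)]]
    qi <- q3(icc); qr <- q3(rv)
    data.frame(setting = nm,
               icc_median = qi[1], icc_q1 = qi[2], icc_q3 = qi[3],
               rmssd_median = qr[1], rmssd_q1 = qr[2], rmssd_q3 = qr[3],
               pct_excellent = 100 * mean(icc[!is.na(icc)] > 0.9),
               n_cells = sum(!is.na(icc)))
  }))
  pairs <- if (length(rms) >= 2) utils::combn(names(rms), 2, simplify = FALSE)
           else list()
  if (is.null(n_comparisons)) n_comparisons <- max(1L, length(pairs))
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(c("icc", "rmssd"), function(metric) {
      cmp <- compare_settings(per_cell[[paste0(metric, "_", pr[1])]],
                              per_cell[[paste0(metric, "_", pr[2])]],
                              n_comparisons = n_comparisons, exact = exact)
      data.frame(pair = paste(pr[1], "vs", pr[2]), metric = metric,
                 z = cmp$z, p_raw = cmp$p_raw, p_adjusted = cmp$p_adjusted,
                 effect_size = cmp$effect_size, n = cmp$n)
    }))
  }))
  list(per_cell = per_cell, summary = summary_tab, comparisons = comparisons)
}

#' Assemble a repeated-measures table from standardized BMD maps
#'
#' Stacks the interior-cell means of one map per knee and repeat into a
#' cells x knees x repeats array; all maps must be on an identical grid.
#' Cells missing (empty) in a map become `NA`.
#'
#' @param maps list over knees, each a list over repeats of `bmd_map` objects.
#' @return a [repeated_measures()].
#' @export
repeated_measures_from_maps <- function(maps) {
  g0 <- maps[[1]][[1]]$grid
  same_grid <- function(g) {
    identical(g$dims, g0$dims) && isTRUE(all.equal(g$origin, g0$origin)) &&
      isTRUE(all.equal(g$cell_size, g0$cell_size))
  }
  lin <- which(g0$interior_mask)
  n_knees <- length(maps)
  n_repeats <- length(maps[[1]])
  vals <- array(NA_real_, dim = c(length(lin), n_knees, n_repeats))
  for (i in seq_len(n_knees)) {
    if (length(maps[[i]]) != n_repeats) stop("unequal repeat counts across knees")
    for (j in seq_len(n_repeats)) {
      m <- maps[[i]][[j]]
      if (!inherits(m, "bmd_map")) stop("maps must be bmd_map objects")
      if (!same_grid(m$grid)) stop("all maps must share the same cell grid")
      vals[, i, j] <- m$mean[lin]
    }
  }
  repeated_measures(vals, cell_ids = lin)
}
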