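# Correlation structure and statistics: pairwise Pearson correlations with
# the 5-minute simultaneous-recording gate, Fisher z-domain averaging,
# exponential correlation-versus-distance fits, covariance-based slope
# comparison, and the ANOVA / Kruskal-Wallis routing used for group
# comparisons.

#' Pairwise Pearson correlations between detrended traces
#'
#' Traces are detrended by subtracting a rolling median, then correlated
#' pairwise over their overlapping valid (non-gap) samples. Pairs with less
#' than `min_overlap_s` of simultaneous recording are marked invalid and
#' carry no r value.
#'
#' @param traces list of trace objects with `dff` computed.
#' @param detrend_window_s rolling-median window (default 20 s).
#' @param min_overlap_s minimum simultaneous valid time (default 300 s).
#' @return list of class `correlation_matrix`: `r`, `overlap_s`, `valid`
#'   (matrices), `labels`.
#' @export
pairwise_correlations <- function(traces, detrend_window_s = 20,
                                  min_overlap_s = 300) {
  stopifnot(length(traces) >= 2L)
  fr <- traces[[1]]$frame_rate
  labels <- vapply(traces, function(t) t$roi_label, integer(1))
  det <- lapply(traces, function(t) {
    t$dff - rolling_median(t$dff, round(detrend_window_s * fr))
  })
  valid_masks <- lapply(traces, function(t) !t$gap_mask)
  n <- length(traces)
  r <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  ov <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    r[i, i] <- 1
    ov[i, i] <- sum(valid_masks[[i]]) / fr
    for (j in seq_len(n)) {
      if (j <= i) next
      both <- valid_masks[[i]] & valid_masks[[j]]
      ov[i, j] <- ov[j, i] <- sum(both) / fr
      if (ov[i, j] >= min_overlap_s) {
        r[i, j] <- r[j, i] <- stats::cor(det[[i]][both], det[[j]][both])
      }
    }
  }
  structure(list(r = r, overlap_s = ov, valid = ov >= min_overlap_s,
                 labels = labels),
            class = "correlation_matrix")
}

#' Fisher z-domain average and SD of correlation coefficients
#'
#' Computes `z = arctanh(r)`, averages in the z domain and maps back:
#' `avg(r) = tanh(mean(z))`, `SD(r) = tanh(sd(z))` (sample SD).
#'
#' @param r numeric vector of correlation coefficients, all `|r| < 1`.
#' @param na.rm drop `NA` values first.
#' @return list with `mean_r`, `sd_r`, `n`.
#' @export
fisher_average <- function(r, na.rm = TRUE) {
  if (na.rm) r <- r[!is.na(r)]
  if (any(abs(r) >= 1)) stop("fisher_average requires |r| < 1")
  z <- atanh(r)
  list(mean_r = tanh(mean(z)),
       sd_r = if (length(z) > 1L) tanh(stats::sd(z)) else NA_real_,
       n = length(z))
}

#' Correlation as a function of distance, with exponential fit
#'
#' Pairwise centroid distances are binned; each bin's correlations are
#' Fisher-averaged; the binned profile is fitted with
#' `r(d) = A * exp(-d / lambda)` by nonlinear least squares. Profiles with
#' no detectable decay (log-linear slope not negative) are flagged flat
#' and return `lambda = Inf`.
#'
#' @param corr a `correlation_matrix` from [pairwise_correlations()].
#' @param centroids data.frame with `label`, `x_um`, `y_um` (e.g. from a
#'   [roi_set()]).
#' @param bin_um distance bin width (default 10).
#' @param min_pairs_per_bin bins with fewer valid pairs are dropped.
#' @return list with `profile` (bin centres, Fisher mean/SD, pair counts),
#'   `A`, `lambda_um`, `flat`, and the `nls` fit (or `NULL`).
#' @export
correlation_vs_distance <- function(corr, centroids, bin_um = 10,
                                    min_pairs_per_bin = 1L) {
  labs <- corr$labels
  pos <- centroids[match(labs, centroids$label), ]
  n <- length(labs)
  ut <- upper.tri(corr$r)
  dmat <- as.matrix(stats::dist(cbind(pos$x_um, pos$y_um)))
  d <- dmat[ut]
  r <- corr$r[ut]
  keep <- !is.na(r)
  d <- d[keep]; r <- r[keep]
  if (!length(d)) stop("no valid pairs")
  breaks <- seq(0, max(d) + bin_um, by = bin_um)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  prof <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    rs <- r[bin == b]
    if (length(rs) < min_pairs_per_bin) return(NULL)
    fa <- fisher_average(rs)
    data.frame(d_um = (breaks[b] + breaks[b + 1]) / 2,
               r_mean = fa$mean_r, r_sd = fa$sd_r, n_pairs = fa$n)
  }))
  if (is.null(prof) || nrow(prof) < 3L) stop("need at least 3 populated bins")
  pos_bins <- prof$r_mean > 0
  flat <- FALSE
  lambda <- Inf
  A <- mean(prof$r_mean)
  fit <- NULL
  if (sum(pos_bins) >= 3L) {
    lf <- stats::lm(log(r_mean) ~ d_um, data = prof[pos_bins, ])
    slope <- unname(stats::coef(lf)[2])
    if (is.finite(slope) && slope < -1e-6) {
      start <- list(A = exp(unname(stats::coef(lf)[1])),
                    lambda = -1 / slope)
      fit <- tryCatch(
        minpack.lm::nlsLM(r_mean ~ A * exp(-d_um / lambda), data = prof,
                          start = start,
                          lower = c(A = 0, lambda = 1e-3),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- stats::coef(fit)
        A <- unname(cf["A"]); lambda <- unname(cf["lambda"])
      } else {
        A <- start$A; lambda <- start$lambda
      }
    } else {
      flat <- TRUE
    }
  } else {
    flat <- TRUE
  }
  list(profile = prof, A = A, lambda_um = lambda, flat = flat, fit = fit)
}

#' Linear fit exposing its covariance matrix
#'
#' Ordinary least squares `y ~ x` packaged with the estimate covariance so
#' slopes of independent fits can be compared.
#'
#' @param x,y numeric vectors.
#' @return list of class `fit_result`: `estimates`, `cov`, `slope`,
#'   `slope_var`, `df`, `sigma`.
#' @export
linear_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  v <- stats::vcov(fit)
  structure(list(estimates = stats::coef(fit), cov = v,
                 slope = unname(stats::coef(fit)[2]),
                 slope_var = v[2, 2], df = fit$df.residual,
                 sigma = summary(fit)$sigma, model = fit),
            class = "fit_result")
}

#' Compare the slopes of two linear fits
#'
#' Two-tailed Student's t-test on the slope difference using the estimated
#' covariance matrices (Welch-Satterthwaite degrees of freedom), with
#' Bonferroni correction for `n_comparisons`.
#'
#' @param fit1,fit2 `fit_result` objects from [linear_fit()].
#' @param n_comparisons number of pairwise comparisons in the family.
#' @return list with `t`, `df`, `p`, `p_adjusted`.
#' @export
compare_slopes <- function(fit1, fit2, n_comparisons = 1L) {
  v1 <- fit1$slope_var; v2 <- fit2$slope_var
  se <- sqrt(v1 + v2)
  if (se == 0) {
    t <- 0; df <- fit1$df + fit2$df
  } else {
    t <- (fit1$slope - fit2$slope) / se
    df <- (v1 + v2)^2 / (v1^2 / fit1$df + v2^2 / fit2$df)
  }
  p <- if (se == 0 && fit1$slope == fit2$slope) 1 else
    2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, p_adjusted = min(1, p * n_comparisons))
}

#' Group comparison with normality routing
#'
#' Shapiro-Wilk screens each group; if all pass at `normality_alpha` the
#' comparison is one-way ANOVA with Tukey's post hoc, otherwise
#' Kruskal-Wallis with Dunn's post hoc (Bonferroni-adjusted). The route
#' taken is part of the report.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param normality_alpha Shapiro-Wilk alpha (default 0.05).
#' @return list with `route` (`"anova"` / `"kruskal"`), `p` (omnibus),
#'   `posthoc` (data.frame of pairwise adjusted p values), `shapiro_p`.
#' @export
group_compare <- function(samples, normality_alpha = 0.05) {
  stopifnot(length(samples) >= 2L)
  g <- factor(rep(names(samples), lengths(samples)),
              levels = names(samples))
  x <- unlist(samples, use.names = FALSE)
  shapiro_p <- vapply(samples, function(s) {
    if (length(unique(s)) < 3L || length(s) < 3L) return(NA_real_)
    stats::shapiro.test(s)$p.value
  }, numeric(1))
  normal <- all(is.na(shapiro_p) | shapiro_p > normality_alpha)
  if (normal) {
    fit <- stats::aov(x ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    posthoc <- data.frame(comparison = rownames(tk),
                          p_adjusted = tk[, "p adj"], row.names = NULL)
    route <- "anova"
  } else {
    kw <- stats::kruskal.test(x, g)
    p <- kw$p.value
    posthoc <- dunn_posthoc(x, g)
    route <- "kruskal"
  }
  list(route = route, p = p, posthoc = posthoc, shapiro_p = shapiro_p)
}

# Dunn's post hoc test: pairwise z statistics on mean ranks with tie
# correction, Bonferroni-adjusted two-sided p values.
dunn_posthoc <- function(x, g) {
  n <- length(x)
  rk <- rank(x)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  groups <- levels(g)
  mean_rank <- tapply(rk, g, mean)
  n_g <- tapply(rk, g, length)
  m <- length(groups)
  pairs <- utils::combn(m, 2)
  n_comp <- ncol(pairs)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / n_g[i] + 1 / n_g[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    c(z = unname(z), p = unname(p))
  })
  data.frame(comparison = paste(groups[pairs[1, ]], groups[pairs[2, ]],
                                sep = "-"),
             z = out["z", ],
             p_adjusted = pmin(1, out["p", ] * n_comp))
}
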