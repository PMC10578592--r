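#' Misclassification error of the binary model
#'
#' Predicted class is the fitted conditional response thresholded at 0.5;
#' the error is the percentage of trials mispredicted. Lower is better.
#'
#' @param fit binomial `pain_glme`.
#' @return error percentage in [0, 100].
#' @export
binary_error_percent <- function(fit) {
  stopifnot(inherits(fit, "pain_glme"))
  if (fit$family != "binomial") stop("error percentage is for the binomial model")
  y <- fit$features$y_binary
  if (!length(y)) stop("empty feature set")
  pred <- as.integer(fit$fitted_conditional >= 0.5)
  100 * mean(pred != y)
}

#' Mean absolute error of the VAS model
#'
#' @param fit gaussian `pain_glme`.
#' @return mean absolute difference between real and fitted conditional VAS.
#' @export
vas_mae <- function(fit) {
  stopifnot(inherits(fit, "pain_glme"))
  if (fit$family != "gaussian") stop("VAS error is for the gaussian model")
  mean(abs(fit$features$y_vas - fit$fitted_conditional))
}

#' Linear reading of a binomial coefficient as a percent change
#'
#' Returns `100 * beta`: the conventional interpretation of the fixed-effect
#' coefficient as the percent change in the proportion of "yes" responses per
#' unit HFA. This linearises the logit slope around the operating point and
#' is an approximation; it is how such coefficients are commonly quoted.
#'
#' @param beta binomial-model fixed-effect coefficient.
#' @return percent change per unit HFA.
#' @export
coefficient_to_percent <- function(beta) 100 * beta

#' t-statistic heatmap matrix from a window scan
#'
#' Reshapes scan results for one event and family into a regions-by-windows
#' matrix of real t-statistics with a parallel significance matrix (used to
#' outline significant cells), and optionally renders and exports it.
#'
#' @param scan `pain_scan` from [scan_windows()].
#' @param family,event which slice of the scan to reshape.
#' @param file optional TSV path for the matrix export.
#' @param plot draw the heatmap (base graphics).
#' @return list of class `pain_heatmap` with `t` and `significant` matrices
#'   (rows regions, columns windows labelled `start:end`).
#' @export
tstat_heatmap <- function(scan, family = "binomial", event = "hand_on",
                          file = NULL, plot = FALSE) {
  sel <- scan$family == family & scan$event == event
  s <- scan[sel, , drop = FALSE]
  regions <- sort(unique(s$region))
  wins <- unique(s[, c("win_start", "win_end")])
  wins <- wins[order(wins$win_start), , drop = FALSE]
  lab <- paste0(wins$win_start, ":", wins$win_end)
  tmat <- matrix(NA_real_, length(regions), nrow(wins),
                 dimnames = list(regions, lab))
  smat <- matrix(FALSE, length(regions), nrow(wins),
                 dimnames = list(regions, lab))
  for (i in seq_len(nrow(s))) {
    r <- s$region[i]
    w <- paste0(s$win_start[i], ":", s$win_end[i])
    tmat[r, w] <- s$t_real[i]
    smat[r, w] <- isTRUE(s$significant[i])
  }
  if (!is.null(file)) {
    utils::write.table(cbind(region = rownames(tmat), as.data.frame(tmat)),
                       file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out <- structure(list(t = tmat, significant = smat, family = family,
                        event = event), class = "pain_heatmap")
  if (plot) plot(out)
  out
}

#' @export
plot.pain_heatmap <- function(x, ...) {
  tmat <- x$t
  nr <- nrow(tmat); nc <- ncol(tmat)
  z <- t(tmat)[, rev(seq_len(nr)), drop = FALSE]
  graphics::image(seq_len(nc), seq_len(nr), z, axes = FALSE,
                  xlab = "window (ms)", ylab = "",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  main = sprintf("%s model, %s", x$family, x$event), ...)
  graphics::axis(1, at = seq_len(nc), labels = colnames(tmat), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(tmat)), las = 1,
                 cex.axis = 0.7)
  sig <- t(x$significant)[, rev(seq_len(nr)), drop = FALSE]
  for (i in seq_len(nc)) for (j in seq_len(nr))
    if (isTRUE(sig[i, j]))
      graphics::rect(i - 0.5, j - 0.5, i + 0.5, j + 0.5, border = "black",
                     lwd = 2)
  # event boundaries at 0 ms
  zero <- which(vapply(strsplit(colnames(tmat), ":"), function(p)
    as.numeric(p[1]) <= 0 && as.numeric(p[2]) > 0, logical(1)))
  if (length(zero)) graphics::abline(v = zero[1] - 0.5, lty = 3)
  invisible(x)
}

#' Read back an exported heatmap matrix
#'
#' @param file TSV written by [tstat_heatmap()].
#' @return numeric matrix with region rownames.
#' @export
read_heatmap_tsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$region
  m
}

#' Fitted-versus-real scatter for the VAS model
#'
#' Emits the (real, fitted-conditional) pairs and their Spearman rank
#' correlation; on data with a real HFA-VAS relationship the correlation is
#' positive and the point cloud hugs the identity line.
#'
#' @param fit gaussian `pain_glme`.
#' @param plot draw the scatter.
#' @return list with `pairs` (data.frame real, fitted) and `rank_cor`.
#' @export
fitted_vs_real_scatter <- function(fit, plot = FALSE) {
  stopifnot(inherits(fit, "pain_glme"))
  if (fit$family != "gaussian") stop("scatter is defined for the VAS model")
  pairs <- data.frame(real = fit$features$y_vas,
                      fitted = fit$fitted_conditional)
  rc <- if (stats::sd(pairs$real) == 0 || stats::sd(pairs$fitted) == 0) NA_real_
        else stats::cor(pairs$real, pairs$fitted, method = "spearman")
  if (plot) {
    graphics::plot(pairs$real, pairs$fitted, xlab = "real VAS",
                   ylab = "fitted conditional VAS",
                   main = sprintf("rank correlation %.2f", rc))
    graphics::abline(0, 1, lty = 2)
  }
  list(pairs = pairs, rank_cor = rc)
}

#' Accuracy report over significant windows
#'
#' For each significant row of a scan, refits the model and computes the
#' accuracy metric (misclassification percent for the binomial model, mean
#' absolute error for the VAS model).
#'
#' @param scan `pain_scan`.
#' @param proc the `pain_hfa_study` the scan was computed from.
#' @return data.frame with one row per significant test: region, event,
#'   window, family, `error_percent` (binomial) or `mae_vas` (gaussian),
#'   `n_trials`.
#' @export
accuracy_report <- function(scan, proc) {
  sel <- which(scan$significant %in% TRUE)
  rows <- lapply(sel, function(i) {
    feats <- build_features(proc, scan$region[i], scan$event[i],
                            c(scan$win_start[i], scan$win_end[i]))
    fit <- fit_glme(feats, scan$family[i])
    data.frame(region = scan$region[i], event = scan$event[i],
               win_start = scan$win_start[i], win_end = scan$win_end[i],
               family = scan$family[i],
               error_percent = if (scan$family[i] == "binomial")
                 binary_error_percent(fit) else NA_real_,
               mae_vas = if (scan$family[i] == "gaussian") vas_mae(fit)
                 else NA_real_,
               n_trials = fit$n_obs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region = character(), event = character(),
                      win_start = numeric(), win_end = numeric(),
                      family = character(), error_percent = numeric(),
                      mae_vas = numeric(), n_trials = integer())
  out
}
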