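#' Fit the intensity-dependent replicate noise model
#'
#' For every (probe set, time point) pair the replicate mean and standard
#' deviation are computed; pairs are binned by mean intensity (equal-count
#' bins) and the per-bin noise estimate is the median of the replicate SDs,
#' rescaled to be a consistent estimator of sigma under Gaussian noise
#' (the median of a sample SD at R replicates underestimates sigma; the
#' correction factor is `sqrt(qchisq(0.5, R-1)/(R-1))`). A decreasing
#' isotonic regression enforces the characteristic monotone decline of
#' noise with intensity, and estimates are floored at 1e-3 so degenerate
#' (constant) inputs never produce infinite z-scores.
#'
#' @param sig a [signal_set()].
#' @param n_bins number of intensity bins, default 50.
#' @return object of class `noise_model`: a grid of `(intensity, sd)` pairs
#'   evaluated by linear interpolation with flat extrapolation.
#' @export
fit_noise <- function(sig, n_bins = 50) {
  samples <- sig$samples
  R <- n_replicates(samples)
  if (R < 2L) stop("need >= 2 replicates per time point to estimate noise")
  tp <- time_points(samples)
  mu <- sd_ <- NULL
  for (t in tp) {
    cols <- .time_cols(sig$values, samples, t)
    x <- sig$values[, cols, drop = FALSE]
    m <- rowMeans(x)
    s <- sqrt(rowSums((x - m)^2) / (length(cols) - 1L))
    mu <- c(mu, m); sd_ <- c(sd_, s)
  }
  ok <- is.finite(mu) & is.finite(sd_)
  mu <- mu[ok]; sd_ <- sd_[ok]
  n_bins <- max(1L, min(n_bins, floor(length(mu) / 2L)))
  br <- unique(stats::quantile(mu, seq(0, 1, length.out = n_bins + 1L), type = 7))
  bin <- cut(mu, br, include.lowest = TRUE)
  centers <- as.numeric(tapply(mu, bin, stats::median))
  med_sd <- as.numeric(tapply(sd_, bin, stats::median))
  keep <- is.finite(centers) & is.finite(med_sd)
  centers <- centers[keep]; med_sd <- med_sd[keep]
  # consistency correction for median-of-SDs under Gaussian noise
  cmed <- sqrt(stats::qchisq(0.5, df = R - 1L) / (R - 1L))
  med_sd <- med_sd / cmed
  o <- order(centers)
  centers <- centers[o]; med_sd <- med_sd[o]
  if (length(centers) > 1L) {
    fit <- stats::isoreg(centers, -med_sd)  # decreasing fit
    sd_hat <- -fit$yf
  } else sd_hat <- med_sd
  sd_hat <- pmax(sd_hat, 1e-3)
  structure(list(intensity = centers, sd = sd_hat, n_replicates = R),
            class = "noise_model")
}

#' Evaluate the noise model
#'
#' @param model a `noise_model`.
#' @param intensity numeric vector of mean log2 intensities.
#' @return replicate SD estimates (linear interpolation, flat
#'   extrapolation, floored at 1e-3).
#' @export
predict_sd <- function(model, intensity) {
  if (length(model$intensity) == 1L)
    return(rep(model$sd, length(intensity)))
  out <- stats::approx(model$intensity, model$sd, xout = intensity,
                       rule = 2)$y
  pmax(out, 1e-3)
}

#' @export
print.noise_model <- function(x, ...) {
  cat("noise_model:", length(x$intensity), "bins, sd range [",
      round(min(x$sd), 4), ",", round(max(x$sd), 4), "], R =",
      x$n_replicates, "\n")
  invisible(x)
}

#' Variance of a log2 fold change between two replicate means
#'
#' @param model a `noise_model`.
#' @param I_t,I_0 mean intensities at the stimulated and pre-stimulus time
#'   point (vectors recycled together).
#' @param R replicates per time point.
#' @return `sd(I_t)^2/R + sd(I_0)^2/R`.
#' @export
fc_variance <- function(model, I_t, I_0, R) {
  predict_sd(model, I_t)^2 / R + predict_sd(model, I_0)^2 / R
}

#' Write / read a noise model as TSV
#'
#' @param model a `noise_model`.
#' @param path TSV with columns `intensity`, `sd` (plus a comment header
#'   carrying the replicate count).
#' @return `path` (write) or a `noise_model` (read).
#' @export
write_noise_model <- function(model, path) {
  con <- file(path, "w")
  writeLines(paste0("# n_replicates=", model$n_replicates), con)
  utils::write.table(data.frame(intensity = model$intensity, sd = model$sd),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_noise_model
#' @export
read_noise_model <- function(path) {
  hdr <- readLines(path, n = 1L)
  R <- as.integer(sub(".*n_replicates=", "", hdr))
  df <- utils::read.delim(path, comment.char = "#")
  structure(list(intensity = df$intensity, sd = df$sd, n_replicates = R),
            class = "noise_model")
}
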