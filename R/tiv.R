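#' Probe-set fold changes versus the pre-stimulus time point
#'
#' For every probe set and time point, the log2 fold change is the
#' difference between the replicate-mean log2 signal at that time and at
#' 0 minutes. A cell is defined only where the probe set is present (all
#' replicates detected) both at that time and at 0; other cells are `NA`.
#' Fold-change variances are propagated from the intensity-dependent noise
#' model as `sd(I_t)^2/R + sd(I_0)^2/R`.
#'
#' @param sig a [signal_set()].
#' @param presence matrix from [presence_mask()].
#' @param noise a [fit_noise()] model.
#' @return object of class `fc_table`: matrices `fc` and `var`
#'   (probe sets x time points, first column is the 0-minute reference and
#'   is identically 0 where present), `times`, `R`.
#' @export
fold_changes <- function(sig, presence, noise) {
  samples <- sig$samples
  tp <- time_points(samples)
  R <- n_replicates(samples)
  M <- matrix(NA_real_, nrow(sig$values), length(tp),
              dimnames = list(rownames(sig$values), as.character(tp)))
  for (k in seq_along(tp))
    M[, k] <- rowMeans(sig$values[, .time_cols(sig$values, samples, tp[k]),
                                  drop = FALSE])
  fc <- M - M[, 1L]
  va <- matrix(NA_real_, nrow(M), ncol(M), dimnames = dimnames(M))
  sd0 <- predict_sd(noise, M[, 1L])
  for (k in seq_along(tp))
    va[, k] <- predict_sd(noise, M[, k])^2 / R + sd0^2 / R
  mask <- !(presence & presence[, 1L])
  fc[mask] <- NA_real_
  va[mask] <- NA_real_
  n_dead <- sum(!presence[, 1L])
  if (n_dead > 0L)
    message("fold_changes: ", n_dead,
            " probe sets absent at t = 0 are fully masked")
  structure(list(fc = fc, var = va, times = tp, R = R), class = "fc_table")
}

#' Gene-level fold changes
#'
#' The gene-level fold change at a time point is the median log2 fold
#' change over the gene's unmasked true-exon probe sets (even counts
#' average the two central values). Cells supported by fewer than
#' `min_ps` probe sets are masked. The variance of the median is
#' approximated by the asymptotic `1.57 * mean(per-PS variance) / m`.
#'
#' @param fc an `fc_table`.
#' @param annot refined annotation (column `refined`; only `true_exon`
#'   probe sets contribute).
#' @param min_ps minimum contributing probe sets per cell, default 3.
#' @return object of class `gene_fc`: matrices `fc`, `n`, `var`
#'   (genes x time points), and `ps_gene` (the probe-set/gene map used).
#' @export
gene_fc <- function(fc, annot, min_ps = 3L) {
  a <- annot[annot$refined == "true_exon" & annot$ps_id %in% rownames(fc$fc), ,
             drop = FALSE]
  genes <- sort(unique(a$gene_id))
  TT <- ncol(fc$fc)
  g_fc <- g_var <- matrix(NA_real_, length(genes), TT,
                          dimnames = list(genes, colnames(fc$fc)))
  g_n <- matrix(0L, length(genes), TT, dimnames = dimnames(g_fc))
  idx_by_gene <- split(match(a$ps_id, rownames(fc$fc)), a$gene_id)
  for (g in genes) {
    rows <- idx_by_gene[[g]]
    sub_fc <- fc$fc[rows, , drop = FALSE]
    sub_va <- fc$var[rows, , drop = FALSE]
    m <- colSums(!is.na(sub_fc))
    g_n[g, ] <- m
    ok <- m >= min_ps
    if (any(ok)) {
      g_fc[g, ok] <- apply(sub_fc[, ok, drop = FALSE], 2L, stats::median,
                           na.rm = TRUE)
      g_var[g, ok] <- 1.57 * colMeans(sub_va[, ok, drop = FALSE],
                                      na.rm = TRUE) / m[ok]
    }
  }
  structure(list(fc = g_fc, n = g_n, var = g_var, times = fc$times,
                 ps_gene = stats::setNames(a$gene_id, a$ps_id)),
            class = "gene_fc")
}

#' Call differentially expressed genes
#'
#' Per gene and post-stimulus time point, `z = FC / sd(FC)` with a
#' two-sided normal p-value; Benjamini-Hochberg FDR is applied across all
#' gene x time tests (or per time point with `fdr_scope = "per_time"`).
#' A gene is called differentially expressed if at any time point the
#' q-value is below `alpha` and the absolute linear fold change is at
#' least `fc_min`. Direction is recorded per time point, so a gene may be
#' up-regulated early and down-regulated late.
#'
#' @param gfc a [gene_fc()] result.
#' @param fc_min minimal linear fold change, default 1.5.
#' @param alpha FDR threshold, default 0.05.
#' @param fdr_scope `"pooled"` (default) or `"per_time"`.
#' @return list with `table` (long per gene-time: fc, z, p, q, direction)
#'   and `calls` (per gene: `de`, `max_abs_linear_fc`, `q_min`).
#' @export
call_de_genes <- function(gfc, fc_min = 1.5, alpha = 0.05,
                          fdr_scope = c("pooled", "per_time")) {
  fdr_scope <- match.arg(fdr_scope)
  post <- which(gfc$times > 0)
  fc <- gfc$fc[, post, drop = FALSE]
  va <- gfc$var[, post, drop = FALSE]
  z <- fc / sqrt(va)
  p <- 2 * stats::pnorm(-abs(z))
  q <- .adjust_fdr(p, fdr_scope)
  lg <- log2(fc_min)
  sig <- !is.na(q) & q < alpha & abs(fc) >= lg
  tab <- data.frame(
    gene_id = rep(rownames(fc), times = ncol(fc)),
    time = rep(gfc$times[post], each = nrow(fc)),
    fc = as.vector(fc), z = as.vector(z), p = as.vector(p),
    q = as.vector(q),
    direction = ifelse(as.vector(sig),
                       ifelse(as.vector(fc) > 0, "up", "down"), "none"),
    stringsAsFactors = FALSE)
  calls <- data.frame(
    gene_id = rownames(fc),
    de = rowSums(sig, na.rm = TRUE) > 0L,
    max_abs_linear_fc = 2^apply(abs(fc), 1L, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)),
    q_min = apply(q, 1L, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(table = tab, calls = calls)
}

.adjust_fdr <- function(p, fdr_scope) {
  q <- p
  if (fdr_scope == "pooled") {
    q[] <- stats::p.adjust(as.vector(p), method = "BH")
  } else {
    for (k in seq_len(ncol(p))) q[, k] <- stats::p.adjust(p[, k], method = "BH")
  }
  q
}

#' Per-probe-set deviation from the gene-level fold change
#'
#' The deviation `delta = FC_ps - FC_gene` is the TIV statistic: a probe
#' set whose fold change departs from its gene's median fold change marks a
#' change in relative isoform abundance. Its variance combines the
#' probe-set fold-change variance with the (asymptotic) variance of the
#' gene median; the positive correlation between a probe set and a median
#' that contains it is ignored, which is conservative.
#'
#' @param fc an `fc_table`.
#' @param gfc a [gene_fc()] result.
#' @return object of class `deviation_stats`: matrices `delta`, `z`, `p`
#'   (true-exon probe sets x post-stimulus time points), `gene` (probe-set
#'   to gene map), `times`.
#' @export
deviation_stats <- function(fc, gfc) {
  ps <- names(gfc$ps_gene)
  gene <- unname(gfc$ps_gene)
  post <- which(gfc$times > 0)
  d <- fc$fc[ps, post, drop = FALSE] - gfc$fc[gene, post, drop = FALSE]
  va <- fc$var[ps, post, drop = FALSE] + gfc$var[gene, post, drop = FALSE]
  z <- d / sqrt(va)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(delta = d, z = z, p = p,
                 gene = stats::setNames(gene, ps),
                 times = gfc$times[post]),
            class = "deviation_stats")
}

#' Call transcript-isoform-variation events
#'
#' Benjamini-Hochberg FDR is applied across all (probe set, post-stimulus
#' time) deviation tests; a probe set is flagged at a time point if its
#' q-value is below `alpha`. Events are maximal runs of at least
#' `min_adjacent` consecutive flagged time points with a consistent
#' deviation sign; flagged probe sets of the same gene with the same sign
#' and overlapping runs are merged into a single event. Because a run must
#' span adjacent time points, the last time point alone can never seed an
#' event.
#'
#' @param dev a [deviation_stats()] result.
#' @param alpha FDR threshold, default 0.05.
#' @param min_adjacent minimum run length, default 2.
#' @param fdr_scope `"pooled"` (default) or `"per_time"`.
#' @return data frame of events: `gene_id`, `ps_ids` (comma separated),
#'   `sign`, `start_idx`/`end_idx` (post-stimulus time indices),
#'   `time_start`/`time_end` (minutes), `run_len`, `q_min`,
#'   `max_abs_delta`, `switch_like` (run >= 3).
#' @export
call_tiv <- function(dev, alpha = 0.05, min_adjacent = 2L,
                     fdr_scope = c("pooled", "per_time")) {
  fdr_scope <- match.arg(fdr_scope)
  q <- .adjust_fdr(dev$p, fdr_scope)
  flag <- !is.na(q) & q < alpha
  sgn <- sign(dev$delta)
  runs <- list()
  cand <- which(rowSums(flag) >= min_adjacent)
  for (i in cand) {
    key <- ifelse(flag[i, ], sgn[i, ], 0)
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values != 0 & r$lengths >= min_adjacent)) {
      runs[[length(runs) + 1L]] <- list(
        ps = rownames(flag)[i], gene = unname(dev$gene[i]),
        sign = r$values[j], s = starts[j], e = ends[j],
        q_min = min(q[i, starts[j]:ends[j]]),
        d_max = max(abs(dev$delta[i, starts[j]:ends[j]])))
    }
  }
  if (length(runs) == 0L) return(.empty_events())
  rdf <- data.frame(ps = vapply(runs, `[[`, "", "ps"),
                    gene = vapply(runs, `[[`, "", "gene"),
                    sign = vapply(runs, `[[`, 0, "sign"),
                    s = vapply(runs, `[[`, 0, "s"),
                    e = vapply(runs, `[[`, 0, "e"),
                    q_min = vapply(runs, `[[`, 0, "q_min"),
                    d_max = vapply(runs, `[[`, 0, "d_max"),
                    stringsAsFactors = FALSE)
  out <- list()
  for (key in sort(unique(paste(rdf$gene, rdf$sign)))) {
    sub <- rdf[paste(rdf$gene, rdf$sign) == key, , drop = FALSE]
    sub <- sub[order(sub$s, sub$e), , drop = FALSE]
    # merge overlapping run index ranges (union of supporting times and PS)
    grp <- cumsum(c(TRUE, sub$s[-1L] > cummax(sub$e)[-nrow(sub)]))
    for (gk in unique(grp)) {
      m <- sub[grp == gk, , drop = FALSE]
      s <- min(m$s); e <- max(m$e)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = m$gene[1L],
        ps_ids = paste(sort(unique(m$ps)), collapse = ","),
        sign = m$sign[1L], start_idx = s, end_idx = e,
        time_start = dev$times[s], time_end = dev$times[e],
        run_len = e - s + 1L,
        q_min = min(m$q_min), max_abs_delta = max(m$d_max),
        switch_like = (e - s + 1L) >= 3L,
        stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$gene_id, ev$start_idx), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

.empty_events <- function() {
  data.frame(gene_id = character(0), ps_ids = character(0), sign = numeric(0),
             start_idx = integer(0), end_idx = integer(0),
             time_start = numeric(0), time_end = numeric(0),
             run_len = integer(0), q_min = numeric(0),
             max_abs_delta = numeric(0), switch_like = logical(0),
             stringsAsFactors = FALSE)
}

#' Keep only switch-like (sustained) events
#'
#' Retains events supported by at least `min_adjacent` consecutive time
#' points -- the screen's "switch-like rather than transient" criterion.
#'
#' @param events data frame from [call_tiv()].
#' @param min_adjacent minimum run length, default 3.
#' @return subset of `events`.
#' @export
switch_like_filter <- function(events, min_adjacent = 3L) {
  events[events$run_len >= min_adjacent, , drop = FALSE]
}
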